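---
title: "Distinguishing sub- from neo-functionalization in duplicated gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing sub- from neo-functionalization in duplicated gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupliverge)
```

## The question

Gene families grow by duplication. A fresh duplicate is redundant, and
redundancy is evolutionarily unstable: the copy either decays, partitions
the ancestral job with its sibling (*sub-functionalization* — different
tissues or developmental stages come to express different paralogs), or
acquires a new job outright (*neo-functionalization*, typically via a burst
of amino-acid change). The two routes leave different statistical
footprints in a family's sequences and expression profiles:

* under **gradual divergence** (weak or no divergent selection), expression
  differences accumulate with time, so expression distance between
  paralogs should increase with genetic distance — a positive association
  detectable by a Mantel matrix-permutation test within each gene class;
* under **rapid sub-functionalization**, expression partitioning completes
  shortly after each duplication, so expression distance saturates
  immediately and carries no relationship to genetic distance — the
  association is masked;
* under **neo-functionalization**, selection for amino-acid change shows up
  as elevated nonsynonymous-to-synonymous substitution ratios (Dn/Ds, ω)
  on particular lineages, testable by relating per-pair ω to genetic and
  expression distances.

`dupliverge` implements this inference pipeline end to end for pre-aligned
coding sequences plus a gene-by-sample expression table, and ships a
simulator that generates families under each regime so the whole chain can
be validated against known truth.

## Pipeline components

### Genetic distances

Pairwise distances are maximum-likelihood estimates under a reversible
substitution model: JC69 or GTR for nucleotides, the published
Jones–Taylor–Thornton (JTT) matrix for amino acids, each optionally with
discrete-gamma rate variation (K equal-probability categories, category
rate = conditional mean of its bin, normalized to mean one) and a
proportion of invariant sites. The two-sequence log-likelihood

$$\ell(t) = \sum_{\text{sites}} \log\Big[\, p_{\mathrm{inv}}\,\mathbf{1}(x{=}y)\,\pi_x
  + (1-p_{\mathrm{inv}}) \sum_{k=1}^{K} \tfrac{1}{K}\, \pi_x\, P_{xy}(t\,r_k) \Big]$$

is maximized over $t \in [0, t_{\max}]$ by Brent's method (absolute
tolerance $10^{-8}$). Sites with a gap or ambiguity in either sequence are
excluded pairwise. Defaults: $\alpha = 1$, $p_{\mathrm{inv}} = 0$, $K = 4$,
$t_{\max} = 10$ substitutions/site. A pair whose optimum sits at
$t_{\max}$ is *saturated*: it is masked (treated as undefined) rather than
clamped, and reported with a reason code. Model parameters are
configuration inputs — model selection is deliberately out of scope; the
defaults are declared, not fitted.

Trees are built by Saitou–Nei neighbor joining from the ML distance
matrix, with negative branch-length estimates clamped to zero and
Q-criterion ties broken by the lexicographically smallest label pair, so
runs are deterministic. On additive (tree-realizable) inputs NJ is exact,
which the tests exploit: `cophenetic(nj_tree(D)) == D` to $10^{-10}$ on
random additive matrices. Branch support comes from nonparametric
bootstrap: alignment columns are resampled with replacement, the distance
matrix and NJ tree recomputed, and each internal bipartition of the
point-estimate tree is annotated with the fraction of replicates
containing it (default 100 replicates). Replicates containing saturated
pairs are dropped and counted; more than half dropped is an error.

The genetic distance fed to the divergence tests defaults to the
*cophenetic* (tip-to-tip path length) distance from the NJ tree, which
smooths pairwise noise through the tree; a configuration flag
(`genetic_source = "pairwise"`) switches to the raw ML distances. The
full-likelihood tree search used upstream of this framework is replaced
here by ML-distances + NJ: the downstream tests consume only a distance
matrix, so the tree estimator is pluggable, and the distance-based
estimator keeps the pipeline fast and fully testable against additivity
oracles.

### Expression distances

Expression rows (genes) are standardized to mean zero and sample
(n−1) standard deviation one; constant rows cannot be standardized and are
dropped with a warning. The distance between two genes is
$d = 1 - r$ where $r$ is the Pearson correlation of their profiles across
samples, giving $d \in [0, 2]$ (0 = identical shape, 1 = uncorrelated,
2 = anti-correlated). Pearson correlation is affine-invariant, so scaling
does not change the distances; the scaling matters for the heatmap-style
row ordering, which uses centroid-linkage agglomerative clustering
(Lance–Williams recursion via `stats::hclust`). Centroid linkage can
produce height inversions; these are preserved, not repaired, because they
are informative about non-compact cluster geometry.

### Dn/Ds (Nei–Gojobori 1986)

Per pair of in-frame coding sequences, codons with a gap, ambiguity, or
stop in either sequence are excluded. Synonymous site counts take, at each
codon position, the fraction of non-stop single-nucleotide changes that
preserve the amino acid, summed over positions and averaged across the two
sequences (so S + N = 3 × codons exactly). Differences are counted by
enumerating all orderings of the differing positions within a codon,
discarding pathways that pass through a stop codon, and averaging the
synonymous/nonsynonymous step counts over the remaining pathways with
equal weight (if every pathway is blocked, all are used). Proportions are
Jukes–Cantor corrected, $D = -\tfrac{3}{4}\log(1 - \tfrac{4}{3}p)$, and
$\omega = D_n / D_s$. A pair is *valid* only when both corrections are
defined and $0 < \omega < 9$; invalid pairs are masked in the ω matrix but
kept in the pair table with reason codes (`identical`, `saturation`,
`zero-synonymous`, `zero-nonsynonymous`, `omega-out-of-range`). NG86 was
chosen over counting variants with transition/transversion weighting
because it is fully specified, symmetric, and exactly testable against a
brute-force neighbor-enumeration oracle — which the acceptance suite runs
over all 61 × 61 sense-codon pairs.

### Mantel tests and regressions

The Mantel statistic is the Pearson correlation of the off-diagonal
entries of two distance matrices over the pairs defined (unmasked) in
both. The null distribution permutes the row/column labels of the second
matrix jointly, with the mask travelling along — masked ω pairs are
excluded pair-wise rather than dropping whole genes, which preserves data
and keeps the permutation scheme exchangeable. With at most 7 labels all
permutations are enumerated and the p-value is exact; otherwise 999
Monte-Carlo permutations (seeded) with the $(1+b)/(1+m)$ correction, so p
is never exactly zero. Tests are one-sided (upper) by default because the
hypotheses concern positive associations; a flag gives two-sided tests on
$|r|$. No multiple-testing correction is applied across classes — the
per-class results are reported raw.

Matrix regression fits ordinary least squares of one vectorized matrix on
another over usable pairs, with a permutation p-value for the slope.
Between classes, the class means are compared by weighted least squares
(`stats::lm` with weights), the weight being the number of usable pairs
behind each mean ("sample size" in the literal sense); the p-value is the
two-sided t-test on the slope with n − 2 degrees of freedom, and at least
three classes are required.

## The simulator

`simulate_family_tree` draws a Yule (pure-birth) duplication tree: with
$k$ lineages alive the waiting time to the next duplication is
$\mathrm{Exp}(k\lambda)$, the duplicating lineage is uniform, and after
the $n$-th tip appears the tips are extended by a final
$\mathrm{Exp}(n\lambda)$; expected root-to-tip depth is
$\sum_{k=2}^{n} 1/(k\lambda)$, which the tests check against 800
replicates.

`simulate_codon_sequences` evolves codon sequences by a Gillespie
simulation of single-nucleotide events: proposals follow HKY-style rates
(transition bias κ, target-frequency weighting) normalized to one proposal
per site per unit branch length; proposals creating stops are rejected,
synonymous proposals always accepted, and nonsynonymous proposals accepted
with the branch's ω. Selection strength is therefore an exactly
controllable acceptance probability in $[0, 1]$; "positive selection"
branches in the neo-burst regime use ω = 1 *plus* expression jumps rather
than ω > 1, which keeps the realized rate interpretable. There are no
indels: alignment is upstream of this framework's scope, so the simulator
emits true alignments directly.

`simulate_expression` evolves per-tissue log-expression and exponentiates
for output (the analysis re-scales rows, and Pearson correlation is
unaffected by the monotone transform on the simulated scale — positivity
just makes the values look like expression levels):

* **gradual_bm** — independent Brownian increments
  $N(0, \sigma^2 \cdot b)$ per tissue per branch, so divergence grows
  with path length (default $\sigma^2 = 1$);
* **rapid_partition** — at every duplication each daughter independently
  re-draws a balanced expressed-tissue subset at log level ±jump/2
  (default jump = 2), erasing the inherited pattern, followed by weak
  drift ($\sigma^2_{\mathrm{post}} = 0.01$);
* **neo_burst** — Brownian drift everywhere plus a one-off balanced
  ±jump/2 shift on designated burst branches (the same branches that get
  elevated ω).

The rapid-partition design deserves a note, because it was the one
genuinely open design choice. Variants in which the two daughters receive
strictly complementary jumps — the textbook picture of reciprocal domain
silencing — turn out to *induce* association between expression and
genetic distance at family scale rather than masking it: cumulative
complementary jumps make expression divergence grow with the number of
separating duplications, which tracks path length, and non-cumulative
complementary jumps make sister pairs maximally divergent, which produces
a spurious *negative* association. Only full re-assortment at each
duplication (each daughter drawing its own domain independently) makes
all pairs exchangeable, which is the saturated end-state the masking
hypothesis describes: every pair is already fully re-partitioned at its
last common duplication, so expression distance carries no signal about
time. At the package's fixture scale this yields mean Mantel r ≈ 0 and a
rejection rate at the nominal 5% level, while the gradual regime rejects
in well over 80% of runs — the discrimination the acceptance suite
demonstrates.

What the simulator does *not* emulate about real expression atlases:
measurement noise and library-size effects, correlated tissues (the
tissues here are exchangeable and independent given the tree),
gene-family-external expression constraints, gene loss, indels, and
among-site ω variation. Passing the regime-discrimination tests therefore
shows the inference machinery behaves correctly under its own model
assumptions — not that real families will separate as cleanly.

## Fixture and problem sizes

The packaged fixture (`inst/extdata/fixture`) holds three classes of eight
genes each — gradual drift (`qa`), rapid partitioning (`qb`), and a
neo-burst class (`rs`) with two high-ω burst branches — with 300 codons,
12 tissues, trees rescaled to a mean root-to-tip depth of 0.3
substitutions/site, background ω = 0.2, κ = 2 and equal base frequencies.
These are the study conditions used throughout the tests: 300 codons gives
distance estimates precise enough for 8-tip tree inference, depth 0.3 is
comfortably below saturation, and ω = 0.2 represents ordinary purifying
selection. The fixture regenerates bit-identically from the seeds recorded
in `dataset_config.json` / `truth.json`. Validation problem sizes (200
replicates for distance-recovery bias, 500 for Mantel type-I error, 50 per
regime for discrimination, 100 bootstrap replicates) were chosen to give
Monte-Carlo error comfortably inside each test's tolerance band.

## Numerical conventions and degenerate inputs

* Distance matrices are symmetric with an exactly zero diagonal; masks are
  symmetric and travel with label permutations.
* Serialization (TSV, Newick, JSON) uses 17 significant digits; round
  trips are lossless to $10^{-12}$.
* Transition matrices come from the symmetrized eigendecomposition of Q;
  tiny negative probabilities from round-off are clipped at zero, and the
  per-site likelihood is floored at $10^{-300}$ before logging.
* Constant expression rows are dropped (scaling) or rejected
  (correlation), never silently imputed. Identical sequences give distance
  0 without optimization. All-equal distance matrices produce a valid NJ
  tree under the tie rule.
* Every stochastic stage (tree, sequence, expression simulation;
  bootstrap; permutation tests) takes an explicit seed and is
  bit-reproducible given it.

## Known limitations

* NG86's equal pathway weighting means a pair of codons that diverged by
  purely synonymous steps can still be assigned a fractional
  nonsynonymous difference count when some minimal pathway passes through
  a different amino acid (e.g. Leu TTA vs CTT); under an ω = 0 simulation
  the tip *proteins* are always identical, but pathway-averaged Nd is not
  always exactly zero. This is a property of the counting method, not a
  bug, and is shared by standard NG86 implementations.
* The ML-distance + NJ estimator is not a full maximum-likelihood tree
  search; bootstrap supports are supports for the distance-based
  estimator.
* GTR defaults to JC-like exchangeabilities unless configured; the
  package does not estimate model parameters.
* One-sided Mantel tests assume the alternative of positive association;
  genuinely negative associations (as strict complementary partitioning
  would produce) require the two-sided flag.
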