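#' Neighbor-joining tree from a distance matrix
#'
#' Saitou–Nei agglomeration with the standard Q-criterion. Deterministic:
#' ties in the Q-criterion (within 1e-12) are broken by the
#' lexicographically smallest sorted label pair. Negative branch-length
#' estimates are clamped to zero. The result is unrooted, stored with a
#' trifurcating root, as an ape `phylo`.
#'
#' @param d a complete (unmasked) [pair_dist] with at least 3 labels
#' @return an ape `phylo`
#' @export
nj_tree <- function(d) {
  if (has_masked(d)) stop("incomplete distance matrix: masked pairs present",
                          call. = FALSE)
  n <- length(d$labels)
  if (n < 3L) stop("neighbor joining needs >= 3 labels", call. = FALSE)
  dm <- d$values
  # each active cluster carries its Newick fragment
  node <- paste0(escape_newick(d$labels))
  act <- seq_len(n)
  fmt <- function(x) formatC(max(x, 0), format = "g", digits = 17)
  while (length(act) > 3L) {
    r <- length(act)
    dmc <- dm[act, act, drop = FALSE]
    rs <- rowSums(dmc)
    qm <- (r - 2) * dmc - outer(rs, rs, "+")
    diag(qm) <- Inf
    qmin <- min(qm)
    cand <- which(qm - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # lexicographic tie rule on sorted label pairs
    labs_a <- vapply(seq_len(nrow(cand)), function(k)
      node_label(node[act[cand[k, 1]]]), character(1))
    labs_b <- vapply(seq_len(nrow(cand)), function(k)
      node_label(node[act[cand[k, 2]]]), character(1))
    lo <- pmin(labs_a, labs_b); hi <- pmax(labs_a, labs_b)
    pick <- order(lo, hi)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    vi <- 0.5 * dmc[i, j] + (rs[i] - rs[j]) / (2 * (r - 2))
    vj <- dmc[i, j] - vi
    ai <- act[i]; aj <- act[j]
    newick <- sprintf("(%s:%s,%s:%s)", node[ai], fmt(vi), node[aj], fmt(vj))
    # distances from the new node u to every other active cluster
    du <- 0.5 * (dm[ai, act] + dm[aj, act] - dm[ai, aj])
    dm <- rbind(cbind(dm, 0), 0)
    u <- nrow(dm)
    dm[u, act] <- du; dm[act, u] <- du; dm[u, u] <- 0
    node <- c(node, newick)
    act <- c(setdiff(act, c(ai, aj)), u)
  }
  a <- act[1]; b <- act[2]; c_ <- act[3]
  va <- (dm[a, b] + dm[a, c_] - dm[b, c_]) / 2
  vb <- (dm[a, b] + dm[b, c_] - dm[a, c_]) / 2
  vc <- (dm[a, c_] + dm[b, c_] - dm[a, b]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", node[a], fmt(va), node[b], fmt(vb),
                 node[c_], fmt(vc))
  ape::read.tree(text = nwk)
}

# first (alphabetically smallest) tip label inside a Newick fragment,
# used as the deterministic identity of a cluster for tie breaking
node_label <- function(frag) {
  labs <- strsplit(gsub("[():]", ",", frag), ",")[[1]]
  labs <- labs[nzchar(labs) & is.na(suppressWarnings(as.numeric(labs)))]
  min(labs)
}

escape_newick <- function(x) {
  if (any(grepl("[(),:;[:space:]]", x))) stop("labels contain Newick metacharacters",
                                        call. = FALSE)
  x
}

#' Cophenetic (patristic) distances of a tree
#'
#' Sum of branch lengths on the tip-to-tip path, as a [pair_dist].
#'
#' @param tree an ape `phylo` with branch lengths
#' @export
cophenetic_dist <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree has missing branch lengths", call. = FALSE)
  }
  m <- ape::cophenetic.phylo(tree)
  m <- m[tree$tip.label, tree$tip.label]
  diag(m) <- 0
  pair_dist((m + t(m)) / 2)
}

#' Bootstrap bipartition supports for a distance-based tree
#'
#' Resamples alignment columns with replacement, recomputes the ML distance
#' matrix and NJ tree per replicate, and attaches to each internal edge of
#' the point-estimate tree the fraction of replicates containing the same
#' bipartition (as `node.label`, in `[0, 1]`). Replicates in which any pair
#' is saturated or has no data are dropped and counted; more than 50%
#' dropped is an error.
#'
#' @param a a [gene_alignment]
#' @param model a [subst_model]
#' @param n_boot number of bootstrap replicates (>= 1)
#' @param seed RNG seed (required, for reproducibility)
#' @param t_max passed through to the distance computation
#' @return the point-estimate `phylo` with `node.label` supports and
#'   attribute `n_used` (replicates retained).
#' @export
bootstrap_support <- function(a, model, n_boot = 100L, seed, t_max = 10) {
  stopifnot(n_boot >= 1L)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  point <- nj_tree(ml_distance_matrix(a, model, t_max))
  L <- aln_width(a)
  set.seed(seed)
  trees <- vector("list", n_boot)
  dropped <- 0L
  for (r in seq_len(n_boot)) {
    cols <- sample.int(L, L, replace = TRUE)
    ar <- aln_subset(a, cols = cols)
    tr <- tryCatch({
      dr <- ml_distance_matrix(ar, model, t_max)
      if (has_masked(dr)) NULL else nj_tree(dr)
    }, error = function(e) NULL)
    if (is.null(tr)) dropped <- dropped + 1L else trees[[r]] <- tr
  }
  trees <- Filter(Negate(is.null), trees)
  if (dropped > n_boot / 2) {
    stop(sprintf("bootstrap failure: %d of %d replicates unusable",
                 dropped, n_boot), call. = FALSE)
  }
  cnt <- ape::prop.clades(point, trees, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  point$node.label <- formatC(cnt / length(trees), format = "g", digits = 6)
  attr(point, "n_used") <- length(trees)
  point
}

#' Numeric bipartition supports of a tree with node labels
#' @param tree `phylo` with `node.label` written by [bootstrap_support]
#' @return numeric vector (NA for unlabeled nodes such as the root)
#' @export
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(numeric(0))
  suppressWarnings(as.numeric(tree$node.label))
}
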