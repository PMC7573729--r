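# Gene-family simulator: duplication trees (Yule), codon sequences evolved
# with controllable per-branch omega, and tissue expression profiles under
# three divergence regimes. Every generator is deterministic given its seed.

#' Simulate a duplication (pure-birth) family tree
#'
#' Yule process: starting from the root split into two lineages, wait an
#' exponential time with rate `k * lambda` while `k` lineages are active,
#' then split a uniformly chosen lineage; after the n-th tip appears the
#' tips are extended by a final `Exp(n * lambda)` waiting time. Expected
#' root-to-tip depth is `sum_{k=2..n} 1 / (k * lambda)`.
#'
#' @param n_tips number of tips (>= 3)
#' @param lambda birth rate (> 0)
#' @param seed RNG seed
#' @param tip_prefix tip label prefix (labels are `g1 .. gn`)
#' @return rooted binary ape `phylo` with positive branch lengths
#' @export
simulate_family_tree <- function(n_tips, lambda = 1, seed, tip_prefix = "g") {
  if (n_tips < 3L) stop("need n_tips >= 3", call. = FALSE)
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  # node records: parent, length, children
  parent <- c(NA_integer_, 1L, 1L)
  len <- c(0, 0, 0)
  active <- c(2L, 3L)
  while (length(active) < n_tips) {
    k <- length(active)
    dt <- stats::rexp(1, rate = k * lambda)
    len[active] <- len[active] + dt
    pick <- active[sample.int(k, 1L)]
    c1 <- length(parent) + 1L; c2 <- c1 + 1L
    parent <- c(parent, pick, pick)
    len <- c(len, 0, 0)
    active <- c(setdiff(active, pick), c1, c2)
  }
  len[active] <- len[active] + stats::rexp(1, rate = n_tips * lambda)
  children <- split(seq_along(parent)[-1], parent[-1])
  labels <- paste0(tip_prefix, seq_len(n_tips))
  names(labels) <- as.character(sort(active))
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  build <- function(v) {
    kids <- children[[as.character(v)]]
    body <- if (is.null(kids)) labels[[as.character(v)]] else
      sprintf("(%s)", paste(vapply(kids, build, character(1)), collapse = ","))
    if (is.na(parent[v])) paste0(body, ";") else
      sprintf("%s:%s", body, fmt(len[v]))
  }
  ape::read.tree(text = build(1L))
}

# HKY-style single-nucleotide proposal rates, normalized so the expected
# proposal rate per site at frequency equilibrium is one
hky_proposal <- function(kappa, pi) {
  nt <- c("A", "C", "G", "T")
  stopifnot(length(pi) == 4, all(pi > 0))
  pi <- pi / sum(pi)
  names(pi) <- nt
  transitions <- matrix(c("A", "G", "C", "T"), 2, byrow = TRUE)
  R <- matrix(0, 4, 4, dimnames = list(nt, nt))
  for (x in nt) for (y in nt) {
    if (x == y) next
    ti <- any((transitions[, 1] == x & transitions[, 2] == y) |
              (transitions[, 1] == y & transitions[, 2] == x))
    R[x, y] <- (if (ti) kappa else 1) * pi[y]
  }
  mu <- sum(pi * rowSums(R))
  R / mu
}

#' Simulate codon sequences along a tree with per-branch omega
#'
#' The root sequence is drawn codon-wise from the nucleotide frequencies,
#' rejecting stop codons. Along each branch, single-nucleotide events are
#' proposed by a Gillespie simulation at HKY-style rates (transition bias
#' `kappa`, target frequency weighting) normalized to one proposal per site
#' per unit branch length; events creating stop codons are rejected,
#' synonymous events are always accepted, and nonsynonymous events are
#' accepted with probability `omega` for the branch. With `omega = 1` the
#' realized substitution rate equals the proposal rate, so branch lengths
#' are approximately substitutions per site.
#'
#' @param tree ape `phylo` with branch lengths
#' @param n_codons root sequence length in codons (>= 50)
#' @param kappa transition/transversion proposal ratio
#' @param pi nucleotide frequencies (A, C, G, T)
#' @param omega global scalar in `[0, 1]`, or numeric vector over
#'   `tree$edge` rows
#' @param seed RNG seed
#' @return a [codon_alignment] of the tip sequences; attribute
#'   `omega_branch` records the per-edge omega used
#' @export
simulate_codon_sequences <- function(tree, n_codons, kappa = 2,
                                     pi = rep(0.25, 4), omega = 1, seed) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_codons < 50L) stop("need >= 50 codons", call. = FALSE)
  tree <- ape::reorder.phylo(tree, "cladewise")
  ne <- nrow(tree$edge)
  omega_e <- if (length(omega) == 1L) rep(omega, ne) else omega
  if (length(omega_e) != ne) stop("omega must be scalar or one per edge",
                                  call. = FALSE)
  if (any(omega_e < 0 | omega_e > 1)) {
    stop("omega must lie in [0, 1] (acceptance probability)", call. = FALSE)
  }
  set.seed(seed)
  nt <- c("A", "C", "G", "T")
  tab <- codon_tables()
  R <- hky_proposal(kappa, pi)
  rate_out <- rowSums(R)
  pi <- pi / sum(pi); names(pi) <- nt
  # root: codons drawn from pi, rejecting stops
  draw_codon <- function() {
    repeat {
      cd <- sample(nt, 3, replace = TRUE, prob = pi)
      if (tab$aa[paste(cd, collapse = "")] != "*") return(cd)
    }
  }
  root_seq <- match(unlist(replicate(n_codons, draw_codon(), simplify = FALSE)),
                    nt)
  L <- 3L * n_codons
  evolve <- function(s, bl, om) {
    t <- 0
    repeat {
      rates <- rate_out[s]
      total <- sum(rates)
      t <- t + stats::rexp(1, rate = total)
      if (t > bl) break
      site <- sample.int(L, 1L, prob = rates)
      x <- s[site]
      y <- sample.int(4L, 1L, prob = R[x, ])
      cod_i <- (site - 1L) %/% 3L
      cod_idx <- cod_i * 3L + 1:3
      old <- s[cod_idx]
      new <- old; new[cod_idx == site] <- y
      aa_old <- tab$aa[paste(nt[old], collapse = "")]
      aa_new <- tab$aa[paste(nt[new], collapse = "")]
      if (aa_new == "*") next                      # stop: reject
      if (aa_new == aa_old || stats::runif(1) < om) s[site] <- y
    }
    s
  }
  nt_tips <- length(tree$tip.label)
  seqs_at <- vector("list", nt_tips + tree$Nnode)
  root_node <- nt_tips + 1L
  seqs_at[[root_node]] <- root_seq
  for (e in seq_len(ne)) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    seqs_at[[child]] <- evolve(seqs_at[[par]], tree$edge.length[e], omega_e[e])
  }
  out <- vapply(seq_len(nt_tips),
                function(i) paste(nt[seqs_at[[i]]], collapse = ""),
                character(1))
  names(out) <- tree$tip.label
  a <- codon_alignment(out)
  attr(a, "omega_branch") <- omega_e
  a
}

#' Simulate tissue expression profiles along a tree
#'
#' Log-expression per tissue evolves along the tree under one of three
#' regimes, then is exponentiated (Pearson correlation distances are
#' invariant to the monotone analysis-side rescaling):
#' \describe{
#'   \item{gradual_bm}{Brownian drift: each tissue gains independent
#'     `N(0, sigma2 * branch_length)` increments, so expression divergence
#'     grows with patristic distance.}
#'   \item{rapid_partition}{immediate sub-functionalization: at every
#'     duplication each daughter independently re-partitions the ancestral
#'     expression domain, drawing a fresh balanced tissue subset expressed
#'     at log level `+jump/2` (silenced tissues at `-jump/2`) that erases
#'     the previous pattern; branches then add only weak drift
#'     `sigma2_post`. Because every pair of paralogs is already fully
#'     re-assorted at its last common duplication, expression distance is
#'     set by the partition draws alone and is independent of branch
#'     lengths.}
#'   \item{neo_burst}{Brownian drift everywhere plus one-off jumps of
#'     magnitude `jump` (random balanced sign vector) on the designated
#'     `burst_edges`.}
#' }
#'
#' @param tree ape `phylo`
#' @param n_tissues number of tissues (>= 3)
#' @param regime `"gradual_bm"`, `"rapid_partition"` or `"neo_burst"`
#' @param params regime parameters: `sigma2` (drift rate, default 1),
#'   `jump` (jump magnitude, default 2), `sigma2_post` (post-jump drift for
#'   rapid_partition, default 0.01), `burst_edges` (edge indices for
#'   neo_burst)
#' @param seed RNG seed
#' @return tips-by-tissues expression matrix (positive values); attribute
#'   `log_expr` holds the simulated log scale
#' @export
simulate_expression <- function(tree, n_tissues, regime = c("gradual_bm",
                                "rapid_partition", "neo_burst"),
                                params = list(), seed) {
  regime <- match.arg(regime)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_tissues < 3L) stop("need >= 3 tissues", call. = FALSE)
  p <- utils::modifyList(list(sigma2 = 1, jump = 2, sigma2_post = 0.01,
                              burst_edges = integer(0)), params)
  set.seed(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  prof <- vector("list", ntip + tree$Nnode)
  prof[[ntip + 1L]] <- rep(0, n_tissues)
  drift_rate <- if (regime == "rapid_partition") p$sigma2_post else p$sigma2
  # random balanced sign vector, used for neo-functionalization bursts
  sign_vec <- function(mag) {
    up <- sample.int(n_tissues, floor(n_tissues / 2))
    v <- rep(-mag / 2, n_tissues)
    v[up] <- mag / 2
    v
  }
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    bl <- tree$edge.length[e]
    drift <- stats::rnorm(n_tissues, 0, sqrt(drift_rate * bl))
    if (regime == "rapid_partition") {
      # the duplication at the parent node erases the inherited pattern:
      # each daughter draws its own balanced expression domain
      prof[[child]] <- sign_vec(p$jump) + drift
    } else {
      x <- prof[[par]] + drift
      if (regime == "neo_burst" && e %in% p$burst_edges) {
        x <- x + sign_vec(p$jump)
      }
      prof[[child]] <- x
    }
  }
  logm <- do.call(rbind, prof[seq_len(ntip)])
  rownames(logm) <- tree$tip.label
  colnames(logm) <- paste0("tissue", seq_len(n_tissues))
  out <- exp(logm)
  attr(out, "log_expr") <- logm
  out
}

#' Generate a complete synthetic gene-family dataset on disk
#'
#' For each configured class: simulates a duplication tree, codon sequences
#' and expression profiles, and writes codon FASTA, translated protein
#' FASTA, an expression TSV covering all classes, true trees as Newick, and
#' a truth JSON sufficient to regenerate the dataset bit-identically.
#'
#' @param config list (or path to a JSON file) with fields `classes`
#'   (named list: per class `n_tips`, `omega`, `regime`, optional
#'   `regime_params`, `burst_edges`), and shared fields `n_codons`,
#'   `n_tissues`, `lambda`, `kappa`, `seed`. Per-class seeds are derived
#'   deterministically from `seed`.
#' @param out_dir output directory (created if missing)
#' @return invisibly, the truth list (also written as `truth.json`)
#' @export
generate_dataset <- function(config, out_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- utils::modifyList(list(n_codons = 300L, n_tissues = 12L, lambda = 1,
                                kappa = 2, tree_scale = 0.3, seed = 1L),
                           config)
  if (is.null(cfg$classes) || !length(cfg$classes)) {
    stop("config$classes is required", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- list(config = cfg, classes = list())
  expr_all <- list()
  tab <- codon_tables()
  for (k in seq_along(cfg$classes)) {
    cls <- names(cfg$classes)[k]
    cc <- utils::modifyList(list(n_tips = 8L, omega = 0.2,
                                 regime = "gradual_bm",
                                 regime_params = list(),
                                 omega_burst = 1),
                            cfg$classes[[k]])
    seed_tree <- cfg$seed * 1000L + k * 3L
    seed_seq <- seed_tree + 1L
    seed_expr <- seed_tree + 2L
    tr <- simulate_family_tree(cc$n_tips, cfg$lambda, seed_tree,
                               tip_prefix = paste0(cls, "_g"))
    # rescale so mean root-to-tip depth ~ tree_scale substitutions/site
    depth <- mean(ape::node.depth.edgelength(tr)[seq_len(cc$n_tips)])
    tr$edge.length <- tr$edge.length * cfg$tree_scale / depth
    omega_e <- if (!is.null(cc$omega_edges)) {
      as.numeric(cc$omega_edges)
    } else if (cc$regime == "neo_burst" &&
               !is.null(cc$regime_params$burst_edges)) {
      oe <- rep(cc$omega, 2L * cc$n_tips - 2L)
      oe[as.integer(cc$regime_params$burst_edges)] <- cc$omega_burst
      oe
    } else {
      cc$omega
    }
    aln <- simulate_codon_sequences(tr, cfg$n_codons, cfg$kappa,
                                    omega = omega_e, seed = seed_seq)
    expr <- simulate_expression(tr, cfg$n_tissues, cc$regime,
                                cc$regime_params, seed_expr)
    write_fasta(aln, file.path(out_dir, paste0(cls, "_codon.fasta")))
    prot <- vapply(aln$seqs, function(s)
      paste(seqinr::translate(strsplit(s, "")[[1]]), collapse = ""),
      character(1))
    write_fasta(gene_alignment(prot, "amino-acid"),
                file.path(out_dir, paste0(cls, "_protein.fasta")))
    write_newick(tr, file.path(out_dir, paste0(cls, "_true_tree.nwk")))
    expr_all[[cls]] <- expr
    truth$classes[[cls]] <- list(
      n_tips = cc$n_tips, regime = cc$regime,
      regime_params = cc$regime_params,
      omega = omega_e,
      expected_mantel_sign = switch(cc$regime, gradual_bm = "positive",
                                    rapid_partition = "none",
                                    neo_burst = "none"),
      seeds = list(tree = seed_tree, sequence = seed_seq,
                   expression = seed_expr),
      newick = ape::write.tree(tr, digits = 17))
  }
  expr_mat <- do.call(rbind, expr_all)
  rownames(expr_mat) <- unlist(lapply(expr_all, rownames), use.names = FALSE)
  write_expression_tsv(expr_mat, file.path(out_dir, "expression.tsv"))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}
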