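# Independent brute-force oracles used to freeze expected values.
# These deliberately avoid the package's own code paths.

# --- NG86 oracle -----------------------------------------------------------
# Translation table built from first principles (hard-coded standard code),
# independent of the package's seqinr-derived table.
oracle_code <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",   # TTT..TGG
    "LLLLPPPPHHQQRRRR",   # CTT..CGG
    "IIIMTTTTNNKKSSRR",   # ATT..AGG
    "VVVVAAAADDEEGGGG"),  # GTT..GGG
    "")[[1]]
  nm <- character(64)
  k <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1
    nm[k] <- paste0(b1, b2, b3)
  }
  names(aas) <- nm
  aas
})

oracle_translate <- function(codon) unname(oracle_code[codon])

# synonymous sites of a codon: per position, fraction of the non-stop
# single-nucleotide neighbors that conserve the amino acid
oracle_syn_sites <- function(codon) {
  bases <- c("T", "C", "A", "G")
  aa0 <- oracle_translate(codon)
  total <- 0
  for (pos in 1:3) {
    ch <- strsplit(codon, "")[[1]]
    neigh <- vapply(setdiff(bases, ch[pos]), function(b) {
      ch2 <- ch; ch2[pos] <- b; paste(ch2, collapse = "")
    }, character(1))
    aa <- oracle_translate(neigh)
    keep <- aa != "*"
    if (any(keep)) total <- total + sum(aa[keep] == aa0) / sum(keep)
  }
  total
}

# exhaustive pathway enumeration for Sd/Nd between two sense codons
oracle_sd_nd <- function(c1, c2) {
  p1 <- strsplit(c1, "")[[1]]
  p2 <- strsplit(c2, "")[[1]]
  diffs <- which(p1 != p2)
  if (!length(diffs)) return(c(0, 0))
  orders <- if (length(diffs) == 1) list(diffs) else {
    # all orderings via recursion on index vectors
    gen <- function(v) {
      if (length(v) == 1) return(list(v))
      res <- list()
      for (i in seq_along(v))
        for (tail_ in gen(v[-i])) res[[length(res) + 1]] <- c(v[i], tail_)
      res
    }
    gen(diffs)
  }
  collect <- function(drop_stop_paths) {
    acc <- c(0, 0); used <- 0
    for (ord in orders) {
      cur <- p1; sd <- 0; nd <- 0; blocked <- FALSE
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- p2[pos]
        aa_n <- oracle_translate(paste(nxt, collapse = ""))
        if (drop_stop_paths && aa_n == "*") { blocked <- TRUE; break }
        aa_c <- oracle_translate(paste(cur, collapse = ""))
        if (aa_n == aa_c) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (!blocked) { acc <- acc + c(sd, nd); used <- used + 1 }
    }
    if (used > 0) acc / used else NULL
  }
  out <- collect(TRUE)
  if (is.null(out)) out <- collect(FALSE)
  out
}

# --- small random generators ----------------------------------------------
# random binary tree with positive branch lengths (for additive matrices)
random_additive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.05, 1))
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# distance matrix from random points (for independence simulations)
random_point_dist <- function(n, seed, dim = 3) {
  set.seed(seed)
  pts <- matrix(stats::rnorm(n * dim), n)
  m <- as.matrix(stats::dist(pts))
  dimnames(m) <- list(paste0("p", seq_len(n)), paste0("p", seq_len(n)))
  pair_dist(m)
}

# textbook per-pair Pearson r
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# weighted least squares via explicit normal equations
oracle_wls <- function(x, y, w) {
  X <- cbind(1, x)
  b <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  yw <- sum(w * y) / sum(w)
  fit <- X %*% b
  r2 <- 1 - sum(w * (y - fit)^2) / sum(w * (y - yw)^2)
  list(intercept = b[1], beta = b[2], r2 = r2)
}

# exhaustive Mantel p-value over all label permutations of the second matrix
oracle_mantel_exact <- function(m1, m2) {
  n <- nrow(m1)
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  perms <- gtools_permutations(n)
  r_obs <- oracle_pearson(v1, m2[ut])
  hits <- 0
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    r_p <- oracle_pearson(v1, m2[p, p][ut])
    if (r_p >= r_obs - 1e-12) hits <- hits + 1
  }
  hits / nrow(perms)
}

# all permutations of 1..n as a matrix (plain recursion)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# hand Lance-Williams centroid agglomeration (naive O(n^3)), smallest-index
# tie handling; returns merge heights in order
oracle_centroid_heights <- function(m) {
  n <- nrow(m)
  sizes <- rep(1, n)
  act <- seq_len(n)
  d <- m
  heights <- numeric(0)
  while (length(act) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (i in act) for (j in act) if (i < j && d[i, j] < bh - 1e-15) {
      bh <- d[i, j]; best <- c(i, j)
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, bh)
    ni <- sizes[i]; nj <- sizes[j]
    newrow <- sapply(seq_len(nrow(d)), function(k) {
      if (!(k %in% act) || k %in% c(i, j)) return(0)
      ni / (ni + nj) * d[i, k] + nj / (ni + nj) * d[j, k] -
        ni * nj / (ni + nj)^2 * d[i, j]
    })
    d <- rbind(cbind(d, newrow), c(newrow, 0))
    sizes <- c(sizes, ni + nj)
    act <- c(setdiff(act, c(i, j)), nrow(d))
  }
  heights
}
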