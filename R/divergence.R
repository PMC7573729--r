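# Mantel permutation tests and regressions between distance matrices, the
# within-class / between-class inference for sub- vs neo-functionalization.

# align two pair_dist objects on common label order and return the usable
# (unmasked-in-both) off-diagonal pair vectors plus permutation plumbing
mantel_prepare <- function(d1, d2) {
  if (!setequal(d1$labels, d2$labels)) {
    stop("distance matrices carry different labels", call. = FALSE)
  }
  d2 <- dist_reorder(d2, d1$labels)
  n <- length(d1$labels)
  ut <- upper.tri(d1$values)
  list(n = n, v1 = d1$values, m1 = d1$mask, v2 = d2$values, m2 = d2$mask,
       ut = ut)
}

# statistic on one labeling: Pearson r over pairs unmasked in both matrices
mantel_stat <- function(prep, perm, stat = c("cor", "ols")) {
  stat <- match.arg(stat)
  v2 <- prep$v2[perm, perm]
  m2 <- prep$m2[perm, perm]
  ok <- prep$ut & !prep$m1 & !m2
  x <- prep$v1[ok]; y <- v2[ok]
  if (length(x) < 3L) return(NULL)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NULL)
  if (stat == "cor") {
    list(r = stats::cor(x, y), n_pairs = length(x))
  } else {
    # OLS of y (response) on x (predictor) over usable pairs
    beta <- stats::cov(x, y) / stats::var(x)
    list(beta = beta, intercept = mean(y) - beta * mean(x),
         r2 = stats::cor(x, y)^2, n_pairs = length(x))
  }
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (k in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
    }
  }
  out
}

#' Mantel matrix-permutation test
#'
#' Pearson correlation between the off-diagonal entries of two labeled
#' distance matrices, with the null distribution generated by jointly
#' permuting the row/column labels of the second matrix. Masked pairs
#' (undefined in either matrix) are excluded from the statistic, and the
#' mask travels with the permuted labels. For `n <= exhaustive_max` labels
#' all permutations are enumerated and the p-value is exact; otherwise
#' `n_perm` Monte-Carlo draws are used with the standard
#' `(1 + b) / (1 + n_perm)` correction.
#'
#' @param d1,d2 [pair_dist] objects over the same labels
#' @param n_perm Monte-Carlo permutation count (default 999)
#' @param seed RNG seed for the permutation draws
#' @param tail `"one"` (upper: positive association, the default) or
#'   `"two"` (on `|r|`)
#' @param exhaustive_max enumerate all permutations when the label count is
#'   at most this (default 7)
#' @return object of class `mantel_result`: `r`, `p`, `n_labels`,
#'   `n_pairs`, `n_permutations`, `exhaustive`, `tail`, `seed`
#' @export
mantel <- function(d1, d2, n_perm = 999L, seed = 1L,
                   tail = c("one", "two"), exhaustive_max = 7L) {
  tail <- match.arg(tail)
  prep <- mantel_prepare(d1, d2)
  obs <- mantel_stat(prep, seq_len(prep$n))
  if (is.null(obs)) {
    stop("insufficient usable pairs (need >= 3 with variation)",
         call. = FALSE)
  }
  score <- function(r) if (tail == "one") r else abs(r)
  obs_s <- score(obs$r)
  exhaustive <- prep$n <= exhaustive_max
  eps <- 1e-12
  if (exhaustive) {
    perms <- all_permutations(prep$n)
    hits <- 0L; m <- 0L
    for (p in perms) {
      st <- mantel_stat(prep, p)
      if (is.null(st)) next
      m <- m + 1L
      if (score(st$r) >= obs_s - eps) hits <- hits + 1L
    }
    p_val <- hits / m
    n_used <- m
  } else {
    set.seed(seed)
    hits <- 0L; m <- 0L
    for (k in seq_len(n_perm)) {
      p <- sample.int(prep$n)
      st <- mantel_stat(prep, p)
      if (is.null(st)) next
      m <- m + 1L
      if (score(st$r) >= obs_s - eps) hits <- hits + 1L
    }
    p_val <- (1 + hits) / (1 + m)
    n_used <- m
  }
  structure(list(r = obs$r, p = p_val, n_labels = prep$n,
                 n_pairs = obs$n_pairs, n_permutations = n_used,
                 exhaustive = exhaustive, tail = tail, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<mantel_result> r=%.4f p=%.4g (%s, %d labels, %d pairs, %d perms%s)\n",
              x$r, x$p, x$tail, x$n_labels, x$n_pairs, x$n_permutations,
              if (x$exhaustive) ", exhaustive" else ""))
  invisible(x)
}

#' Matrix regression with label-permutation p-value
#'
#' Ordinary least squares of the vectorized response matrix on the
#' vectorized predictor matrix over usable (unmasked) pairs, with a
#' permutation p-value for the slope obtained by permuting the response
#' matrix's labels.
#'
#' @param dy response [pair_dist]
#' @param dx predictor [pair_dist]
#' @inheritParams mantel
#' @return object of class `regression_result`: `beta`, `intercept`, `r2`,
#'   `p`, `n_points`, `weights`, plus permutation metadata
#' @export
matrix_regression <- function(dy, dx, n_perm = 999L, seed = 1L,
                              tail = c("one", "two"), exhaustive_max = 7L) {
  tail <- match.arg(tail)
  # permute the response labels: prep with d1 = predictor, permuted = dy
  prep <- mantel_prepare(dx, dy)
  obs <- mantel_stat(prep, seq_len(prep$n), stat = "ols")
  if (is.null(obs)) {
    stop("insufficient usable pairs or degenerate predictor", call. = FALSE)
  }
  score <- function(b) if (tail == "one") b else abs(b)
  obs_s <- score(obs$beta)
  exhaustive <- prep$n <= exhaustive_max
  eps <- 1e-12
  count_hits <- function(perms) {
    hits <- 0L; m <- 0L
    for (p in perms) {
      st <- mantel_stat(prep, p, stat = "ols")
      if (is.null(st)) next
      m <- m + 1L
      if (score(st$beta) >= obs_s - eps) hits <- hits + 1L
    }
    c(hits, m)
  }
  if (exhaustive) {
    hm <- count_hits(all_permutations(prep$n))
    p_val <- hm[1] / hm[2]
  } else {
    set.seed(seed)
    perms <- replicate(n_perm, sample.int(prep$n), simplify = FALSE)
    hm <- count_hits(perms)
    p_val <- (1 + hm[1]) / (1 + hm[2])
  }
  structure(list(beta = obs$beta, intercept = obs$intercept, r2 = obs$r2,
                 p = p_val, n_points = obs$n_pairs,
                 weights = "unweighted (matrix pairs)",
                 n_permutations = hm[2], exhaustive = exhaustive,
                 tail = tail, seed = seed),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> beta=%.4f intercept=%.4f r2=%.3f p=%.4g (n=%d, %s)\n",
              x$beta, x$intercept, x$r2, x$p, x$n_points, x$weights))
  invisible(x)
}

#' Per-class summaries of distance matrices
#'
#' Mean, sample standard deviation and pair count of the unmasked
#' off-diagonal pairs of each distance kind in each gene class.
#'
#' @param class_dists named list (one element per class) of named lists of
#'   [pair_dist] objects (e.g. `list(Qa = list(genetic = ..,
#'   expression = .., omega = ..))`)
#' @return data.frame: `class`, `kind`, `mean`, `sd` (NA when n < 2), `n`
#' @export
class_summary <- function(class_dists) {
  rows <- list()
  for (cls in names(class_dists)) {
    for (kind in names(class_dists[[cls]])) {
      d <- class_dists[[cls]][[kind]]
      if (is.null(d)) next
      v <- dist_pairs(d)$value
      if (!length(v)) {
        warning("class ", cls, " kind ", kind, " has no usable pairs; skipped")
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        class = cls, kind = kind, mean = mean(v),
        sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
        n = length(v), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(class = character(), kind = character(),
                                       mean = numeric(), sd = numeric(),
                                       n = integer()))
  do.call(rbind, rows)
}

#' Weighted least-squares regression of class means
#'
#' Fits `y ~ x` with per-class weights (the number of usable pairs behind
#' each class mean), via `stats::lm`. The p-value is the two-sided t-test
#' on the slope with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of class means
#' @param w positive weights (class sample sizes)
#' @return a `regression_result`
#' @export
weighted_lm <- function(x, y, w = rep(1, length(x))) {
  stopifnot(length(x) == length(y), length(w) == length(x), all(w > 0))
  if (length(x) < 2L) stop("need >= 2 points", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate predictor: zero variance",
                              call. = FALSE)
  fit <- stats::lm(y ~ x, weights = w)
  beta <- unname(stats::coef(fit)["x"])
  res <- stats::residuals(fit)
  n <- length(x)
  yw <- sum(w * y) / sum(w)
  xw <- sum(w * x) / sum(w)
  rss <- sum(w * res^2)
  tss <- sum(w * (y - yw)^2)
  r2 <- 1 - rss / tss
  p <- if (n >= 3L) {
    sxx <- sum(w * (x - xw)^2)
    se <- sqrt(rss / (n - 2L) / sxx)
    if (se == 0) 0 else 2 * stats::pt(-abs(beta / se), df = n - 2L)
  } else NA_real_
  structure(list(beta = beta,
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 r2 = r2, p = p, n_points = n,
                 weights = "class sample sizes (usable pair counts)",
                 n_permutations = NA_integer_, exhaustive = FALSE,
                 tail = "two", seed = NA_integer_),
            class = "regression_result")
}

#' Run the full within- and between-class divergence test suite
#'
#' Per class: Mantel tests of expression distance against genetic distance
#' (sub-functionalization) and against Dn/Ds (neo-functionalization), and a
#' matrix regression of Dn/Ds on genetic distance. Between classes:
#' sample-size-weighted linear models of mean expression distance on mean
#' genetic distance and on mean Dn/Ds.
#'
#' @param class_dists named list per class with elements `genetic`,
#'   `expression`, and optionally `omega` ([pair_dist] objects)
#' @param n_perm,seed,tail passed to [mantel] / [matrix_regression]
#' @return list of class `divergence_report`: `within` (data.frame of test
#'   rows), `summary` (class summary table), `between` (data.frame of
#'   weighted regressions), `skipped` (reasons), `seed`
#' @export
run_divergence_suite <- function(class_dists, n_perm = 999L, seed = 1L,
                                 tail = c("one", "two")) {
  tail <- match.arg(tail)
  if (!length(class_dists)) stop("no classes", call. = FALSE)
  within <- list(); skipped <- list()
  for (cls in names(class_dists)) {
    cd <- class_dists[[cls]]
    tests <- list(
      expression_vs_genetic = function()
        mantel(cd$expression, cd$genetic, n_perm, seed, tail),
      expression_vs_omega = function()
        if (is.null(cd$omega)) NULL else
          mantel(cd$expression, cd$omega, n_perm, seed, tail),
      omega_vs_genetic_regression = function()
        if (is.null(cd$omega)) NULL else
          matrix_regression(cd$omega, cd$genetic, n_perm, seed, tail))
    for (nm in names(tests)) {
      res <- tryCatch(tests[[nm]](), error = function(e) conditionMessage(e))
      if (is.null(res)) next
      if (is.character(res)) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          class = cls, test = nm, reason = res, stringsAsFactors = FALSE)
        next
      }
      stat <- if (inherits(res, "mantel_result")) res$r else res$beta
      within[[length(within) + 1L]] <- data.frame(
        class = cls, test = nm, statistic = stat, p = res$p,
        n_pairs = if (inherits(res, "mantel_result")) res$n_pairs else res$n_points,
        n_permutations = res$n_permutations, exhaustive = res$exhaustive,
        stringsAsFactors = FALSE)
    }
  }
  summary_tab <- class_summary(class_dists)
  between <- list()
  for (pred in c("genetic", "omega")) {
    sx <- summary_tab[summary_tab$kind == pred, ]
    sy <- summary_tab[summary_tab$kind == "expression", ]
    common <- intersect(sx$class, sy$class)
    if (length(common) < 3L) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        class = "(between)", test = paste0("expression_vs_", pred, "_wls"),
        reason = sprintf("only %d classes with usable %s and expression pairs",
                         length(common), pred), stringsAsFactors = FALSE)
      next
    }
    sx <- sx[match(common, sx$class), ]
    sy <- sy[match(common, sy$class), ]
    w <- pmin(sx$n, sy$n)
    res <- tryCatch(weighted_lm(sx$mean, sy$mean, w),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        class = "(between)", test = paste0("expression_vs_", pred, "_wls"),
        reason = res, stringsAsFactors = FALSE)
      next
    }
    between[[length(between) + 1L]] <- data.frame(
      test = paste0("expression_vs_", pred, "_wls"), beta = res$beta,
      intercept = res$intercept, r2 = res$r2, p = res$p,
      n_classes = res$n_points, stringsAsFactors = FALSE)
  }
  structure(list(
    within = if (length(within)) do.call(rbind, within) else NULL,
    summary = summary_tab,
    between = if (length(between)) do.call(rbind, between) else NULL,
    skipped = if (length(skipped)) do.call(rbind, skipped) else NULL,
    n_perm = n_perm, seed = seed, tail = tail),
    class = "divergence_report")
}

#' @export
print.divergence_report <- function(x, ...) {
  cat("<divergence_report>\n")
  if (!is.null(x$within)) { cat("within-class tests:\n"); print(x$within) }
  if (!is.null(x$between)) { cat("between-class regressions:\n"); print(x$between) }
  if (!is.null(x$skipped)) { cat("skipped:\n"); print(x$skipped) }
  invisible(x)
}
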