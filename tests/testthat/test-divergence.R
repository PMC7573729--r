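test_that("mantel of a matrix with itself gives r = 1 and minimal p", {
  d <- random_point_dist(10, seed = 51)
  res <- mantel(d, d, n_perm = 99L, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / (99 + 1))
  expect_false(res$exhaustive)
})

test_that("small-label mantel p equals the exhaustive enumeration oracle", {
  for (seed in 1:4) {
    d1 <- random_point_dist(4, seed = 100 + seed)
    d2 <- random_point_dist(4, seed = 200 + seed)
    d2 <- pair_dist(d2$values, labels = d1$labels)
    res <- mantel(d1, d2, seed = 1)
    expect_true(res$exhaustive)
    expect_equal(res$n_permutations, factorial(4))
    expect_equal(res$p, oracle_mantel_exact(d1$values, d2$values),
                 tolerance = 1e-12)
  }
})

test_that("mantel handles masks by pairwise exclusion, mask follows labels", {
  d1 <- random_point_dist(6, seed = 61)
  v <- random_point_dist(6, seed = 62)$values
  dimnames(v) <- dimnames(d1$values)
  v[1, 2] <- v[2, 1] <- NA
  d2 <- pair_dist(v)
  res <- mantel(d1, d2, seed = 1)
  expect_equal(res$n_pairs, choose(6, 2) - 1L)
  # r must equal the correlation over the unmasked pairs only
  ut <- upper.tri(v)
  ok <- ut & !is.na(v)
  expect_equal(res$r, oracle_pearson(d1$values[ok], v[ok]), tolerance = 1e-12)
})

test_that("mantel p is invariant to common relabeling of both matrices", {
  d1 <- random_point_dist(9, seed = 63)
  d2 <- pair_dist(random_point_dist(9, seed = 64)$values,
                  labels = d1$labels)
  r1 <- mantel(d1, d2, n_perm = 199L, seed = 5)
  perm <- rev(d1$labels)
  r2 <- mantel(dist_reorder(d1, perm), dist_reorder(d2, perm),
               n_perm = 199L, seed = 5)
  expect_equal(r1$r, r2$r, tolerance = 1e-12)
  expect_lt(abs(r1$p - r2$p), 0.1)   # same distribution, fixed-seed draws
  d3 <- random_point_dist(9, seed = 65)
  d3 <- pair_dist(d3$values, labels = paste0("other", 1:9))
  expect_error(mantel(d1, d3), "labels")
})

test_that("matrix regression matches the normal-equations oracle", {
  dx <- random_point_dist(7, seed = 71)
  dy <- pair_dist(2 * dx$values, labels = dx$labels)
  res <- matrix_regression(dy, dx, seed = 1)
  expect_equal(res$beta, 2, tolerance = 1e-10)
  expect_equal(res$r2, 1, tolerance = 1e-10)

  vy <- random_point_dist(7, seed = 72)$values
  dimnames(vy) <- dimnames(dx$values)
  dy2 <- pair_dist(vy)
  res2 <- matrix_regression(dy2, dx, seed = 1)
  ut <- upper.tri(vy)
  ora <- oracle_wls(dx$values[ut], vy[ut], rep(1, sum(ut)))
  expect_equal(res2$beta, ora$beta, tolerance = 1e-10)
  expect_equal(res2$intercept, ora$intercept, tolerance = 1e-10)
  expect_equal(res2$r2, ora$r2, tolerance = 1e-10)

  # joint relabeling leaves the coefficients unchanged
  perm <- rev(dx$labels)
  res3 <- matrix_regression(dist_reorder(dy2, perm), dist_reorder(dx, perm),
                            seed = 1)
  expect_equal(res3$beta, res2$beta, tolerance = 1e-12)
  expect_equal(res3$r2, res2$r2, tolerance = 1e-12)
})

test_that("class summaries report mean, sample sd and pair counts", {
  v <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  v[1, 2] <- v[2, 1] <- 0.1
  v[1, 3] <- v[3, 1] <- 0.3
  mask <- matrix(FALSE, 3, 3); mask[2, 3] <- mask[3, 2] <- TRUE
  d <- pair_dist(v, mask)
  tab <- class_summary(list(q = list(genetic = d)))
  expect_equal(tab$mean, 0.2)
  expect_equal(tab$sd, sd(c(0.1, 0.3)))
  expect_equal(tab$n, 2L)
  # single usable pair: sd undefined
  v2 <- matrix(c(0, 0.5, 0.5, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  tab2 <- class_summary(list(r = list(omega = pair_dist(v2))))
  expect_equal(tab2$mean, 0.5)
  expect_true(is.na(tab2$sd))
  expect_equal(tab2$n, 1L)
})

test_that("weighted least squares matches the normal equations", {
  res <- weighted_lm(c(1, 2, 3), c(1, 2, 3), c(5, 1, 2))
  expect_equal(res$beta, 1, tolerance = 1e-12)
  expect_equal(res$intercept, 0, tolerance = 1e-12)
  expect_equal(res$r2, 1, tolerance = 1e-12)

  x <- c(0.2, 0.5, 0.9, 1.3)
  y <- c(0.15, 0.6, 0.7, 1.4)
  w <- c(1, 1, 4, 2)
  res2 <- weighted_lm(x, y, w)
  ora <- oracle_wls(x, y, w)
  expect_equal(res2$beta, ora$beta, tolerance = 1e-10)
  expect_equal(res2$intercept, ora$intercept, tolerance = 1e-10)
  expect_equal(res2$r2, ora$r2, tolerance = 1e-10)

  # equal weights reduce to OLS
  res3 <- weighted_lm(x, y, rep(2, 4))
  fit <- lm(y ~ x)
  expect_equal(res3$beta, unname(coef(fit)["x"]), tolerance = 1e-12)
  expect_equal(res3$intercept, unname(coef(fit)["(Intercept)"]),
               tolerance = 1e-12)
  expect_error(weighted_lm(c(1, 1), c(1, 2)), "degenerate")
})

test_that("mantel agrees with an independent implementation on clean input", {
  skip_if_not_installed("vegan")
  d1 <- random_point_dist(12, seed = 81)
  d2 <- pair_dist(random_point_dist(12, seed = 82)$values,
                  labels = d1$labels)
  res <- mantel(d1, d2, n_perm = 499L, seed = 3)
  ref <- vegan::mantel(stats::as.dist(d1$values), stats::as.dist(d2$values),
                       permutations = 499)
  expect_equal(res$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(res$p - ref$signif), 0.12)
})

test_that("the divergence suite assembles within/between rows and skips", {
  set.seed(91)
  mk_class <- function(seed) {
    g <- random_point_dist(6, seed = seed)
    e <- pair_dist(random_point_dist(6, seed = seed + 1)$values,
                   labels = g$labels)
    o <- pair_dist(random_point_dist(6, seed = seed + 2)$values,
                   labels = g$labels)
    list(genetic = g, expression = e, omega = o)
  }
  cls <- list(qa = mk_class(911), qb = mk_class(921), r = mk_class(931))
  rep <- run_divergence_suite(cls, n_perm = 99L, seed = 2)
  expect_equal(nrow(rep$within), 9L)
  expect_setequal(unique(rep$within$test),
                  c("expression_vs_genetic", "expression_vs_omega",
                    "omega_vs_genetic_regression"))
  expect_equal(nrow(rep$between), 2L)
  expect_equal(nrow(rep$summary), 9L)

  # a single class cannot support between-class regressions
  rep1 <- run_divergence_suite(cls["qa"], n_perm = 99L, seed = 2)
  expect_null(rep1$between)
  expect_true(any(grepl("classes", rep1$skipped$reason)))
})
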