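test_that("codon filtering drops gapped, ambiguous and stop codons", {
  a <- codon_alignment(c(x = "ATGTTT", y = "ATGTTC"))
  cf <- codon_filter(a, c("x", "y"))
  expect_equal(nrow(cf), 2L)

  b <- codon_alignment(c(x = "ATG---AGA", y = "ATGTTCAGA"))
  cf <- codon_filter(b, c("x", "y"))
  expect_equal(cf$position, c(1L, 3L))
  expect_equal(attr(cf, "excluded")[["gap_or_ambiguous"]], 1L)

  d <- codon_alignment(c(x = "ATGTAAAGA", y = "ATGCAAAGA"))  # TAA = stop
  cf <- codon_filter(d, c("x", "y"))
  expect_equal(cf$position, c(1L, 3L))
  expect_equal(attr(cf, "excluded")[["stop_codon"]], 1L)

  e <- codon_alignment(c(x = "---", y = "ATG"))
  expect_error(codon_filter(e, c("x", "y")), "no comparable codons")
})

test_that("ng86 reproduces hand-enumerated single-codon cases", {
  # TTT vs TTC: Phe/Phe, one synonymous difference; s(TTT) = s(TTC) = 1/3
  r <- ng86("TTT", "TTC")
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$S, 1 / 3)
  expect_equal(r$N, 3 - 1 / 3)
  # TTT vs GTA: two pathways, one blocked by nothing; hand enumeration
  # TTT->GTT(V, nonsyn)->GTA(V, syn) and TTT->TTA(L, nonsyn)->GTA(V, nonsyn)
  r2 <- ng86("TTT", "GTA")
  expect_equal(r2$Sd, 0.5)
  expect_equal(r2$Nd, 1.5)
})

test_that("ng86 site and difference counts match the brute-force oracle", {
  tab <- codon_tables()
  # sites: every sense codon
  for (cd in tab$sense) {
    expect_equal(unname(tab$syn_sites[cd]), oracle_syn_sites(cd),
                 info = cd)
  }
  # differences: a deterministic subsample of codon pairs spanning 0-3
  # differences (the full 61x61 sweep runs in the acceptance suite)
  set.seed(41)
  picks <- cbind(sample(tab$sense, 120, replace = TRUE),
                 sample(tab$sense, 120, replace = TRUE))
  for (i in seq_len(nrow(picks))) {
    got <- c(tab$Sd[picks[i, 1], picks[i, 2]],
             tab$Nd[picks[i, 1], picks[i, 2]])
    expect_equal(got, oracle_sd_nd(picks[i, 1], picks[i, 2]),
                 info = paste(picks[i, ], collapse = "/"))
  }
})

test_that("ng86 is symmetric and preserves the site-count identity", {
  set.seed(42)
  tab <- codon_tables()
  ca <- sample(tab$sense, 40, replace = TRUE)
  cb <- sample(tab$sense, 40, replace = TRUE)
  r1 <- ng86(ca, cb)
  r2 <- ng86(cb, ca)
  expect_equal(r1$Sd, r2$Sd)
  expect_equal(r1$Nd, r2$Nd)
  expect_equal(r1$S, r2$S)
  expect_equal(r1$S + r1$N, 3 * 40, tolerance = 1e-9)
})

test_that("validity classification follows the 0 < omega < 9 filter", {
  r <- ng86("TTT", "TTT")
  expect_false(r$valid)
  expect_equal(r$reason, "identical")
  # purely synonymous divergence in a longer context: omega = 0 rejected
  ctx <- rep("GGG", 10)   # glycine: one synonymous site each, no differences
  r0 <- ng86(c(ctx, "TTT"), c(ctx, "TTC"))
  expect_false(r0$valid)
  expect_equal(r0$reason, "zero-nonsynonymous")
  # purely nonsynonymous divergence: Ds = 0
  rs <- ng86(c(ctx, "AAA"), c(ctx, "GCA"))
  expect_false(rs$valid)
  expect_equal(rs$reason, "zero-synonymous")
  # two lone codons with a synonymous change saturate the JC correction
  expect_equal(ng86("TTT", "TTC")$reason, "saturation")
  expect_error(ng86("TT-", "TTC"), "non-sense codon")
})

test_that("the pairwise table matches per-pair calls and masks invalid pairs", {
  set.seed(43)
  tab <- codon_tables()
  mk <- function(codons) paste(codons, collapse = "")
  base <- sample(tab$sense, 30, replace = TRUE)
  mut <- base
  sw <- sample(30, 8)
  mut[sw] <- sample(tab$sense, 8, replace = TRUE)
  a <- codon_alignment(c(g1 = mk(base), g2 = mk(mut), g3 = mk(base)))
  out <- pairwise_kaks_table(a)
  expect_equal(nrow(out$table), 3L)
  for (k in seq_len(nrow(out$table))) {
    row <- out$table[k, ]
    ref <- ng86(codon_filter(a, c(row$gene_a, row$gene_b)))
    expect_equal(row$omega, ref$omega)
    expect_equal(row$Sd, ref$Sd)
    expect_equal(row$valid, ref$valid)
  }
  # identical pair g1/g3 must be masked
  expect_true(out$omega_dist$mask["g1", "g3"])
  expect_equal(out$table$reason[out$table$gene_a == "g1" &
                                out$table$gene_b == "g3"], "identical")
})

test_that("the omega matrix masks exactly the out-of-range ratios", {
  vals <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  vals[1, 2] <- vals[2, 1] <- 0.5
  vals[1, 3] <- vals[3, 1] <- 9.5
  mask <- matrix(FALSE, 3, 3)
  mask[1, 3] <- mask[3, 1] <- TRUE   # 9.5 fails the < 9 rule
  mask[2, 3] <- mask[3, 2] <- TRUE   # 0 fails the > 0 rule
  d <- pair_dist(vals, mask)
  pairs <- dist_pairs(d)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$value, 0.5)
})
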