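test_that("Yule trees have the right shape and are seed-deterministic", {
  tr <- simulate_family_tree(5, lambda = 1, seed = 101)
  expect_equal(length(tr$tip.label), 5L)
  expect_equal(tr$Nnode, 4L)
  expect_true(all(tr$edge.length > 0))
  tr2 <- simulate_family_tree(5, lambda = 1, seed = 101)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  tr3 <- simulate_family_tree(5, lambda = 1, seed = 102)
  expect_false(identical(ape::write.tree(tr), ape::write.tree(tr3)))
  expect_error(simulate_family_tree(2, 1, seed = 1), "n_tips")
  expect_error(simulate_family_tree(5, -1, seed = 1), "lambda")
})

test_that("Yule root-to-tip depth matches the pure-birth expectation", {
  n <- 6; lambda <- 2
  depths <- vapply(1:800, function(s) {
    tr <- simulate_family_tree(n, lambda, seed = 7000 + s)
    mean(ape::node.depth.edgelength(tr)[seq_len(n)])
  }, numeric(1))
  expected <- sum(1 / (lambda * (2:n)))
  expect_lt(abs(mean(depths) - expected) / expected, 0.1)
})

test_that("codon simulation honours omega and never emits stops", {
  tr <- simulate_family_tree(4, 1, seed = 111)
  tab <- codon_tables()
  aln0 <- simulate_codon_sequences(tr, 60, omega = 0, seed = 112)
  codons_of <- function(s) substring(s, seq(1, nchar(s), 3),
                                     seq(3, nchar(s), 3))
  for (s in aln0$seqs) {
    expect_false(any(tab$aa[codons_of(s)] == "*"))
  }
  # omega = 0: no nonsynonymous substitution is ever accepted, so every
  # tip translates to the same protein (pathway-averaged Nd can still be
  # positive for synonymously-reachable codon pairs such as Leu TTA/CTT)
  prots <- vapply(aln0$seqs, function(s)
    paste(oracle_translate(codons_of(s)), collapse = ""), character(1))
  expect_equal(length(unique(prots)), 1L)
  # same seed, same sequences; different seed differs
  aln0b <- simulate_codon_sequences(tr, 60, omega = 0, seed = 112)
  expect_identical(aln0$seqs, aln0b$seqs)
  expect_error(simulate_codon_sequences(tr, 10, omega = 0, seed = 1),
               ">= 50")
  expect_error(simulate_codon_sequences(tr, 60, omega = 2, seed = 1),
               "\\[0, 1\\]")
})

test_that("neutral simulation is recovered by the NG86 estimator", {
  # two tips separated by ~0.3 substitutions/site, omega = 1
  two <- ape::read.tree(text = "(a:0.15,b:0.15);")
  omegas <- vapply(1:30, function(s) {
    al <- simulate_codon_sequences(two, 500, omega = 1, seed = 9000 + s)
    r <- ng86(codon_filter(al, c("a", "b")))
    r$omega
  }, numeric(1))
  expect_gt(median(omegas, na.rm = TRUE), 0.8)
  expect_lt(median(omegas, na.rm = TRUE), 1.2)
})

test_that("expression simulation has the right dimensions per regime", {
  tr <- simulate_family_tree(6, 1, seed = 121)
  for (reg in c("gradual_bm", "rapid_partition", "neo_burst")) {
    e <- simulate_expression(tr, 12, reg, seed = 122,
                             params = list(burst_edges = 1L))
    expect_equal(dim(e), c(6L, 12L))
    expect_true(all(e > 0))
    expect_equal(dim(attr(e, "log_expr")), c(6L, 12L))
  }
  expect_error(simulate_expression(tr, 2, "gradual_bm", seed = 1), "tissues")
})

test_that("Brownian drift variance scales with patristic distance", {
  two <- ape::read.tree(text = "(a:0.6,b:0.4);")
  sigma2 <- 0.5
  diffs <- unlist(lapply(1:400, function(s) {
    e <- simulate_expression(two, 5, "gradual_bm",
                             params = list(sigma2 = sigma2), seed = 3000 + s)
    lg <- attr(e, "log_expr")
    lg["a", ] - lg["b", ]
  }))
  expect_lt(abs(var(diffs) - sigma2 * 1.0) / (sigma2 * 1.0), 0.1)
})

test_that("rapid partitioning with zero drift depends only on history", {
  # identical topology and partition draws, wildly different branch
  # lengths: with no post-duplication drift the profiles are identical
  tr1 <- ape::read.tree(text = "((a:0.9,b:0.1):0.5,(c:0.01,d:2.0):0.1);")
  tr2 <- ape::read.tree(text = "((a:0.1,b:0.9):0.1,(c:1.5,d:0.2):0.9);")
  e1 <- simulate_expression(tr1, 12, "rapid_partition",
                            params = list(jump = 2, sigma2_post = 0),
                            seed = 131)
  e2 <- simulate_expression(tr2, 12, "rapid_partition",
                            params = list(jump = 2, sigma2_post = 0),
                            seed = 131)
  expect_equal(attr(e1, "log_expr"), attr(e2, "log_expr"))
  # every tip expresses a balanced subset: half up, half down
  lg <- attr(e1, "log_expr")
  expect_true(all(abs(rowSums(lg)) < 1e-9))
  expect_true(all(abs(lg) == 1))
})

test_that("generate_dataset writes a complete, bit-reproducible bundle", {
  cfg <- list(classes = list(qa = list(n_tips = 4, omega = 0.3,
                                       regime = "gradual_bm"),
                             rr = list(n_tips = 4, omega = 0.3,
                                       regime = "rapid_partition")),
              n_codons = 60, n_tissues = 6, seed = 5)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  truth1 <- generate_dataset(cfg, out1)
  truth2 <- generate_dataset(cfg, out2)
  for (f in c("qa_codon.fasta", "qa_protein.fasta", "qa_true_tree.nwk",
              "rr_codon.fasta", "expression.tsv", "truth.json")) {
    expect_true(file.exists(file.path(out1, f)))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
  # translated FASTA equals the codon FASTA translated under the code
  aln <- read_codon_fasta(file.path(out1, "qa_codon.fasta"))
  prot <- read_fasta(file.path(out1, "qa_protein.fasta"), "amino-acid")
  tr_prot <- vapply(aln$seqs, function(s)
    paste(oracle_translate(substring(s, seq(1, nchar(s), 3),
                                     seq(3, nchar(s), 3))), collapse = ""),
    character(1))
  expect_equal(unname(tr_prot), unname(prot$seqs))
  expect_equal(names(truth1$classes), c("qa", "rr"))
  expect_equal(truth1$classes$qa$expected_mantel_sign, "positive")
})
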