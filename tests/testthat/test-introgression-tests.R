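# D-statistic, block jackknife, HyDe-style test, relative rate test

test_that("D-statistic arithmetic and domain", {
  expect_equal(d_statistic(c(n_abba = 100, n_baba = 100)), 0)
  expect_equal(d_statistic(c(n_abba = 1, n_baba = 0)), 1)
  expect_error(d_statistic(c(n_abba = 0, n_baba = 0)), "undefined")
  bc <- fake_blocks(c(30, 10), c(10, 10), c(50, 50))
  expect_equal(d_statistic(bc), (40 - 20) / 60)
})

test_that("identical blocks give zero jackknife SE", {
  bc <- fake_blocks(rep(20, 10), rep(10, 10), rep(40, 10))
  jk <- block_jackknife(bc, d_statistic)
  expect_equal(jk$se, 0)
  expect_equal(jk$estimate, 1 / 3)
})

test_that("two-block jackknife SE matches the hand-computed formula", {
  bc <- fake_blocks(c(30, 10), c(10, 30), c(0, 0))
  jk <- block_jackknife(bc, d_statistic)
  # leave-one-out estimates: drop block1 -> (10-30)/40 = -0.5; drop
  # block2 -> +0.5; SE^2 = (1/2) * ((0.5)^2 + (0.5)^2) = 0.25
  expect_equal(sort(jk$loo), c(-0.5, 0.5))
  expect_equal(jk$se, 0.5)
})

test_that("degenerate leave-one-out subsets are flagged and dropped", {
  # dropping block 3 removes all ABBA+BABA counts -> statistic undefined
  bc <- fake_blocks(c(0, 0, 5), c(0, 0, 3), c(9, 9, 9))
  expect_warning(jk <- block_jackknife(bc, d_statistic), "undefined")
  expect_equal(jk$n_blocks, 2L)
  bc2 <- fake_blocks(c(0, 5), c(0, 3), c(9, 9))
  expect_warning(expect_error(block_jackknife(bc2, d_statistic),
                              "fewer than two"))
})

test_that("symmetric counts are not significant; skew drives the z-test", {
  set.seed(1)
  n <- stats::rpois(100, 50)
  bc <- fake_blocks(n, n, n + 5)
  dt <- d_test(bc)
  expect_equal(dt$z, 0)
  expect_false(dt$significant)
  expect_true(is.na(dt$inferred_pair))
  skew <- fake_blocks(n + 25, n, n)
  dts <- d_test(skew)
  expect_true(dts$significant)
  expect_equal(dts$inferred_pair, "P2-P3")
  neg <- fake_blocks(n, n + 25, n)
  dtn <- d_test(neg)
  expect_true(dtn$significant)
  expect_equal(dtn$inferred_pair, "P1-P3")
})

test_that("zero-SE corner cases are handled explicitly", {
  bc <- fake_blocks(rep(10, 5), rep(4, 5), rep(9, 5))
  expect_warning(dt <- d_test(bc), "SE is zero")
  expect_equal(dt$p, 0)
  expect_true(dt$significant)
  bal <- fake_blocks(rep(7, 5), rep(7, 5), rep(9, 5))
  dt2 <- d_test(bal)
  expect_false(dt2$significant)
  expect_equal(dt2$p, 1)
})

test_that("HyDe-style test targets the two least frequent patterns", {
  set.seed(2)
  n <- stats::rpois(80, 60)
  even <- fake_blocks(n, n + stats::rpois(80, 1) - stats::rpois(80, 1),
                      n + 100)
  expect_false(hyde_jk_test(even)$significant)
  # BABA clearly smallest -> parents P1,P3; hybrid P2
  hy <- hyde_jk_test(fake_blocks(n + 40, n, n + 200))
  expect_true(hy$significant)
  expect_equal(hy$smallest, "baba")
  expect_equal(hy$hybrid, "P2")
  expect_equal(hy$assignment, "P1-P2-P3")
  # ABBA smallest -> hybrid P1
  hy2 <- hyde_jk_test(fake_blocks(n, n + 40, n + 200))
  expect_equal(hy2$hybrid, "P1")
  expect_equal(hy2$assignment, "P2-P1-P3")
  # BBAA smallest -> hybrid P3 (outgroup-misrooting regime)
  hy3 <- hyde_jk_test(fake_blocks(n + 200, n + 40, n))
  expect_equal(hy3$hybrid, "P3")
  expect_error(hyde_jk_test(fake_blocks(c(0, 0), c(1, 1), c(2, 2))),
               "positive")
})

test_that("JC69 distance follows the closed form and its domain", {
  s <- strrep("ACGT", 2500)
  expect_equal(jc69_distance(s, s), 0)
  # 3% raw divergence over 10000 sites
  x <- rep("A", 10000); y <- x; y[seq_len(300)] <- "C"
  expect_equal(jc69_distance(paste(x, collapse = ""),
                             paste(y, collapse = "")),
               -0.75 * log(1 - 4 * 0.03 / 3))
  expect_equal(jc69_distance(paste(x, collapse = ""),
                             paste(y, collapse = "")),
               jc69_distance(paste(y, collapse = ""),
                             paste(x, collapse = "")))
  z <- rep("C", 10000)
  expect_error(jc69_distance(paste(x, collapse = ""),
                             paste(z, collapse = "")), "saturation")
})

test_that("relative rate arithmetic on supplied distances", {
  rr <- relative_rate_from_distances(0.03, 0.02, 0.01)
  expect_equal(rr$a, 0.02)
  expect_equal(rr$b, 0.01)
  expect_equal(rr$rate_difference, 0.5)
  expect_equal(relative_rate_from_distances(0, 0, 0)$rate_difference, 0)
  expect_warning(relative_rate_from_distances(0.01, 0.05, 0.001), "clamped")
})

test_that("identical ingroup sequences give zero rate difference", {
  set.seed(3)
  o <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  s <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  rr <- relative_rate_test(s, s, o)
  expect_equal(rr$rate_difference, 0)
  expect_equal(rr$z, 0)
})

test_that("relative rate test recovers a 1.5x rate ratio from sequence data", {
  # low-ILS triplet: 2N tiny relative to T_S so tip branches dominate
  sc <- scenario_config(T_S = 1e5, T_I = 1e5, T_O = 1e5, two_N = 200,
                        lambda_p1 = 1.5, genome_size_bp = 1e6)
  fa <- tempfile(fileext = ".fa")
  sim_dataset(sc, seed = 8, emit_fasta = fa)
  aln <- as.character(read_alignment_fasta(fa))
  rr <- relative_rate_test(aln[["P1"]], aln[["P2"]], aln[["O"]])
  # expected rate difference 1 - 1/1.5; sampling noise of the distance
  # difference gives SE(rate_difference) ~ 0.033 at 1e6 sites
  expect_lt(abs(rr$rate_difference - (1 - 1 / 1.5)), 0.1)
  expect_gt(rr$a, rr$b)
  expect_lt(rr$p, 0.01)  # strong clock violation is detected
})
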