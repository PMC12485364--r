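# Coalescent + JC69 simulator: genealogies, rate scaling, sequences, counts

test_that("topology discordance matches the coalescent closed form", {
  sc <- cell_scenario(T = 1e5, two_N = 1e5, genome_mb = 10)  # T_I/2N = 1
  set.seed(99)
  L <- 1e5
  tr <- homoplasyD:::.sim_gene_trees(sc, L)
  # tip-set bitmasks of each node (tips 1..4 -> bits 1,2,4,8)
  cmask <- function(child, m5, m6)
    ifelse(child <= 4L, bitwShiftL(1L, child - 1L),
           ifelse(child == 5L, m5, m6))
  m5 <- cmask(tr$ev_c1[, 1], 0L, 0L) + cmask(tr$ev_c2[, 1], 0L, 0L)
  m6 <- cmask(tr$ev_c1[, 2], m5, 0L) + cmask(tr$ev_c2[, 2], m5, 0L)
  # the P1,P2,P3 triplet topology: at the first event joining two lineages
  # that both contain ingroup tips, concordance means the union restricted
  # to {P1,P2} is complete and P3 is absent
  conc <- rep(NA, L)
  for (k in 1:2) {
    c1 <- cmask(tr$ev_c1[, k], m5, m6); c2 <- cmask(tr$ev_c2[, k], m5, m6)
    rel <- is.na(conc) & bitwAnd(c1, 7L) > 0L & bitwAnd(c2, 7L) > 0L
    conc[rel] <- bitwAnd(bitwOr(c1, c2), 7L)[rel] == 3L
  }
  # the first two events always suffice: an event not joining two
  # ingroup-bearing lineages can only pair one ingroup tip with O, after
  # which every remaining pair is ingroup-bearing
  expect_false(anyNA(conc))
  disc <- mean(!conc)
  exp_disc <- (2 / 3) * exp(-sc$T_I / sc$two_N)
  se <- sqrt(exp_disc * (1 - exp_disc) / L)
  expect_lt(abs(disc - exp_disc), 3 * se)
})

test_that("without introgression the P3 lineage never enters P1's population", {
  sc <- cell_scenario(T = 5e4, two_N = 5e4, gamma = 0)
  for (s in 1:20) {
    gt <- sim_gene_tree(sc, seed = s)
    expect_false(gt$jumped)
    expect_false("P1" %in% gt$segments$P3$pop)
  }
})

test_that("a long internal branch forces concordance", {
  sc <- scenario_config(T_S = 1e4, T_I = 1e6, T_O = 1e4, two_N = 1e4)
  set.seed(5)
  tr <- homoplasyD:::.sim_gene_trees(sc, 2000L)
  ab_first <- (tr$ev_c1[, 1] == 1L & tr$ev_c2[, 1] == 2L) |
    (tr$ev_c1[, 1] == 2L & tr$ev_c2[, 1] == 1L)
  expect_gt(mean(ab_first), 0.999)
})

test_that("segment-based rate scaling is linear in per-population residence", {
  sc <- cell_scenario(T = 1e5, two_N = 1e4, lambda_p1 = 2, gamma = 0.1,
                      T_G = 4e4)
  # hand-built tree: P3 jumped, spending T_G in P3's population then
  # (t - T_G) in P1's population
  gt <- structure(list(
    segments = list(P3 = data.frame(pop = c("P3", "P1"),
                                    from = c(0, 4e4), to = c(4e4, 1e5))),
    scenario = sc), class = "gene_tree")
  len <- scale_to_mutation_lengths(gt)
  expect_equal(unname(len["P3"]), sc$mu * (4e4 + 2 * (1e5 - 4e4)))
  # unknown population label rejected
  gt$segments$P3$pop <- c("P3", "Q9")
  expect_error(scale_to_mutation_lengths(gt), "unknown population")
})

test_that("segment scaling agrees with the engine's branch lengths", {
  scs <- list(cell_scenario(T = 1e5, two_N = 1e4, lambda_p1 = 1.5,
                            lambda_p3 = 0.5, lambda_o = 2),
              cell_scenario(T = 5e4, two_N = 1e4, gamma = 0.6,
                            T_G = 0.95 * 5e4, lambda_p1 = 1.3))
  for (sc in scs) {
    for (s in 1:25) {
      gt <- sim_gene_tree(sc, seed = s)
      expect_equal(unname(scale_to_mutation_lengths(gt)), unname(gt$blen),
                   tolerance = 1e-12)
    }
  }
})

test_that("all-unit rates give branch length = duration * mu", {
  sc <- cell_scenario(T = 1e5, two_N = 1e4)
  gt <- sim_gene_tree(sc, seed = 2)
  dur <- vapply(gt$segments, function(sg) sum(sg$to - sg$from), numeric(1))
  expect_equal(unname(gt$blen), unname(dur * sc$mu), tolerance = 1e-12)
})

test_that("zero branch lengths yield four identical sequences", {
  sc <- cell_scenario(T = 1e5, two_N = 1e4)
  gt <- sim_gene_tree(sc, seed = 4)
  aln <- sim_locus_alignment(gt, locus_length = 200,
                             blen = setNames(rep(0, 6), names(gt$blen)))
  expect_equal(nrow(unique(aln)), 1L)
  expect_error(sim_locus_alignment(gt, blen = c(-1, 0, 0, 0, 0, 0)),
               "negative")
})

test_that("a saturated branch decouples its taxon (JC69 limit)", {
  sc <- cell_scenario(T = 1e5, two_N = 1e4)
  gt <- sim_gene_tree(sc, seed = 4)
  bl <- setNames(rep(0, 6), names(gt$blen))
  bl["O"] <- 50  # effectively infinite
  set.seed(1)
  aln <- sim_locus_alignment(gt, locus_length = 20000, blen = bl)
  match_rate <- mean(aln["O", ] == aln["P1", ])
  expect_lt(abs(match_rate - 0.25), 3 * sqrt(0.25 * 0.75 / 20000))
})

test_that("fixed-tree site simulation matches the analytic JC69 pattern probabilities", {
  # caterpillar ((P1,P2),P3),O with chosen mutation lengths
  blen <- c(t1 = 0.02, t2 = 0.01, t3 = 0.03, t4 = 0.06, n5 = 0.015,
            n6 = 0.01)
  want <- jc69_site_pattern_prob(c(1, 2), c(5, 3), blen)
  sc <- cell_scenario(T = 1e5, two_N = 1e4)
  gt <- sim_gene_tree(sc, seed = 9)
  # force the matching topology: P1,P2 join node5, node5+P3 join node6
  gt$par <- c(5L, 5L, 6L, 7L, 6L, 7L)
  bl <- setNames(c(0.02, 0.01, 0.03, 0.06, 0.015, 0.01), names(gt$blen))
  set.seed(21)
  n <- 4e5
  aln <- sim_locus_alignment(gt, locus_length = n, blen = bl)
  lab <- classify_sites(apply(aln, 1, paste, collapse = ""))
  for (nm in c("abba", "baba", "bbaa")) {
    obs <- mean(lab == toupper(nm))
    se <- sqrt(want[[nm]] * (1 - want[[nm]]) / n)
    expect_lt(abs(obs - want[[nm]]), 3 * se)
  }
})

test_that("simulated genome-wide frequencies match the exact theory", {
  # parameter sets spanning the depth/population-size surface, including
  # rate deceleration and introgression
  cells <- list(
    cell_scenario(T = 5e4, two_N = 2.5e4, lambda_p1 = 1.5, genome_mb = 10),
    cell_scenario(T = 1.5e5, two_N = 2.5e4, lambda_p1 = 1.5, genome_mb = 10),
    cell_scenario(T = 1e5, two_N = 5e3, lambda_p1 = 1.5, genome_mb = 10),
    cell_scenario(T = 1e5, two_N = 1e4, lambda_p1 = 0.67, genome_mb = 10),
    cell_scenario(T = 1e5, two_N = 1e4, gamma = 0.05, T_G = 9.5e4,
                  genome_mb = 10))
  for (i in seq_along(cells)) {
    sc <- cells[[i]]
    bc <- sim_dataset(sc, seed = 1000 + i)
    tot <- totals3(bc)
    n <- attr(bc, "total_sites")
    pf <- pattern_freqs(scenario_params(sc))
    want <- c(pf$p_abba, pf$p_baba, pf$p_bbaa)
    se <- sqrt(want * (1 - want) / n)
    expect_true(all(abs(tot / n - want) < 3 * se))
  }
})

test_that("clock simulation balances ABBA and BABA", {
  sc <- cell_scenario(T = 1e5, two_N = 1e4, genome_mb = 10)
  tot <- totals3(sim_dataset(sc, seed = 31))
  expect_lt(abs(tot[1] - tot[2]) / sqrt(tot[1] + tot[2]), 3)
})

test_that("datasets are reproducible from their seed", {
  sc <- cell_scenario(T = 1e5, two_N = 1e4, lambda_p1 = 1.5, genome_mb = 1)
  a <- sim_dataset(sc, seed = 77)
  b <- sim_dataset(sc, seed = 77)
  expect_identical(a, b)
})

test_that("fast counting equals recounting the emitted FASTA", {
  sc <- cell_scenario(T = 1e5, two_N = 1e4, lambda_p1 = 1.5, genome_mb = 1)
  fa <- tempfile(fileext = ".fa")
  bc <- sim_dataset(sc, seed = 123, n_blocks = 50, emit_fasta = fa)
  rc <- count_patterns(read_alignment_fasta(fa), outgroup = "O",
                       n_blocks = 50)
  expect_equal(bc$n_abba, rc$n_abba)
  expect_equal(bc$n_baba, rc$n_baba)
  expect_equal(bc$n_bbaa, rc$n_bbaa)
  # and counts do not depend on whether FASTA was emitted
  bc2 <- sim_dataset(sc, seed = 123, n_blocks = 50)
  expect_equal(bc$n_abba, bc2$n_abba)
})

test_that("locus length does not change expected counts at fixed genome size", {
  sc100 <- cell_scenario(T = 1e5, two_N = 1e4, lambda_p1 = 1.5,
                         genome_mb = 8, locus_length_bp = 100)
  sc1k <- cell_scenario(T = 1e5, two_N = 1e4, lambda_p1 = 1.5,
                        genome_mb = 8, locus_length_bp = 1000)
  t1 <- totals3(sim_dataset(sc100, seed = 5))
  t2 <- totals3(sim_dataset(sc1k, seed = 6))
  z <- abs(t1 - t2) / sqrt(t1 + t2)
  expect_true(all(z < 3))
})

test_that("the sampling-time-shift transform matches the quoted construction", {
  sc <- cell_scenario(T = 1e5, two_N = 1e4, lambda_p1 = 1.5)
  ts <- time_shift_transform(sc)
  expect_equal(ts$T_S, 1.5e5)
  expect_equal(ts$sample_times, c(0, 5e4, 5e4, 5e4))
  expect_equal(ts$lambda_p1, 1)
  # identity when no rate variation
  sc1 <- cell_scenario(T = 1e5, two_N = 1e4)
  expect_identical(time_shift_transform(sc1), sc1)
  # unsupported cases
  expect_error(time_shift_transform(
    cell_scenario(T = 1e5, two_N = 1e4, lambda_p1 = 1.5, lambda_o = 2)),
    "single")
  expect_error(time_shift_transform(
    cell_scenario(T = 1e5, two_N = 1e4, gamma = 0.05, T_G = 1e4)), "gamma")
})

test_that("time-shifted and rate-scaled simulations agree in expectation", {
  sc <- cell_scenario(T = 1e5, two_N = 1e4, lambda_p1 = 1.5, genome_mb = 20)
  ts <- time_shift_transform(sc)
  t1 <- totals3(sim_dataset(sc, seed = 41))
  t2 <- totals3(sim_dataset(ts, seed = 42))
  z <- abs(t1 - t2) / sqrt(t1 + t2)
  expect_true(all(z < 3))
})
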