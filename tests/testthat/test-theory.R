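# Expected site-pattern frequencies and D under MSci + JC69

test_that("generation-to-mutation unit conversion follows tau = T*mu, theta = 2*(2N)*mu", {
  gp <- generation_params(1e5, 1e5, 1e5, 1e4, mu = 2e-8)
  p <- to_mutation_units(gp)
  expect_equal(p$tau1, 2e-3)
  expect_equal(p$tau2, 4e-3)
  expect_equal(p$tau3, 6e-3)
  expect_equal(p$theta, 4e-4)
  gpg <- generation_params(1e5, 1e5, 1e5, 1e4, mu = 2e-8, T_G = 0.95e5)
  expect_equal(to_mutation_units(gpg, gamma = 0.05)$tau_g, 1.9e-3)
  expect_error(generation_params(1e5, 1e5, 1e5, 1e4, mu = 0), "mu")
  expect_error(generation_params(-1, 1e5, 1e5, 1e4), "> 0")
  expect_error(to_mutation_units(gp, lambda = c(1, -1, 1)), "positive")
})

test_that("parameter validation enforces the model's domain", {
  expect_error(msci_params(2e-3, 1e-3, 3e-3, 1e-3), "tau2")
  expect_error(msci_params(1e-3, 2e-3, 3e-3, 0), "theta")
  expect_error(msci_params(1e-3, 2e-3, 3e-3, 1e-3, gamma = 1.2), "gamma")
  expect_error(msci_params(1e-3, 2e-3, 3e-3, 1e-3, gamma = 0.1,
                           tau_g = 2e-3), "tau_g")
  expect_error(msci_params(1e-3, 2e-3, 3e-3, 1e-3, lambda_p1 = 0), "rate")
})

test_that("closed-form ABBA-BABA difference vanishes in the clock / equal-outgroup limits", {
  expect_identical(abba_baba_diff_eq1(tau_family(1e-3, 1e-3, 1)), 0)
  p <- msci_params(1e-3, 2e-3, 2e-3, 1e-3, lambda_p1 = 1.7)
  expect_identical(abba_baba_diff_eq1(p), 0)
  expect_error(abba_baba_diff_eq1(
    msci_params(1e-3, 2e-3, 3e-3, 1e-3, gamma = 0.1, tau_g = 5e-4)),
    "gamma")
  expect_error(abba_baba_diff_eq1(
    msci_params(1e-3, 2e-3, 3e-3, 1e-3, lambda_p3 = 2)), "unit rates")
})

test_that("numeric pattern frequencies match the closed-form difference", {
  p <- tau_family(1e-3, 1e-3, 1.5)
  pf <- pattern_freqs(msci_params(1e-3, 2e-3, 3e-3, 1e-3, lambda_p1 = 1.5))
  expect_lt(abs((pf$p_abba - pf$p_baba) - abba_baba_diff_eq1(p)), 1e-10)
  for (q in random_params(25, seed = 42)) {
    pf <- pattern_freqs(q)
    expect_lt(abs((pf$p_abba - pf$p_baba) - abba_baba_diff_eq1(q)), 1e-8)
  }
})

test_that("pattern orderings follow the sign of the P1 rate multiplier", {
  # lambda = 1: exact ABBA = BABA symmetry, BBAA dominant
  pf <- pattern_freqs(tau_family(1e-3, 1e-3, 1))
  expect_lt(abs(pf$p_abba - pf$p_baba), 1e-12)
  expect_gt(pf$p_bbaa, pf$p_baba)
  for (q in random_params(8, seed = 7, lambda_range = c(1.1, 3))) {
    pf <- pattern_freqs(q)
    expect_gt(min(pf$p_bbaa, pf$p_abba), pf$p_baba)  # lambda > 1
  }
  for (q in random_params(8, seed = 8, lambda_range = c(0.3, 0.9))) {
    pf <- pattern_freqs(q)
    expect_gt(pf$p_bbaa, pf$p_baba)                  # lambda < 1
    expect_gt(pf$p_baba, pf$p_abba)
  }
})

test_that("frequencies are proper probabilities", {
  for (q in random_params(6, seed = 11)) {
    pf <- pattern_freqs(q)
    expect_true(all(unlist(pf) >= 0))
    expect_lt(pf$p_abba + pf$p_baba + pf$p_bbaa, 1)
  }
})

test_that("expected D reproduces the depth-curve anchors", {
  expect_equal(round(expected_D(tau_family(1e-3, 1e-3, 1.5)), 3), 0.006)
  expect_equal(round(expected_D(tau_family(3e-3, 1e-3, 1.5)), 3), 0.055)
  expect_equal(round(expected_D(tau_family(1e-2, 1e-3, 1.5)), 3), 0.063)
  expect_equal(expected_D(tau_family(2e-3, 1e-3, 1)), 0, tolerance = 1e-9)
})

test_that("expected D increases with outgroup distance tau3 - tau2", {
  ds <- vapply(c(1e-3, 3e-3, 6e-3, 1e-2), function(gap)
    expected_D(msci_params(1e-3, 2e-3, 2e-3 + gap, 1e-3, lambda_p1 = 1.5)),
    numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("root-finding recovers the depth needed for D = 0.05", {
  expect_equal(tau_for_target_D(1e-3, 1.5, 0.05), 2.4e-3, tolerance = 0.02)
  expect_equal(tau_for_target_D(2e-4, 1.5, 0.05), 5.8e-4, tolerance = 0.02)
  expect_error(tau_for_target_D(1e-3, 1, 0), "degenerate")
  expect_error(tau_for_target_D(1e-3, 1.01, 0.5), "sign")
})

test_that("D approaches 1 in the long-P1/long-O, small-theta limit", {
  expect_gt(expected_D(msci_params(1e-6, 2e-6, 10, 1e-8, lambda_p1 = 1e4)),
            0.99)
  taus <- c(3e-3, 1e-3, 3e-4, 1e-4)  # tau1 -> 0 with lambda*tau1 fixed
  seq_ps <- lapply(taus, function(tau)
    msci_params(tau, 2 * tau, 8, 1e-6, lambda_p1 = 3 / tau))
  d <- limit_D(seq_ps)
  path <- attr(d, "path")
  expect_true(all(diff(path) > -1e-3))
  expect_equal(as.numeric(d), 1, tolerance = 1e-3)
  expect_equal(expected_D(msci_params(1e-4, 2e-4, 8, 1e-6)), 0,
               tolerance = 1e-9)
})

test_that("introgression with clock rates drives D negative", {
  tau <- 1e-3
  p <- msci_params(tau, 2 * tau, 3 * tau, 1e-3, gamma = 0.05,
                   tau_g = 0.95 * tau)
  expect_lt(expected_D(p), 0)
})
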