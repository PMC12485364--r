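# shared fixtures: small scenario cells and count helpers

totals3 <- function(bc) colSums(bc[, c("n_abba", "n_baba", "n_bbaa")])

# the depth family used in the theory analyses
tau_family <- function(tau, theta, lambda_p1 = 1, ...) {
  msci_params(tau1 = tau, tau2 = 2 * tau, tau3 = 3 * tau, theta = theta,
              lambda_p1 = lambda_p1, ...)
}

# simulation cell with all branches equal to T generations
cell_scenario <- function(T = 1e5, two_N = 1e4, lambda_p1 = 1,
                          lambda_p3 = 1, lambda_o = 1, gamma = 0, T_G = 0,
                          genome_mb = 1, seed = 1, n_replicates = 5,
                          locus_length_bp = 100) {
  scenario_config(T_S = T, T_I = T, T_O = T, two_N = two_N,
                  lambda_p1 = lambda_p1, lambda_p3 = lambda_p3,
                  lambda_o = lambda_o, gamma = gamma, T_G = T_G,
                  genome_size_bp = genome_mb * 1e6,
                  locus_length_bp = locus_length_bp,
                  n_replicates = n_replicates, seed = seed)
}

# fabricated block-counts table
fake_blocks <- function(abba, baba, bbaa) {
  B <- length(abba)
  out <- data.frame(block_id = seq_len(B), start_bp = 0, end_bp = 0,
                    n_abba = abba, n_baba = baba, n_bbaa = bbaa)
  class(out) <- c("block_counts", "data.frame")
  out
}

# random valid no-introgression parameter draws for property sweeps
random_params <- function(n, seed, lambda_range = c(0.5, 2)) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    tau1 <- stats::runif(1, 2e-4, 5e-3)
    tau2 <- tau1 * stats::runif(1, 1.2, 3)
    tau3 <- tau2 * stats::runif(1, 1.2, 3)
    theta <- stats::runif(1, 2e-4, 3e-3)
    lam <- stats::runif(1, lambda_range[1], lambda_range[2])
    msci_params(tau1, tau2, tau3, theta, lambda_p1 = lam)
  })
}
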