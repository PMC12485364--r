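#' Parameter set for the four-taxon MSci model with lineage rate multipliers
#'
#' Container for the multispecies-coalescent-with-introgression (MSci) model
#' on the asymmetric species tree (((P1,P2),P3),O), with Jukes-Cantor (JC69)
#' mutation and per-lineage relative substitution rates. All times are
#' measured in expected mutations per site at the reference rate
#' (tau = T * mu), and the population size as theta = 4*N*mu.
#'
#' @param tau1,tau2,tau3 Divergence times of (P1,P2), ((P1,P2),P3) and the
#'   root, in expected mutations per site. Must satisfy
#'   0 < tau1 < tau2 <= tau3 (equality of tau2 and tau3 is allowed as the
#'   degenerate zero-length outgroup stem).
#' @param theta Scaled population size 4*N*mu, assumed equal across all
#'   populations (terminal-branch rate multipliers rescale the mutational
#'   size of a terminal population but not its genealogical dynamics).
#' @param gamma Introgression proportion in [0,1]: the probability that the
#'   P3 lineage traces back through P1's population at time \code{tau_g}.
#' @param tau_g Introgression time (mutation units); required to satisfy
#'   0 <= tau_g < tau1 whenever \code{gamma > 0}.
#' @param lambda_p1,lambda_p3,lambda_o Relative substitution-rate
#'   multipliers (> 0) of the terminal lineages P1, P3 and O. The reference
#'   rate 1 applies on P2 and on all ancestral branches.
#'
#' @return An object of class \code{"msci_params"} (a validated list).
#' @seealso [pattern_freqs()], [expected_D()], [to_mutation_units()]
#' @export
msci_params <- function(tau1, tau2, tau3, theta, gamma = 0, tau_g = 0,
                        lambda_p1 = 1, lambda_p3 = 1, lambda_o = 1) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    as.numeric(x)
  }
  tau1 <- num1(tau1, "tau1"); tau2 <- num1(tau2, "tau2")
  tau3 <- num1(tau3, "tau3"); theta <- num1(theta, "theta")
  gamma <- num1(gamma, "gamma"); tau_g <- num1(tau_g, "tau_g")
  lambda_p1 <- num1(lambda_p1, "lambda_p1")
  lambda_p3 <- num1(lambda_p3, "lambda_p3")
  lambda_o <- num1(lambda_o, "lambda_o")
  if (tau1 <= 0) stop("tau1 must be > 0", call. = FALSE)
  if (tau2 <= tau1) stop("tau2 must exceed tau1", call. = FALSE)
  if (tau3 < tau2) stop("tau3 must be >= tau2", call. = FALSE)
  if (theta <= 0) stop("theta must be > 0", call. = FALSE)
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0,1]", call. = FALSE)
  if (gamma > 0 && (tau_g < 0 || tau_g >= tau1))
    stop("tau_g must satisfy 0 <= tau_g < tau1 when gamma > 0", call. = FALSE)
  if (min(lambda_p1, lambda_p3, lambda_o) <= 0)
    stop("rate multipliers must be > 0", call. = FALSE)
  structure(list(tau1 = tau1, tau2 = tau2, tau3 = tau3, theta = theta,
                 gamma = gamma, tau_g = tau_g,
                 lambda_p1 = lambda_p1, lambda_p3 = lambda_p3,
                 lambda_o = lambda_o),
            class = "msci_params")
}

#' @export
print.msci_params <- function(x, ...) {
  cat("MSci parameters (mutation units):\n")
  cat(sprintf("  tau1 = %g, tau2 = %g, tau3 = %g, theta = %g\n",
              x$tau1, x$tau2, x$tau3, x$theta))
  cat(sprintf("  gamma = %g (tau_g = %g)\n", x$gamma, x$tau_g))
  cat(sprintf("  lambda: P1 = %g, P3 = %g, O = %g\n",
              x$lambda_p1, x$lambda_p3, x$lambda_o))
  invisible(x)
}

#' Branch lengths and demography in generation units
#'
#' Generation-unit companion of [msci_params()], following the conventions
#' of the simulation scenarios: \code{T_S} is the divergence time of the
#' sister lineages P1 and P2, \code{T_I} the internal branch length,
#' \code{T_O} the outgroup stem length and \code{T_G} the introgression
#' time, all in generations. \code{two_N} is the population size quoted as
#' 2N, interpreted throughout as the number of haploid gene copies, so the
#' pairwise coalescent rate is 1/(2N) per generation and
#' theta = 2 * (2N) * mu.
#'
#' @param T_S,T_I,T_O Branch lengths in generations (all > 0).
#' @param two_N Population size as 2N (number of gene copies).
#' @param mu Mutation rate per site per generation.
#' @param T_G Introgression time in generations (0 disables; must be
#'   < \code{T_S} otherwise).
#' @return An object of class \code{"generation_params"}.
#' @export
generation_params <- function(T_S, T_I, T_O, two_N, mu = 2e-8, T_G = 0) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
    as.numeric(x)
  }
  T_S <- num1(T_S, "T_S"); T_I <- num1(T_I, "T_I"); T_O <- num1(T_O, "T_O")
  two_N <- num1(two_N, "two_N"); mu <- num1(mu, "mu"); T_G <- num1(T_G, "T_G")
  if (min(T_S, T_I, T_O, two_N) <= 0)
    stop("branch lengths and 2N must be > 0", call. = FALSE)
  if (mu <= 0) stop("mu must be > 0", call. = FALSE)
  if (T_G < 0 || (T_G > 0 && T_G >= T_S))
    stop("T_G must satisfy 0 <= T_G < T_S", call. = FALSE)
  structure(list(T_S = T_S, T_I = T_I, T_O = T_O, two_N = two_N,
                 mu = mu, T_G = T_G),
            class = "generation_params")
}

#' Convert generation-unit parameters to mutation units
#'
#' Applies tau = T * mu and theta = 4*N*mu = 2 * (2N) * mu to a
#' [generation_params()] object, attaching rate multipliers and the
#' introgression proportion.
#'
#' @param gp A [generation_params()] object.
#' @param lambda Numeric length-3 vector of rate multipliers for
#'   (P1, P3, O).
#' @param gamma Introgression proportion.
#' @return An [msci_params()] object.
#' @export
to_mutation_units <- function(gp, lambda = c(1, 1, 1), gamma = 0) {
  stopifnot(inherits(gp, "generation_params"))
  if (length(lambda) != 3L || any(!is.finite(lambda)) || any(lambda <= 0))
    stop("lambda must be three positive rate multipliers (P1, P3, O)",
         call. = FALSE)
  msci_params(tau1 = gp$T_S * gp$mu,
              tau2 = (gp$T_S + gp$T_I) * gp$mu,
              tau3 = (gp$T_S + gp$T_I + gp$T_O) * gp$mu,
              theta = 2 * gp$two_N * gp$mu,
              gamma = gamma,
              tau_g = gp$T_G * gp$mu,
              lambda_p1 = lambda[1], lambda_p3 = lambda[2],
              lambda_o = lambda[3])
}
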