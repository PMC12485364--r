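#' Simulation scenario for a four-taxon genome
#'
#' One simulation cell: the species tree (((P1,P2),P3),O) with branch
#' lengths in generations, a constant population size (quoted as 2N, the
#' number of haploid gene copies), per-lineage relative substitution rates,
#' optional episodic P1-to-P3 introgression, and the genome layout
#' (independent non-recombining loci, freely recombining between loci,
#' concatenated in simulation order).
#'
#' @param T_S Divergence time of the sister lineages P1, P2 (generations).
#' @param T_I Internal branch length (generations).
#' @param T_O Outgroup stem length (generations).
#' @param two_N Population size as 2N (haploid gene copies); the pairwise
#'   coalescent rate is 1/(2N) per generation in every population.
#' @param lambda_p1,lambda_p3,lambda_o Relative substitution rates of the
#'   terminal lineages (reference rate 1 on P2 and all ancestral branches).
#' @param gamma Introgression proportion (P1 -> P3 outflow, i.e. the P3
#'   lineage traces back into P1's population with this probability).
#' @param T_G Introgression time in generations (< T_S when gamma > 0).
#' @param genome_size_bp Total alignment length; must be a multiple of
#'   \code{locus_length_bp}.
#' @param locus_length_bp Length of each independent locus (default 100).
#' @param mu Mutation rate per site per generation (default 2e-8).
#' @param n_replicates Default replicate count for scenario orchestration.
#' @param seed Master seed for the scenario.
#' @param sample_times Sampling times of (P1,P2,P3,O) in generations before
#'   present; nonzero values are only meaningful for the uniform-rate
#'   sampling-time-shift construction and therefore require all rate
#'   multipliers to equal 1.
#' @return An object of class \code{"scenario_config"}.
#' @seealso [sim_dataset()], [time_shift_transform()], [to_mutation_units()]
#' @export
scenario_config <- function(T_S, T_I, T_O, two_N,
                            lambda_p1 = 1, lambda_p3 = 1, lambda_o = 1,
                            gamma = 0, T_G = 0,
                            genome_size_bp = 1e7, locus_length_bp = 100,
                            mu = 2e-8, n_replicates = 20, seed = 1L,
                            sample_times = c(0, 0, 0, 0)) {
  if (min(T_S, T_I, T_O, two_N, mu) <= 0)
    stop("times, 2N and mu must be positive", call. = FALSE)
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0,1]", call. = FALSE)
  if (gamma > 0 && (T_G < 0 || T_G >= T_S))
    stop("T_G must satisfy 0 <= T_G < T_S when gamma > 0", call. = FALSE)
  if (min(lambda_p1, lambda_p3, lambda_o) <= 0)
    stop("rate multipliers must be > 0", call. = FALSE)
  nloc <- genome_size_bp / locus_length_bp
  if (nloc != round(nloc))
    stop("genome_size_bp must be a multiple of locus_length_bp", call. = FALSE)
  if (length(sample_times) != 4L || any(sample_times < 0))
    stop("sample_times must be four nonnegative times", call. = FALSE)
  if (any(sample_times > 0) &&
      any(c(lambda_p1, lambda_p3, lambda_o) != 1))
    stop("nonzero sample_times require unit rate multipliers", call. = FALSE)
  if (max(sample_times) >= T_S)
    stop("sample_times must precede the sister divergence", call. = FALSE)
  structure(list(T_S = T_S, T_I = T_I, T_O = T_O, two_N = two_N,
                 lambda_p1 = lambda_p1, lambda_p3 = lambda_p3,
                 lambda_o = lambda_o, gamma = gamma, T_G = T_G,
                 genome_size_bp = genome_size_bp,
                 locus_length_bp = locus_length_bp, mu = mu,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 sample_times = as.numeric(sample_times)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario: TS=%g TI=%g TO=%g 2N=%g mu=%g\n",
              x$T_S, x$T_I, x$T_O, x$two_N, x$mu))
  cat(sprintf("  lambda (P1,P3,O) = (%g, %g, %g); gamma=%g TG=%g\n",
              x$lambda_p1, x$lambda_p3, x$lambda_o, x$gamma, x$T_G))
  cat(sprintf("  genome %g bp in %g-bp loci; %d replicates; seed %d\n",
              x$genome_size_bp, x$locus_length_bp, x$n_replicates, x$seed))
  invisible(x)
}

#' Mutation-unit parameters of a scenario
#'
#' Convenience bridge from a [scenario_config()] to the [msci_params()]
#' used by the theory functions.
#'
#' @param sc A [scenario_config()].
#' @return An [msci_params()] object.
#' @export
scenario_params <- function(sc) {
  stopifnot(inherits(sc, "scenario_config"))
  gp <- generation_params(sc$T_S, sc$T_I, sc$T_O, sc$two_N, sc$mu, sc$T_G)
  to_mutation_units(gp, lambda = c(sc$lambda_p1, sc$lambda_p3, sc$lambda_o),
                    gamma = sc$gamma)
}

#' Recast lineage rate variation as non-contemporaneous sampling
#'
#' Converts a scenario in which exactly one terminal lineage has a non-unit
#' rate multiplier (and no introgression) into an equivalent uniform-rate
#' scenario by shifting divergence times and sampling times: for an
#' accelerated lineage with multiplier lambda on a terminal branch of
#' length B, all divergence times move into the past by (lambda-1)*B, the
#' accelerated tip is sampled at the present, and all other tips are
#' sampled (lambda-1)*B generations ago. For lambda < 1 the affected tip is
#' instead sampled (1-lambda)*B generations ago with divergence times
#' unchanged. Expected site-pattern counts are identical to those of the
#' rate-scaled scenario.
#'
#' @param sc A [scenario_config()] with \code{gamma = 0} and at most one
#'   non-unit rate multiplier.
#' @return A [scenario_config()] with unit rates and shifted times.
#' @export
time_shift_transform <- function(sc) {
  stopifnot(inherits(sc, "scenario_config"))
  if (sc$gamma > 0)
    stop("the sampling-time-shift construction requires gamma = 0",
         call. = FALSE)
  lam <- c(sc$lambda_p1, sc$lambda_p3, sc$lambda_o)
  hot <- which(lam != 1)
  if (length(hot) == 0L) return(sc)  # identity
  if (length(hot) > 1L)
    stop("only a single non-unit rate multiplier is supported", call. = FALSE)
  B <- switch(hot, sc$T_S, sc$T_S + sc$T_I, sc$T_S + sc$T_I + sc$T_O)
  tip <- c(1L, 3L, 4L)[hot]
  l <- lam[hot]
  if (l > 1) {
    shift <- (l - 1) * B
    stimes <- rep(shift, 4); stimes[tip] <- 0
    scenario_config(T_S = sc$T_S + shift, T_I = sc$T_I, T_O = sc$T_O,
                    two_N = sc$two_N, gamma = 0,
                    genome_size_bp = sc$genome_size_bp,
                    locus_length_bp = sc$locus_length_bp, mu = sc$mu,
                    n_replicates = sc$n_replicates, seed = sc$seed,
                    sample_times = stimes)
  } else {
    stimes <- rep(0, 4); stimes[tip] <- (1 - l) * B
    scenario_config(T_S = sc$T_S, T_I = sc$T_I, T_O = sc$T_O,
                    two_N = sc$two_N, gamma = 0,
                    genome_size_bp = sc$genome_size_bp,
                    locus_length_bp = sc$locus_length_bp, mu = sc$mu,
                    n_replicates = sc$n_replicates, seed = sc$seed,
                    sample_times = stimes)
  }
}

#' Read a scenario from a YAML file
#'
#' Reads a scenario description whose fields mirror the simulation grid
#' conventions: \code{TS}, \code{TI}, \code{TO}, \code{N2} (the printed
#' 2N), \code{lambdaP1}, \code{lambdaP3}, \code{lambdaO}, \code{GS} (genome
#' size in bp), \code{gamma}, \code{TG}, and optionally \code{locus},
#' \code{mu}, \code{reps}, \code{seed}.
#'
#' @param path Path to a YAML file.
#' @return A [scenario_config()].
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("TS", "TI", "TO", "N2")
  if (!all(need %in% names(y)))
    stop("scenario YAML must define TS, TI, TO and N2", call. = FALSE)
  # YAML readers return plain-notation scientific numbers ("1e5") as
  # strings; coerce every field numerically
  gv <- function(nm, dft) {
    if (is.null(y[[nm]])) return(dft)
    v <- suppressWarnings(as.numeric(y[[nm]]))
    if (is.na(v)) stop("field '", nm, "' is not numeric", call. = FALSE)
    v
  }
  for (nm in need) y[[nm]] <- gv(nm, NULL)
  scenario_config(T_S = y$TS, T_I = y$TI, T_O = y$TO, two_N = y$N2,
                  lambda_p1 = gv("lambdaP1", 1),
                  lambda_p3 = gv("lambdaP3", 1),
                  lambda_o = gv("lambdaO", 1),
                  gamma = gv("gamma", 0), T_G = gv("TG", 0),
                  genome_size_bp = gv("GS", 1e7),
                  locus_length_bp = gv("locus", 100),
                  mu = gv("mu", 2e-8),
                  n_replicates = gv("reps", 20),
                  seed = gv("seed", 1))
}

#' Deterministic derived seeds
#'
#' Mixes a master seed with integer coordinates (e.g. scenario index and
#' replicate number) into a new seed below 2^31, so that any replicate can
#' be re-run independently.
#'
#' @param seed Master seed.
#' @param ... Integer coordinates.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483647
  for (k in c(...)) s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  as.integer(s)
}
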