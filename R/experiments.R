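# Scenario orchestration: replicate runs, false-positive / power
# summaries, and expansion of the simulation-grid scenario rows.

#' Run all replicates of one scenario cell
#'
#' Simulates \code{sc$n_replicates} independent genomes (replicate seeds
#' derived from the scenario master seed), applies the block-jackknife
#' D-statistic test and the HyDe-style jackknife test to each, and returns
#' one record per replicate. Errors in a replicate are recorded in the
#' \code{error} column rather than aborting the batch.
#'
#' @param sc A [scenario_config()].
#' @param n_blocks Number of jackknife blocks (default 100).
#' @param alpha Significance threshold for both tests (default 0.01).
#' @return A data frame with one row per replicate: seeds, pattern totals,
#'   D, its jackknife SE, z, p and inference, and the HyDe-style
#'   assignment and p.
#' @export
run_scenario <- function(sc, n_blocks = 100L, alpha = 0.01) {
  stopifnot(inherits(sc, "scenario_config"))
  R <- sc$n_replicates
  rows <- vector("list", R)
  for (r in seq_len(R)) {
    sd <- derive_seed(sc$seed, r)
    rec <- data.frame(replicate = r, seed = sd, n_abba = NA_real_,
                      n_baba = NA_real_, n_bbaa = NA_real_, D = NA_real_,
                      se = NA_real_, z = NA_real_, p = NA_real_,
                      d_significant = NA, d_inference = NA_character_,
                      hyde_stat = NA_real_, hyde_z = NA_real_,
                      hyde_p = NA_real_, hyde_significant = NA,
                      hyde_hybrid = NA_character_,
                      hyde_assignment = NA_character_,
                      error = NA_character_)
    res <- tryCatch({
      bc <- sim_dataset(sc, seed = sd, n_blocks = n_blocks)
      tot <- colSums(bc[, c("n_abba", "n_baba", "n_bbaa")])
      dt <- d_test(bc, alpha = alpha)
      hy <- tryCatch(hyde_jk_test(bc, alpha = alpha),
                     error = function(e) NULL)
      rec$n_abba <- tot[[1]]; rec$n_baba <- tot[[2]]; rec$n_bbaa <- tot[[3]]
      rec$D <- dt$D; rec$se <- dt$se; rec$z <- dt$z; rec$p <- dt$p
      rec$d_significant <- dt$significant
      rec$d_inference <- dt$inferred_pair
      if (!is.null(hy)) {
        rec$hyde_stat <- hy$statistic; rec$hyde_z <- hy$z
        rec$hyde_p <- hy$p; rec$hyde_significant <- hy$significant
        rec$hyde_hybrid <- hy$hybrid; rec$hyde_assignment <- hy$assignment
      }
      rec
    }, error = function(e) {
      rec$error <- conditionMessage(e)
      rec
    })
    rows[[r]] <- res
  }
  do.call(rbind, rows)
}

#' Summarise replicate records into false-positive / power rates
#'
#' For a cell with no simulated introgression (\code{truth = "none"}),
#' every significant call is a false positive. For a simulated P1-P3
#' introgression (\code{truth = "P1-P3"}), a significant D test inferring
#' the P1-P3 pair counts as power and any other significant inference as a
#' false positive; for the HyDe-style test the introgressed ingroup P3 is
#' taken as the correct hybrid, so significant calls naming another hybrid
#' (e.g. P1, the classic directional confusion) count as false positives.
#'
#' @param records Data frame from [run_scenario()].
#' @param truth \code{"none"} or \code{"P1-P3"}.
#' @param theory_D Optional analytic expected D for the overlay column.
#' @return A one-row data frame of summaries (rates in [0, 1]).
#' @export
summarize_records <- function(records, truth = c("none", "P1-P3"),
                              theory_D = NA_real_) {
  truth <- match.arg(truth)
  ok <- is.na(records$error)
  if (!any(ok)) stop("no successful replicates to summarise", call. = FALSE)
  r <- records[ok, , drop = FALSE]
  dsig <- r$d_significant %in% TRUE
  hsig <- r$hyde_significant %in% TRUE
  if (truth == "none") {
    d_fp <- mean(dsig); d_power <- 0
    hyde_fp <- mean(hsig); hyde_power <- 0
  } else {
    d_power <- mean(dsig & r$d_inference %in% "P1-P3")
    d_fp <- mean(dsig & !r$d_inference %in% "P1-P3")
    hyde_power <- mean(hsig & r$hyde_hybrid %in% "P3")
    hyde_fp <- mean(hsig & !r$hyde_hybrid %in% "P3")
  }
  data.frame(n_replicates = nrow(r),
             mean_D = mean(r$D), min_D = min(r$D), max_D = max(r$D),
             sd_D = stats::sd(r$D), theory_D = theory_D,
             d_fp = d_fp, d_power = d_power,
             hyde_fp = hyde_fp, hyde_power = hyde_power,
             truth = truth)
}

# fixed per-scenario settings of the simulation grid rows
.table1_defaults <- function(scenario) {
  if (!scenario %in% 1:8) stop("unknown scenario id", call. = FALSE)
  list(gamma = if (scenario == 8) 0.05 else 0)
}

#' Expand simulation-grid cells for a scenario row
#'
#' Builds the cell table for one row of the simulation grid: scenario 1
#' varies the common branch length T and 2N under P1-rate variation;
#' scenarios 2-4 vary one branch at a time (T_S, T_I or T_O) at
#' lambda_P1 = 1.5; scenarios 5-6 vary the P3 or O rate; scenario 7 varies
#' genome size; scenario 8 repeats scenario 1 with an episodic P1 -> P3
#' introgression (gamma = 0.05 at T_G = 0.95 T_S). Defaults are reduced
#' desk-scale axes; pass explicit vectors for other cells.
#'
#' @param scenario Scenario id (1-8).
#' @param T Common branch length in generations (scenarios 1, 7, 8).
#' @param two_N Population size values.
#' @param lambda_p1,lambda_p3,lambda_o Rate-multiplier axes.
#' @param T_S,T_I,T_O Branch-length axes for scenarios 2-4.
#' @param genome_mb Genome sizes in Mb.
#' @return A data frame of cells suitable for [table1_grid()].
#' @export
table1_cells <- function(scenario,
                         T = 1e5, two_N = 1e4,
                         lambda_p1 = NULL, lambda_p3 = 1, lambda_o = 1,
                         T_S = NULL, T_I = NULL, T_O = NULL,
                         genome_mb = 10) {
  dft <- .table1_defaults(scenario)
  if (is.null(lambda_p1))
    lambda_p1 <- switch(as.character(scenario),
                        "1" = c(0.67, 1, 1.5), "8" = c(0.67, 1, 1.5), 1.5)
  if (scenario %in% c(1, 7, 8)) {
    g <- expand.grid(T = T, two_N = two_N, lambda_p1 = lambda_p1,
                     lambda_p3 = lambda_p3, lambda_o = lambda_o,
                     genome_mb = genome_mb)
    g$T_S <- g$T; g$T_I <- g$T; g$T_O <- g$T
  } else if (scenario == 2) {
    if (is.null(T_S)) T_S <- c(1e4, 1e5, 1e6)
    g <- expand.grid(T_S = T_S, two_N = two_N, lambda_p1 = lambda_p1,
                     lambda_p3 = lambda_p3, lambda_o = lambda_o,
                     genome_mb = genome_mb)
    g$T_I <- 1e5; g$T_O <- 1e5
  } else if (scenario == 3) {
    if (is.null(T_I)) T_I <- c(1e4, 1e5, 1e6)
    g <- expand.grid(T_I = T_I, two_N = two_N, lambda_p1 = lambda_p1,
                     lambda_p3 = lambda_p3, lambda_o = lambda_o,
                     genome_mb = genome_mb)
    g$T_S <- 1e5; g$T_O <- 1e5
  } else if (scenario == 4) {
    if (is.null(T_O)) T_O <- c(1e4, 1e5, 1e6)
    g <- expand.grid(T_O = T_O, two_N = two_N, lambda_p1 = lambda_p1,
                     lambda_p3 = lambda_p3, lambda_o = lambda_o,
                     genome_mb = genome_mb)
    g$T_S <- 1e5; g$T_I <- 1e5
  } else if (scenario == 5) {
    g <- expand.grid(lambda_p3 = if (length(lambda_p3) > 1 || lambda_p3 != 1)
                       lambda_p3 else c(0.5, 1, 2),
                     lambda_p1 = lambda_p1, lambda_o = lambda_o,
                     two_N = two_N, genome_mb = genome_mb)
    g$T_S <- 1e5; g$T_I <- 1e5; g$T_O <- 1e5
  } else if (scenario == 6) {
    g <- expand.grid(lambda_o = if (length(lambda_o) > 1 || lambda_o != 1)
                       lambda_o else c(0.5, 1, 2),
                     lambda_p1 = lambda_p1, lambda_p3 = lambda_p3,
                     two_N = two_N, genome_mb = genome_mb)
    g$T_S <- 1e5; g$T_I <- 1e5; g$T_O <- 1e5
  }
  g$scenario <- scenario
  g$gamma <- dft$gamma
  g$T_G <- if (scenario == 8) 0.95 * g$T_S else 0
  g$cell <- paste0("s", scenario, "_", seq_len(nrow(g)))
  g[, c("cell", "scenario", "T_S", "T_I", "T_O", "two_N", "lambda_p1",
        "lambda_p3", "lambda_o", "gamma", "T_G", "genome_mb")]
}

#' Run and summarise a table of scenario cells
#'
#' Expands each cell into a [scenario_config()], runs all replicates,
#' and attaches the analytic expected D as a theory overlay.
#'
#' @param cells Data frame from [table1_cells()] (rows may mix scenarios).
#' @param n_replicates Replicates per cell.
#' @param seed Master seed; each cell uses \code{derive_seed(seed, row)}.
#' @param n_blocks Jackknife blocks per genome.
#' @param alpha Significance threshold.
#' @param locus_length_bp Locus length (default 100).
#' @return List with \code{records} (all replicate rows, keyed by cell)
#'   and \code{summary} (one row per cell).
#' @export
table1_grid <- function(cells, n_replicates = 20, seed = 1,
                        n_blocks = 100L, alpha = 0.01,
                        locus_length_bp = 100) {
  recs <- list(); sums <- list()
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    sc <- scenario_config(T_S = cl$T_S, T_I = cl$T_I, T_O = cl$T_O,
                          two_N = cl$two_N, lambda_p1 = cl$lambda_p1,
                          lambda_p3 = cl$lambda_p3, lambda_o = cl$lambda_o,
                          gamma = cl$gamma, T_G = cl$T_G,
                          genome_size_bp = cl$genome_mb * 1e6,
                          locus_length_bp = locus_length_bp,
                          n_replicates = n_replicates,
                          seed = derive_seed(seed, i))
    r <- run_scenario(sc, n_blocks = n_blocks, alpha = alpha)
    r <- cbind(cell = cl$cell, r)
    thD <- tryCatch(expected_D(scenario_params(sc)), error = function(e) NA)
    s <- summarize_records(r, truth = if (cl$gamma > 0) "P1-P3" else "none",
                           theory_D = thD)
    s <- cbind(cl, s)
    recs[[i]] <- r; sums[[i]] <- s
  }
  list(records = do.call(rbind, recs), summary = do.call(rbind, sums))
}
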