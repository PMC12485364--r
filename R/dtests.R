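# The D-statistic with block-jackknife z-test, and the HyDe-style
# jackknife test on the two least-frequent site patterns.

#' Patterson's D statistic from site-pattern counts
#'
#' D = (N_ABBA - N_BABA) / (N_ABBA + N_BABA).
#'
#' @param counts Either a \code{"block_counts"} data frame (counts are
#'   pooled over blocks) or a numeric vector with named elements
#'   \code{n_abba} and \code{n_baba} (or the first two elements in that
#'   order).
#' @return D in [-1, 1]; an error when both counts are zero.
#' @export
d_statistic <- function(counts) {
  if (inherits(counts, "block_counts") || is.data.frame(counts)) {
    na <- sum(counts$n_abba); nb <- sum(counts$n_baba)
  } else if (is.numeric(counts)) {
    if (!is.null(names(counts)) &&
        all(c("n_abba", "n_baba") %in% names(counts))) {
      na <- counts[["n_abba"]]; nb <- counts[["n_baba"]]
    } else {
      na <- counts[[1]]; nb <- counts[[2]]
    }
  } else stop("unsupported counts input", call. = FALSE)
  if (na + nb <= 0)
    stop("N_ABBA + N_BABA is zero; D undefined", call. = FALSE)
  (na - nb) / (na + nb)
}

#' Block-jackknife z-test of the D-statistic
#'
#' Tests D = 0 with the delete-one block-jackknife standard error and a
#' normal z statistic. A significant positive D is interpreted as
#' introgression between P2 and P3, a significant negative D as
#' introgression between P1 and P3.
#'
#' @param blocks A \code{"block_counts"} data frame.
#' @param alpha Significance threshold on the p-value (default 0.01).
#' @param alternative \code{"two.sided"} (default) or \code{"one.sided"}
#'   (tail selected by the sign of the estimate).
#' @return A list of class \code{"d_test_result"}: \code{D}, \code{se},
#'   \code{z}, \code{p}, \code{significant}, and \code{inferred_pair}
#'   (\code{"P2-P3"}, \code{"P1-P3"}, or NA when not significant).
#' @export
d_test <- function(blocks, alpha = 0.01,
                   alternative = c("two.sided", "one.sided")) {
  alternative <- match.arg(alternative)
  jk <- block_jackknife(blocks, d_statistic)
  D <- jk$estimate
  if (jk$se == 0) {
    if (D != 0) {
      warning("jackknife SE is zero with a nonzero D; p set to 0")
      z <- Inf * sign(D); p <- 0
    } else { z <- 0; p <- 1 }
  } else {
    z <- D / jk$se
    p <- if (alternative == "two.sided") 2 * stats::pnorm(-abs(z))
         else stats::pnorm(-abs(z))
  }
  sig <- p < alpha
  pair <- if (sig) { if (D > 0) "P2-P3" else "P1-P3" } else NA_character_
  structure(list(D = D, se = jk$se, z = z, p = p, significant = sig,
                 inferred_pair = pair, alpha = alpha,
                 n_blocks = jk$n_blocks),
            class = "d_test_result")
}

#' @export
print.d_test_result <- function(x, ...) {
  cat(sprintf("D = %.5f  SE = %.5f  z = %.3f  p = %.3g\n",
              x$D, x$se, x$z, x$p))
  if (x$significant)
    cat("significant at alpha =", x$alpha, "-> introgression",
        x$inferred_pair, "\n")
  else cat("not significant at alpha =", x$alpha, "\n")
  invisible(x)
}

# fixed priority used to resolve ties among equally frequent patterns
.hyde_tie_order <- c("n_baba", "n_abba", "n_bbaa")

#' HyDe-style block-jackknife test of the two least-frequent site patterns
#'
#' Tests whether the two least frequent of the three parsimony-informative
#' site-pattern counts are equal, which is the operating principle of
#' hybrid-detection from site patterns: the two ingroup lineages sharing
#' alleles in the smallest number of informative sites are called the
#' parents and the remaining ingroup lineage the hybrid. The two smallest
#' totals are identified on the full data (ties resolved in the fixed
#' order BABA, ABBA, BBAA), their normalised difference is tested with a
#' delete-one block-jackknife standard error and a two-sided normal
#' p-value. This is a jackknife equality test in the spirit of HyDe rather
#' than a re-implementation of the HyDe software's invariant statistic.
#'
#' @param blocks A \code{"block_counts"} data frame; all three pattern
#'   totals must be positive.
#' @param alpha Significance threshold (default 0.01).
#' @return A list of class \code{"hyde_result"}: \code{assignment}
#'   (\code{"Pi-Pj-Pk"} with Pj the hybrid, NA when not significant),
#'   \code{hybrid}, \code{statistic}, \code{se}, \code{z}, \code{p},
#'   \code{significant}, \code{smallest} (the least-frequent pattern).
#' @export
hyde_jk_test <- function(blocks, alpha = 0.01) {
  cnt <- as.matrix(blocks[, c("n_abba", "n_baba", "n_bbaa")])
  tot <- colSums(cnt)
  if (any(tot <= 0))
    stop("all three pattern totals must be positive", call. = FALSE)
  pri <- match(names(tot), .hyde_tie_order)
  ordn <- names(tot)[order(tot, pri)]
  s1 <- ordn[1]; s2 <- ordn[2]  # the two least frequent, s1 smallest
  f <- function(v) (v[[s1]] - v[[s2]]) / (v[[s1]] + v[[s2]])
  jk <- block_jackknife(blocks, f)
  if (jk$se == 0) {
    if (jk$estimate != 0) {
      warning("jackknife SE is zero with a nonzero statistic; p set to 0")
      z <- Inf * sign(jk$estimate); p <- 0
    } else { z <- 0; p <- 1 }
  } else {
    z <- jk$estimate / jk$se
    p <- 2 * stats::pnorm(-abs(z))
  }
  sig <- p < alpha
  hyb <- switch(s1,
                n_baba = "P2",   # parents P1, P3
                n_abba = "P1",   # parents P2, P3
                n_bbaa = "P3")   # parents P1, P2
  assignment <- switch(s1,
                       n_baba = "P1-P2-P3",
                       n_abba = "P2-P1-P3",
                       n_bbaa = "P1-P3-P2")
  structure(list(assignment = if (sig) assignment else NA_character_,
                 hybrid = if (sig) hyb else NA_character_,
                 statistic = jk$estimate, se = jk$se, z = z, p = p,
                 significant = sig, smallest = sub("n_", "", s1),
                 alpha = alpha),
            class = "hyde_result")
}

#' @export
print.hyde_result <- function(x, ...) {
  cat(sprintf("HyDe_jk: stat = %.5f  SE = %.5f  z = %.3f  p = %.3g\n",
              x$statistic, x$se, x$z, x$p))
  if (x$significant)
    cat("significant: hybrid =", x$hybrid, "(", x$assignment, ")\n")
  else cat("not significant at alpha =", x$alpha, "\n")
  invisible(x)
}
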