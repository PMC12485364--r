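#' Delete-one block jackknife for genome-wide count statistics
#'
#' Computes a statistic on pooled genome-wide site-pattern counts and its
#' standard error by deleting one contiguous block at a time: with B
#' blocks and leave-one-out estimates \eqn{\hat\theta_{(i)}},
#' \deqn{SE^2 = \frac{B-1}{B}\sum_i (\hat\theta_{(i)} - \bar\theta)^2.}
#'
#' @param blocks A \code{"block_counts"} data frame (columns
#'   \code{n_abba}, \code{n_baba}, \code{n_bbaa}) with at least two
#'   blocks.
#' @param statistic Function taking a named numeric vector
#'   \code{c(n_abba=, n_baba=, n_bbaa=)} and returning a scalar. Blocks
#'   whose removal leaves the statistic undefined (error, NA or NaN) are
#'   flagged and dropped with a warning; at least two usable leave-one-out
#'   subsets are required.
#' @return List with \code{estimate} (full-data statistic), \code{se},
#'   \code{loo} (leave-one-out values), and \code{n_blocks}.
#' @export
block_jackknife <- function(blocks, statistic) {
  cnt <- as.matrix(blocks[, c("n_abba", "n_baba", "n_bbaa")])
  B <- nrow(cnt)
  if (B < 2L) stop("need at least two blocks", call. = FALSE)
  tot <- colSums(cnt)
  est <- statistic(tot)
  loo <- vapply(seq_len(B), function(i) {
    v <- tryCatch(statistic(tot - cnt[i, ]), error = function(e) NA_real_)
    if (!is.finite(v)) NA_real_ else v
  }, numeric(1))
  usable <- is.finite(loo)
  if (!all(usable))
    warning(sum(!usable), " leave-one-out subset(s) left the statistic ",
            "undefined and were dropped")
  if (sum(usable) < 2L)
    stop("fewer than two usable leave-one-out subsets", call. = FALSE)
  lu <- loo[usable]
  Bu <- length(lu)
  se <- sqrt((Bu - 1) / Bu * sum((lu - mean(lu))^2))
  list(estimate = est, se = se, loo = loo, n_blocks = Bu)
}
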