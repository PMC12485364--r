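# Site-pattern classification and counting from four-taxon alignments.

# map nucleotide characters to codes 1..4; anything else (N, gaps, ...) is 0
.nt_codes <- local({
  idx <- integer(128)
  idx[utf8ToInt("A")] <- 1L; idx[utf8ToInt("C")] <- 2L
  idx[utf8ToInt("G")] <- 3L; idx[utf8ToInt("T")] <- 4L
  idx[utf8ToInt("a")] <- 1L; idx[utf8ToInt("c")] <- 2L
  idx[utf8ToInt("g")] <- 3L; idx[utf8ToInt("t")] <- 4L
  idx
})

.seq_to_codes <- function(s) {
  v <- utf8ToInt(s)
  if (any(v > 127L | v < 1L))
    stop("malformed sequence characters", call. = FALSE)
  .nt_codes[v]
}

#' Classify aligned site columns into ABBA / BABA / BBAA / OTHER
#'
#' A column over the taxa (P1, P2, P3, O) is ABBA when P1 and the outgroup
#' share one state and P2, P3 share a different one; BABA when P1, P3 share
#' against P2, O; BBAA when the sister pair P1, P2 shares against P3, O.
#' Everything else -- invariant columns, singletons, three or four alleles,
#' or columns containing ambiguity codes or gaps -- is OTHER. Only strictly
#' biallelic arrangements are counted; no fractional weighting of
#' ambiguous bases is applied.
#'
#' @param states Either a character vector of four single nucleotides
#'   (one site, ordered P1, P2, P3, O) or a 4-row character matrix /
#'   4-element vector of equal-length strings (one row or element per
#'   taxon).
#' @return A character vector of labels, one per site.
#' @export
classify_sites <- function(states) {
  if (is.matrix(states)) {
    stopifnot(nrow(states) == 4L)
    codes <- apply(states, 1, function(r) {
      v <- utf8ToInt(paste(r, collapse = ""))
      if (any(v > 127L)) stop("malformed sequence characters", call. = FALSE)
      .nt_codes[v]
    })
  } else if (is.character(states) && length(states) == 4L) {
    codes <- vapply(states, .seq_to_codes, integer(nchar(states[1])))
    if (!is.matrix(codes)) codes <- matrix(codes, 1L, 4L)
  } else stop("states must be four sequences or one four-base site",
              call. = FALSE)
  s1 <- codes[, 1]; s2 <- codes[, 2]; s3 <- codes[, 3]; s4 <- codes[, 4]
  ok <- s1 > 0L & s2 > 0L & s3 > 0L & s4 > 0L
  lab <- rep("OTHER", length(s1))
  lab[ok & s1 == s4 & s2 == s3 & s1 != s2] <- "ABBA"
  lab[ok & s1 == s3 & s2 == s4 & s1 != s2] <- "BABA"
  lab[ok & s1 == s2 & s3 == s4 & s1 != s3] <- "BBAA"
  lab
}

#' Read a multiple-sequence FASTA alignment
#'
#' @param path Path to an uncompressed FASTA file holding one alignment.
#' @return A [Biostrings::DNAStringSet] whose sequences all have equal
#'   width.
#' @export
read_alignment_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(unique(Biostrings::width(x))) != 1L)
    stop("sequences are not aligned (unequal lengths)", call. = FALSE)
  x
}

#' Count site patterns in a four-taxon alignment, by genome block
#'
#' Classifies every column of a four-taxon alignment (see
#' [classify_sites()]) and tallies ABBA/BABA/BBAA counts in contiguous
#' equal-length blocks, the resampling unit of the block jackknife. Block
#' intervals are 0-based and half-open.
#'
#' @param aln A [Biostrings::DNAStringSet] or named character vector of
#'   four equal-length sequences.
#' @param outgroup Name of the outgroup sequence (role O).
#' @param ingroup Optional names of the three ingroup sequences in the
#'   roles (P1, P2, P3); defaults to the non-outgroup sequences in
#'   alignment order.
#' @param n_blocks Number of contiguous blocks (default 100).
#' @return A \code{"block_counts"} data frame as in [sim_dataset()].
#' @export
count_patterns <- function(aln, outgroup = "O", ingroup = NULL,
                           n_blocks = 100L) {
  if (inherits(aln, "DNAStringSet")) aln <- as.character(aln)
  if (!is.character(aln) || length(aln) != 4L || is.null(names(aln)))
    stop("alignment must be four named sequences", call. = FALSE)
  if (!outgroup %in% names(aln))
    stop("outgroup '", outgroup, "' not found in the alignment",
         call. = FALSE)
  if (is.null(ingroup)) ingroup <- setdiff(names(aln), outgroup)
  if (length(ingroup) != 3L || !all(ingroup %in% names(aln)))
    stop("ingroup must name the three non-outgroup sequences", call. = FALSE)
  ord <- aln[c(ingroup, outgroup)]
  n <- nchar(ord[[1]])
  if (any(nchar(ord) != n)) stop("sequence length mismatch", call. = FALSE)
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 1L || n_blocks > n)
    stop("n_blocks must be between 1 and the alignment length",
         call. = FALSE)
  codes <- vapply(ord, .seq_to_codes, integer(n))
  s1 <- codes[, 1]; s2 <- codes[, 2]; s3 <- codes[, 3]; s4 <- codes[, 4]
  ok <- s1 > 0L & s2 > 0L & s3 > 0L & s4 > 0L
  lab <- integer(n)
  lab[ok & s1 == s4 & s2 == s3 & s1 != s2] <- 1L
  lab[ok & s1 == s3 & s2 == s4 & s1 != s2] <- 2L
  lab[ok & s1 == s2 & s3 == s4 & s1 != s3] <- 3L
  bid <- ceiling(seq_len(n) * as.double(n_blocks) / n)
  counts <- vapply(1:3, function(k) tabulate(bid[lab == k], n_blocks),
                   integer(n_blocks))
  if (!is.matrix(counts)) counts <- matrix(counts, n_blocks)
  sites_per_block <- tabulate(bid, n_blocks)
  end_bp <- cumsum(sites_per_block)
  out <- data.frame(block_id = seq_len(n_blocks),
                    start_bp = c(0, end_bp[-n_blocks]),
                    end_bp = end_bp,
                    n_abba = counts[, 1], n_baba = counts[, 2],
                    n_bbaa = counts[, 3])
  attr(out, "total_sites") <- n
  class(out) <- c("block_counts", "data.frame")
  out
}

#' Write / read block-wise site-pattern counts as TSV
#'
#' @param counts A \code{"block_counts"} data frame.
#' @param path Output (or input) TSV path.
#' @return \code{read_counts_tsv} returns a \code{"block_counts"} data
#'   frame; \code{write_counts_tsv} returns \code{path} invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  utils::write.table(as.data.frame(counts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("block_id", "start_bp", "end_bp", "n_abba", "n_baba", "n_bbaa")
  if (!all(need %in% names(out)))
    stop("counts TSV lacks required columns", call. = FALSE)
  class(out) <- c("block_counts", "data.frame")
  out
}
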