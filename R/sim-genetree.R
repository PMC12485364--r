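# Single-gene-tree API: an inspectable tree with per-population segments,
# explicit rate scaling, and per-locus alignment simulation.

# population timeline of a lineage kind; kinds: "tip1".."tip4", "internal"
.lineage_profile <- function(kind, sc, jumped = FALSE, birth = 0) {
  T1 <- sc$T_S; T2 <- sc$T_S + sc$T_I; T3 <- T2 + sc$T_O; TG <- sc$T_G
  anc <- function(from) {
    rbind(data.frame(pop = "A12", from = max(from, T1), to = T2),
          data.frame(pop = "A123", from = max(from, T2), to = T3),
          data.frame(pop = "root", from = max(from, T3), to = Inf))
  }
  pr <- switch(kind,
    tip1 = rbind(data.frame(pop = "P1", from = 0, to = T1), anc(T1)),
    tip2 = rbind(data.frame(pop = "P2", from = 0, to = T1), anc(T1)),
    tip3 = if (jumped)
      rbind(data.frame(pop = "P3", from = 0, to = TG),
            data.frame(pop = "P1", from = TG, to = T1), anc(T1))
    else
      rbind(data.frame(pop = "P3", from = 0, to = T2), anc(T2)),
    tip4 = rbind(data.frame(pop = "O", from = 0, to = T3),
                 data.frame(pop = "root", from = T3, to = Inf)),
    internal = if (birth < T1)
      rbind(data.frame(pop = "P1", from = birth, to = T1), anc(T1))
    else anc(T1),
    stop("unknown lineage kind"))
  pr[pr$to > pr$from, , drop = FALSE]
}

# clip a profile to [birth, death) and return (pop, from, to) segments
.clip_profile <- function(pr, birth, death) {
  from <- pmax(pr$from, birth)
  to <- pmin(pr$to, death)
  keep <- to > from
  data.frame(pop = pr$pop[keep], from = from[keep], to = to[keep])
}

#' Simulate one gene tree under the MSci scenario
#'
#' Backward-in-time coalescent sample of a single 100-bp-locus genealogy
#' for (P1, P2, P3, O): with probability gamma the P3 lineage jumps into
#' P1's population at T_G; pairwise coalescence occurs at rate 1/(2N) per
#' generation within each population. The returned tree records, for every
#' branch, the populations traversed and the time spent in each -- the
#' carrier for per-population rate scaling.
#'
#' @param sc A [scenario_config()].
#' @param seed Optional seed.
#' @return An object of class \code{"gene_tree"}: \code{events} (node
#'   times in generations and the two children of each of nodes 5..7),
#'   \code{jumped}, \code{par} (parent pointers of nodes 1..6),
#'   \code{segments} (per-branch population segments), and \code{blen}
#'   (branch lengths in expected substitutions per site, as produced by
#'   the simulation engine).
#' @export
sim_gene_tree <- function(sc, seed = NULL) {
  stopifnot(inherits(sc, "scenario_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  tr <- .sim_gene_trees(sc, 1L)
  events <- data.frame(node = 5:7, time = tr$ev_t[1, ],
                       child1 = tr$ev_c1[1, ], child2 = tr$ev_c2[1, ])
  J <- tr$J[1]
  node_birth <- c(sc$sample_times, tr$ev_t[1, 1:2])
  node_death <- c(tr$ev_t[1, tr$par[1, ] - 4L])
  segments <- vector("list", 6L)
  names(segments) <- c("P1", "P2", "P3", "O", "node5", "node6")
  for (v in 1:6) {
    kind <- if (v <= 4L) paste0("tip", v) else "internal"
    pr <- .lineage_profile(kind, sc, jumped = J, birth = node_birth[v])
    segments[[v]] <- .clip_profile(pr, node_birth[v], node_death[v])
  }
  blen <- tr$blen[1, ]
  names(blen) <- names(segments)
  structure(list(events = events, jumped = J, par = tr$par[1, ],
                 segments = segments, blen = blen,
                 scenario = sc),
            class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("Gene tree (times in generations):\n")
  print(x$events)
  if (x$jumped) cat("P3 lineage introgressed into P1's population\n")
  invisible(x)
}

#' Scale a segmented gene tree to mutation lengths
#'
#' Converts per-branch population segments into branch lengths in expected
#' substitutions per site: each segment contributes
#' lambda_pop * duration * mu, with lambda_pop the relative rate of the
#' population it traverses (terminal populations carry the scenario's
#' multipliers; P2 and all ancestral populations have rate 1).
#'
#' @param gt A \code{"gene_tree"} from [sim_gene_tree()].
#' @param sc The scenario (defaults to the one stored in the tree).
#' @return Named numeric vector of six branch lengths
#'   (P1, P2, P3, O, node5, node6).
#' @export
scale_to_mutation_lengths <- function(gt, sc = gt$scenario) {
  stopifnot(inherits(gt, "gene_tree"))
  lam <- c(P1 = sc$lambda_p1, P2 = 1, P3 = sc$lambda_p3, O = sc$lambda_o,
           A12 = 1, A123 = 1, root = 1)
  out <- vapply(gt$segments, function(sg) {
    if (any(!sg$pop %in% names(lam)))
      stop("unknown population label in segments", call. = FALSE)
    sum(lam[sg$pop] * (sg$to - sg$from)) * sc$mu
  }, numeric(1))
  names(out) <- names(gt$segments)
  out
}

#' Simulate a JC69 alignment for one locus
#'
#' Given a gene tree with branch lengths in expected substitutions per
#' site, simulates i.i.d. sites with a uniform root state and JC69
#' transitions along each branch.
#'
#' @param gt A \code{"gene_tree"}.
#' @param locus_length Number of sites (defaults to the scenario's locus
#'   length).
#' @param blen Optional branch lengths (substitutions/site) overriding
#'   [scale_to_mutation_lengths()]; must be nonnegative.
#' @return A 4 x locus_length character matrix with rows P1, P2, P3, O.
#' @export
sim_locus_alignment <- function(gt, locus_length = gt$scenario$locus_length_bp,
                                blen = NULL) {
  stopifnot(inherits(gt, "gene_tree"))
  if (is.null(blen)) blen <- scale_to_mutation_lengths(gt)
  if (any(blen < 0)) stop("negative branch length", call. = FALSE)
  bp <- as.integer(locus_length)
  ST <- matrix(0L, bp, 7)
  ST[, 7] <- sample.int(4L, bp, replace = TRUE) - 1L
  for (v in c(6L, 5L, 4L, 3L, 2L, 1L)) {
    pst <- ST[, gt$par[v]]
    pch <- 0.75 * (1 - exp(-4 * blen[v] / 3))
    w <- which(stats::runif(bp) < pch)
    if (length(w))
      pst[w] <- (pst[w] + sample.int(3L, length(w), replace = TRUE)) %% 4L
    ST[, v] <- pst
  }
  nt <- c("A", "C", "G", "T")
  out <- matrix(nt[ST[, 1:4] + 1L], bp, 4)
  t(structure(out, dimnames = list(NULL, c("P1", "P2", "P3", "O"))))
}
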