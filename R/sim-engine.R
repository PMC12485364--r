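# Vectorized coalescent + JC69 simulation engine.
#
# Gene trees for all loci of a chunk are sampled simultaneously by masked
# vector operations: within each inter-node epoch of the species network,
# waiting times are exponential with rate k(k-1)/2 / (2N) and the merging
# pair is uniform. Site states are then dropped down the per-locus trees
# with JC69 change probabilities computed from per-population rate
# multipliers (a segment resident in population 'pop' accrues
# lambda_pop * duration * mu expected substitutions).

# canonical pair tables: row k (number of lineages), column r (pair index)
.PAIR_I <- rbind(c(NA, NA, NA, NA, NA, NA),
                 c(1L, NA, NA, NA, NA, NA),
                 c(1L, 1L, 2L, NA, NA, NA),
                 c(1L, 1L, 1L, 2L, 2L, 3L))
.PAIR_J <- rbind(c(NA, NA, NA, NA, NA, NA),
                 c(2L, NA, NA, NA, NA, NA),
                 c(2L, 3L, 3L, NA, NA, NA),
                 c(2L, 3L, 4L, 3L, 4L, 4L))

# distinct sorted values per row of an L x 4 matrix with NAs; at most 4
.row_unique4 <- function(vals) {
  big <- 1e9
  a <- vals
  a[is.na(a)] <- big
  a1 <- a[, 1]; a2 <- a[, 2]; a3 <- a[, 3]; a4 <- a[, 4]
  t1 <- pmin(a1, a2); t2 <- pmax(a1, a2)
  t3 <- pmin(a3, a4); t4 <- pmax(a3, a4)
  s1 <- pmin(t1, t3); u3 <- pmax(t1, t3)
  u2 <- pmin(t2, t4); s4 <- pmax(t2, t4)
  s2 <- pmin(u2, u3); s3 <- pmax(u2, u3)
  f1 <- s1 < big
  d2 <- (s2 > s1) & (s2 < big)
  d3 <- (s3 > s2) & (s3 < big)
  d4 <- (s4 > s3) & (s4 < big)
  r1 <- as.integer(f1); r2 <- r1 + d2; r3 <- r2 + d3; r4 <- r3 + d4
  n <- length(s1)
  ids <- matrix(NA_real_, n, 4)
  w <- which(f1); ids[cbind(w, r1[w])] <- s1[w]
  w <- which(d2); ids[cbind(w, r2[w])] <- s2[w]
  w <- which(d3); ids[cbind(w, r3[w])] <- s3[w]
  w <- which(d4); ids[cbind(w, r4[w])] <- s4[w]
  list(ids = ids, k = r4)
}

# fast path for an epoch holding (at most) one fixed coalescible pair of
# tip lineages, before any other event has touched them
.pair_epoch <- function(stt, mask, ci, cj, t0, t1v, cN) {
  L <- nrow(stt$memb)
  w <- stats::rexp(L, 1 / cN)
  sel <- which(mask & (t0 + w < t1v))
  if (length(sel)) {
    ev_col <- stt$nev[sel] + 1L
    newid <- 5L + stt$nev[sel]
    stt$ev_t[cbind(sel, ev_col)] <- t0 + w[sel]
    stt$ev_c1[cbind(sel, ev_col)] <- stt$memb[sel, ci]
    stt$ev_c2[cbind(sel, ev_col)] <- stt$memb[sel, cj]
    stt$memb[sel, ci] <- newid
    stt$memb[sel, cj] <- newid
    stt$nev[sel] <- stt$nev[sel] + 1L
  }
  stt
}

# run one epoch of the masked multi-locus coalescent
.coalesce_epoch <- function(stt, allowed, t0, t1v, cN, max_events) {
  L <- nrow(stt$memb)
  elapsed <- numeric(L)
  alive <- rep(TRUE, L)
  for (slot in seq_len(max_events)) {
    vals <- stt$memb
    vals[!allowed] <- NA_real_
    u <- .row_unique4(vals)
    k <- u$k
    act <- alive & (k >= 2L)
    if (!any(act)) break
    npairs <- k * (k - 1) / 2
    rate <- ifelse(act, npairs / cN, 1)
    w <- stats::rexp(L, rate)
    tnew <- t0 + elapsed + w
    occur <- act & (tnew < t1v)
    r <- 1L + as.integer(floor(stats::runif(L) * pmax(npairs, 1)))
    r <- pmin(r, pmax(npairs, 1L))
    kc <- pmax(pmin(k, 4L), 2L)
    pi_ <- .PAIR_I[cbind(kc, r)]
    pj_ <- .PAIR_J[cbind(kc, r)]
    idx <- seq_len(L)
    id_i <- u$ids[cbind(idx, pi_)]
    id_j <- u$ids[cbind(idx, pj_)]
    newid <- 5L + stt$nev
    sel <- which(occur)
    if (length(sel)) {
      ev_col <- stt$nev[sel] + 1L
      stt$ev_t[cbind(sel, ev_col)] <- tnew[sel]
      stt$ev_c1[cbind(sel, ev_col)] <- as.integer(id_i[sel])
      stt$ev_c2[cbind(sel, ev_col)] <- as.integer(id_j[sel])
      for (col in 1:4) {
        m <- stt$memb[, col]
        hit <- occur & (m == id_i | m == id_j)
        m[hit] <- newid[hit]
        stt$memb[, col] <- m
      }
      stt$nev[sel] <- stt$nev[sel] + 1L
      elapsed[sel] <- tnew[sel] - t0
    }
    alive <- occur
  }
  stt
}

# sample gene trees for L loci; returns parent pointers, branch lengths in
# expected substitutions/site, event bookkeeping and the jump indicator
.sim_gene_trees <- function(sc, L) {
  cN <- sc$two_N; mu <- sc$mu
  T1 <- sc$T_S; T2 <- sc$T_S + sc$T_I; T3 <- T2 + sc$T_O
  TG <- sc$T_G
  lp1 <- sc$lambda_p1; lp3 <- sc$lambda_p3; lo <- sc$lambda_o
  smp <- sc$sample_times

  J <- if (sc$gamma > 0) stats::runif(L) < sc$gamma else rep(FALSE, L)

  stt <- list(memb = matrix(rep(1:4, each = L), L, 4),
              nev = integer(L),
              ev_t = matrix(NA_real_, L, 3),
              ev_c1 = matrix(NA_integer_, L, 3),
              ev_c2 = matrix(NA_integer_, L, 3))

  if (any(J))
    stt <- .pair_epoch(stt, J, 1L, 3L, TG, T1, cN)
  if (any(J)) {
    stt <- .coalesce_epoch(stt, cbind(TRUE, TRUE, J, FALSE), T1, T2, cN, 2L)
  } else {
    stt <- .pair_epoch(stt, rep(TRUE, L), 1L, 2L, T1, T2, cN)
  }
  stt <- .coalesce_epoch(stt, matrix(c(TRUE, TRUE, TRUE, FALSE),
                                     L, 4, byrow = TRUE), T2, T3, cN, 2L)
  stt <- .coalesce_epoch(stt, matrix(TRUE, L, 4), T3, Inf, cN, 3L)
  stopifnot(all(stt$nev == 3L))

  par <- matrix(NA_integer_, L, 6)
  idx <- seq_len(L)
  for (k in 1:3) {
    par[cbind(idx, stt$ev_c1[, k])] <- 4L + k
    par[cbind(idx, stt$ev_c2[, k])] <- 4L + k
  }

  Lam1 <- function(t) mu * (lp1 * pmin(t, T1) + pmax(t - T1, 0))
  Lam2 <- function(t) mu * t
  Lam3n <- function(t) mu * (lp3 * pmin(t, T2) + pmax(t - T2, 0))
  Lam3j <- function(t) mu * (lp3 * pmin(t, TG) +
                               lp1 * pmax(pmin(t, T1) - TG, 0) +
                               pmax(t - T1, 0))
  Lam4 <- function(t) mu * (lo * pmin(t, T3) + pmax(t - T3, 0))

  ptime <- function(v) stt$ev_t[cbind(idx, par[, v] - 4L)]
  blen <- matrix(NA_real_, L, 6)
  blen[, 1] <- Lam1(ptime(1)) - Lam1(smp[1])
  blen[, 2] <- Lam2(ptime(2)) - Lam2(smp[2])
  l3 <- ifelse(J, Lam3j(ptime(3)), Lam3n(ptime(3)))
  l3s <- ifelse(J, Lam3j(smp[3]), Lam3n(smp[3]))
  blen[, 3] <- l3 - l3s
  blen[, 4] <- Lam4(ptime(4)) - Lam4(smp[4])
  for (v in 5:6) {
    s <- stt$ev_t[, v - 4L]
    tp <- ptime(v)
    inP1 <- s < T1  # only the pre-divergence jump coalescence (ac) lineage
    blen[, v] <- ifelse(inP1,
                        mu * (lp1 * (T1 - s) + (tp - T1)),
                        mu * (tp - s))
  }

  list(par = par, blen = blen, J = J,
       ev_t = stt$ev_t, ev_c1 = stt$ev_c1, ev_c2 = stt$ev_c2)
}

# evaluate expr with an isolated RNG stream, preserving the caller's stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# Sparse site simulation: sample, per (locus, branch), the number of sites
# with a net JC69 substitution (Binomial(bp, p_change)), place them at
# distinct positions, and simulate states only at sites hit at least once.
# All other sites are invariant and classify as OTHER. Returns the per-site
# tip states of the mutated sites and their locus indices.
.sim_site_events <- function(trees, bp) {
  L <- nrow(trees$par)
  p_ch <- 0.75 * (1 - exp(-4 * trees$blen / 3))
  ev_l <- ev_v <- integer(0)
  for (v in 1:6) {
    k <- stats::rbinom(L, bp, p_ch[, v])
    w <- which(k > 0L)
    if (length(w)) {
      ev_l <- c(ev_l, rep(w, k[w]))
      ev_v <- c(ev_v, rep(v, sum(k[w])))
    }
  }
  ne <- length(ev_l)
  if (ne == 0L)
    return(list(states = matrix(0L, 0, 4), locus = integer(0),
                site = integer(0)))
  pos <- as.integer(ceiling(stats::runif(ne) * bp))
  # enforce distinct positions within each (locus, branch) group
  grp <- (ev_l - 1) * 6 + ev_v
  for (it in 1:100) {
    o <- order(grp, pos)
    dup <- c(FALSE, diff(grp[o]) == 0 & diff(pos[o]) == 0)
    if (!any(dup)) break
    redo <- o[dup]
    pos[redo] <- as.integer(ceiling(stats::runif(length(redo)) * bp))
  }
  key <- (ev_l - 1) * bp + pos
  us <- sort(unique(key))
  m <- length(us)
  row <- match(key, us)
  ul <- as.integer((us - 1) %/% bp + 1L)
  ST <- matrix(0L, m, 7)
  ST[, 7] <- sample.int(4L, m, replace = TRUE) - 1L
  ridx <- seq_len(m)
  for (v in c(6L, 5L, 4L, 3L, 2L, 1L)) {
    st <- ST[cbind(ridx, trees$par[ul, v])]
    rows_v <- row[ev_v == v]
    if (length(rows_v))
      st[rows_v] <- (st[rows_v] +
                       sample.int(3L, length(rows_v), replace = TRUE)) %% 4L
    ST[, v] <- st
  }
  # 'site' is the 1-based site index within the simulated stretch
  list(states = ST[, 1:4, drop = FALSE], locus = ul, site = as.integer(us))
}

# drop JC69 site states down the trees; returns an (L*bp) x 4 integer
# matrix of tip states coded 0..3 (dense path, used for alignments)
.sim_tip_states <- function(trees, bp) {
  L <- nrow(trees$par)
  n <- L * bp
  ST <- matrix(0L, n, 7)
  ST[, 7] <- sample.int(4L, n, replace = TRUE) - 1L
  site <- seq_len(n)
  for (v in c(6L, 5L, 4L, 3L, 2L, 1L)) {
    pv <- rep(trees$par[, v], each = bp)
    pch <- 0.75 * (1 - exp(-4 * trees$blen[, v] / 3))
    pstate <- ST[cbind(site, pv)]
    chg <- stats::runif(n) < rep(pch, each = bp)
    w <- which(chg)
    if (length(w))
      pstate[w] <- (pstate[w] + sample.int(3L, length(w), replace = TRUE)) %% 4L
    ST[, v] <- pstate
  }
  ST[, 1:4, drop = FALSE]
}

# classify site states: 1 = ABBA, 2 = BABA, 3 = BBAA, 0 = other
.classify_state_matrix <- function(S) {
  s1 <- S[, 1]; s2 <- S[, 2]; s3 <- S[, 3]; s4 <- S[, 4]
  ab <- (s1 == s4) & (s2 == s3) & (s1 != s2)
  ba <- (s1 == s3) & (s2 == s4) & (s1 != s2)
  bb <- (s1 == s2) & (s3 == s4) & (s1 != s3)
  as.integer(ab) + 2L * as.integer(ba) + 3L * as.integer(bb)
}

#' Simulate a four-taxon genome and count site patterns
#'
#' Simulates \code{genome_size_bp / locus_length_bp} independent loci
#' (free recombination between loci, none within), each with its own gene
#' tree under the MSci model with rate variation, drops JC69 mutations
#' along the trees, and tallies the ABBA/BABA/BBAA site-pattern counts in
#' contiguous equal-length genome blocks (the unit of jackknife
#' resampling). A fast path counts patterns directly from the simulated
#' site states; optionally the concatenated alignment is also written as
#' FASTA (taxa P1, P2, P3, O), which is practical for genomes up to a few
#' tens of Mb.
#'
#' @param sc A [scenario_config()].
#' @param seed Seed for this dataset (defaults to the scenario seed).
#' @param n_blocks Number of contiguous blocks (default 100).
#' @param emit_fasta Optional path; if given, the concatenated alignment is
#'   written as uncompressed FASTA.
#' @return An object of class \code{"block_counts"}: a data frame with
#'   columns \code{block_id}, \code{start_bp}, \code{end_bp} (0-based,
#'   half-open), \code{n_abba}, \code{n_baba}, \code{n_bbaa}, with the
#'   total site count, scenario and seed attached as attributes.
#' @export
sim_dataset <- function(sc, seed = sc$seed, n_blocks = 100L,
                        emit_fasta = NULL) {
  stopifnot(inherits(sc, "scenario_config"))
  bp <- sc$locus_length_bp
  L <- as.integer(sc$genome_size_bp / bp)
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 1L || n_blocks > L)
    stop("n_blocks must be between 1 and the number of loci", call. = FALSE)
  block_of <- ceiling(seq_len(L) * n_blocks / L)
  set.seed(as.integer(seed))

  chunk <- 20000L  # loci per chunk; fixed so that a seed fully determines
                   # the RNG stream layout
  fillseed <- derive_seed(seed, 424243L)  # isolated stream for invariant
                                          # root states on the FASTA path
  counts <- matrix(0, n_blocks, 3)
  fasta_acc <- if (!is.null(emit_fasta)) vector("list", ceiling(L / chunk))
  ci <- 0L
  for (lo in seq(1L, L, by = chunk)) {
    hi <- min(lo + chunk - 1L, L)
    nl <- hi - lo + 1L
    trees <- .sim_gene_trees(sc, nl)
    ev <- .sim_site_events(trees, bp)
    lab <- .classify_state_matrix(ev$states)
    bid <- block_of[lo:hi][ev$locus]
    for (k in 1:3) {
      hit <- bid[lab == k]
      if (length(hit)) counts[, k] <- counts[, k] + tabulate(hit, n_blocks)
    }
    ci <- ci + 1L
    if (!is.null(emit_fasta)) {
      # reconstruct the full alignment: invariant sites carry a root state
      # drawn from a separate stream, so block counts do not depend on
      # whether FASTA is emitted
      n <- nl * bp
      root <- .with_seed(derive_seed(fillseed, ci),
                         sample.int(4L, n, replace = TRUE) - 1L)
      S <- matrix(root, n, 4)
      if (nrow(ev$states)) S[ev$site, ] <- ev$states
      nt <- c("A", "C", "G", "T")
      fasta_acc[[ci]] <- vapply(1:4, function(t)
        paste(nt[S[, t] + 1L], collapse = ""), "")
      rm(S)
    }
    rm(ev, lab, trees)
  }

  locus_per_block <- tabulate(block_of, n_blocks)
  end_bp <- cumsum(locus_per_block) * bp
  out <- data.frame(block_id = seq_len(n_blocks),
                    start_bp = c(0, end_bp[-n_blocks]),
                    end_bp = end_bp,
                    n_abba = counts[, 1], n_baba = counts[, 2],
                    n_bbaa = counts[, 3])
  attr(out, "total_sites") <- L * bp
  attr(out, "scenario") <- sc
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("block_counts", "data.frame")

  if (!is.null(emit_fasta)) {
    seqs <- vapply(1:4, function(t)
      paste(vapply(fasta_acc[seq_len(ci)], `[`, "", t), collapse = ""), "")
    names(seqs) <- c("P1", "P2", "P3", "O")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), emit_fasta)
  }
  out
}
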