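#' Closed-form ABBA-BABA frequency difference without introgression
#'
#' Evaluates the analytic expression for P(ABBA) - P(BABA) under the
#' no-introgression MSci + JC69 model when only the P1 lineage deviates
#' from the reference rate:
#' (3/16) * (1 - exp(-(4/3)(lambda-1) tau1)) / (1 + 4 theta/3) *
#' (exp(-8 tau2/3) - exp(-8 tau3/3)).
#' The sign equals the sign of lambda - 1: the faster sister lineage gains
#' homoplasic sharing with the outgroup, inflating ABBA.
#'
#' @param p An [msci_params()] object with \code{gamma = 0} and
#'   \code{lambda_p3 = lambda_o = 1}; other settings are outside the
#'   formula's domain and raise an error.
#' @return The expected per-site frequency difference (numeric scalar).
#' @export
abba_baba_diff_eq1 <- function(p) {
  stopifnot(inherits(p, "msci_params"))
  if (p$gamma != 0)
    stop("closed form requires gamma = 0", call. = FALSE)
  if (p$lambda_p3 != 1 || p$lambda_o != 1)
    stop("closed form requires unit rates on P3 and O", call. = FALSE)
  lam <- p$lambda_p1
  (3 / 16) * (1 - exp(-(4 / 3) * (lam - 1) * p$tau1)) /
    (1 + 4 * p$theta / 3) *
    (exp(-8 * p$tau2 / 3) - exp(-8 * p$tau3 / 3))
}

#' Expected D-statistic under the MSci + JC69 model
#'
#' D = (P(ABBA) - P(BABA)) / (P(ABBA) + P(BABA)) evaluated on the exact
#' expected pattern frequencies from [pattern_freqs()].
#'
#' @param p An [msci_params()] object.
#' @return Expected D in (-1, 1).
#' @export
expected_D <- function(p) {
  pf <- pattern_freqs(p)
  s <- pf$p_abba + pf$p_baba
  if (s <= 0) stop("ABBA and BABA frequencies are both zero; D undefined",
                   call. = FALSE)
  (pf$p_abba - pf$p_baba) / s
}

# the tau-family used throughout the depth analyses: tau1 = tau,
# tau2 = 2 tau, tau3 = 3 tau, no introgression
.tau_family <- function(tau, theta, lambda_p1) {
  msci_params(tau1 = tau, tau2 = 2 * tau, tau3 = 3 * tau, theta = theta,
              lambda_p1 = lambda_p1)
}

#' Phylogenetic depth at which expected D reaches a target value
#'
#' Along the depth family tau1 = tau, tau2 = 2 tau, tau3 = 3 tau (no
#' introgression), finds by bracketed root-finding the tau at which the
#' expected D-statistic equals \code{target_D}. Monotonicity of D over the
#' bracket is checked numerically before solving.
#'
#' @param theta Scaled population size.
#' @param lambda_p1 Rate multiplier of P1.
#' @param target_D Target expected D (nonzero; a zero target is degenerate
#'   since it holds for every tau when lambda_p1 = 1).
#' @param bracket Search interval for tau.
#' @param tol Required accuracy on |expected_D(tau) - target_D|.
#' @return The solution tau (mutation units).
#' @export
tau_for_target_D <- function(theta, lambda_p1, target_D,
                             bracket = c(1e-4, 1e-2), tol = 1e-6) {
  if (target_D == 0)
    stop("target D = 0 is degenerate for this family", call. = FALSE)
  f <- function(tau) expected_D(.tau_family(tau, theta, lambda_p1)) - target_D
  flo <- f(bracket[1]); fhi <- f(bracket[2])
  if (is.na(flo) || is.na(fhi) || flo * fhi > 0)
    stop("expected_D - target does not change sign over the bracket",
         call. = FALSE)
  fmid <- f(sqrt(prod(bracket)))
  if (!(fmid >= min(flo, fhi) - abs(target_D) && fmid <= max(flo, fhi) + abs(target_D)))
    stop("expected_D does not appear monotone over the bracket", call. = FALSE)
  r <- stats::uniroot(f, interval = bracket, tol = bracket[1] * 1e-8)
  if (abs(r$f.root) > tol)
    stop("root-finding did not reach the requested accuracy", call. = FALSE)
  r$root
}

#' Expected D along a sequence of parameter sets
#'
#' Evaluates [expected_D()] along a list of parameter sets, typically a
#' sequence approaching the extreme regime (tau1, tau2 -> 0 with
#' lambda*tau1 and tau3 large, theta small) in which D approaches 1.
#'
#' @param ps A list of [msci_params()] objects.
#' @return The expected D at the final element, with the full path attached
#'   as attribute \code{"path"}.
#' @export
limit_D <- function(ps) {
  stopifnot(is.list(ps), length(ps) >= 1L)
  d <- vapply(ps, expected_D, numeric(1))
  structure(d[length(d)], path = d)
}

#' JC69 site-pattern probabilities on a fixed four-taxon gene tree
#'
#' Independent small-scale oracle: for a fixed rooted gene-tree shape with
#' given branch lengths (expected substitutions per site), computes the
#' probability of the ABBA, BABA and BBAA site patterns by direct summation
#' over internal states under JC69 with a uniform root state. The tree is
#' given by the two coalescence events below the root.
#'
#' @param first_pair Integer vector of the two tips (1 = P1 ... 4 = O)
#'   joined by the first (lowest) coalescence.
#' @param second_pair The two lineages joined next: tip numbers, or 5 for
#'   the node created by the first event. The root joins whatever remains.
#' @param blen Named numeric vector of branch lengths with entries
#'   \code{t1..t4} (tip branches), \code{n5} (first node to its parent) and
#'   \code{n6} (second node to the root).
#' @return Named numeric vector with elements abba, baba, bbaa.
#' @export
jc69_site_pattern_prob <- function(first_pair, second_pair, blen) {
  ptrans <- function(l) {
    same <- 0.25 + 0.75 * exp(-4 * l / 3)
    diff <- (1 - same) / 3
    matrix(diff, 4, 4) + diag(rep(same - diff, 4))
  }
  Pt <- lapply(1:4, function(i) ptrans(blen[[paste0("t", i)]]))
  P5 <- ptrans(blen[["n5"]])
  balanced <- !(5 %in% second_pair)
  P6 <- ptrans(blen[["n6"]])

  # straightforward nested-sum implementation (4^3 terms at most)
  tips <- 1:4
  rest <- setdiff(tips, first_pair)
  res <- c(abba = 0, baba = 0, bbaa = 0)
  pats <- list(abba = c(1, 2, 2, 1), baba = c(2, 1, 2, 1),
               bbaa = c(2, 2, 1, 1))
  for (nm in names(pats)) {
    st <- pats[[nm]]
    tot <- 0
    for (r in 1:4) {
      if (balanced) {
        # shape ((first_pair), (second_pair)) with node6 = second_pair
        m5 <- 0; m6 <- 0
        for (u in 1:4) {
          m5 <- m5 + P5[r, u] *
            Pt[[first_pair[1]]][u, st[first_pair[1]]] *
            Pt[[first_pair[2]]][u, st[first_pair[2]]]
        }
        for (v in 1:4) {
          m6 <- m6 + P6[r, v] *
            Pt[[second_pair[1]]][v, st[second_pair[1]]] *
            Pt[[second_pair[2]]][v, st[second_pair[2]]]
        }
        tot <- tot + 0.25 * m5 * m6
      } else {
        # caterpillar: node5 = first_pair, node6 = (node5, other), root =
        # (node6, last)
        other <- setdiff(second_pair, 5)
        last <- setdiff(rest, other)
        m <- 0
        for (v in 1:4) {        # state of node6
          inner <- 0
          for (u in 1:4) {      # state of node5
            inner <- inner + P5[v, u] *
              Pt[[first_pair[1]]][u, st[first_pair[1]]] *
              Pt[[first_pair[2]]][u, st[first_pair[2]]]
          }
          m <- m + P6[r, v] * inner * Pt[[other]][v, st[other]]
        }
        tot <- tot + 0.25 * m * Pt[[last]][r, st[last]]
      }
    }
    # 12 ordered nucleotide pairs realise each pattern; states above use a
    # representative pair (1, 2)
    res[nm] <- 12 * tot
  }
  res
}
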