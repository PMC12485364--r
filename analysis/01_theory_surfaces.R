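#!/usr/bin/env Rscript
# Exact theory: how much apparent introgression signal (expected D) does
# lineage rate variation create under the MSci + JC69 model, and how does
# it scale with phylogenetic depth, population size and outgroup distance?
# Writes anchor values and small curve tables under results/.

suppressPackageStartupMessages(library(homoplasyD))
dir.create("results", showWarnings = FALSE)

depth_family <- function(tau, theta, lambda)
  msci_params(tau, 2 * tau, 3 * tau, theta, lambda_p1 = lambda)

## Anchors of the depth curve (theta = 1e-3, lambda_P1 = 1.5):
anchors <- data.frame(
  tau = c(1e-3, 3e-3, 1e-2),
  D = vapply(c(1e-3, 3e-3, 1e-2),
             function(tau) expected_D(depth_family(tau, 1e-3, 1.5)),
             numeric(1)))
cat("Expected D along the depth curve (theta=1e-3, lambda=1.5):\n")
print(transform(anchors, D = round(D, 4)))
cat("A 50% rate acceleration of P1 alone pushes expected D from ~0.006\n",
    "at tau = 1e-3 to ~0.063 at tau = 1e-2 -- without any gene flow.\n")

## Depth required for D = 0.05 at two population sizes:
tau_needed <- data.frame(
  theta = c(1e-3, 2e-4),
  tau_at_D05 = c(tau_for_target_D(1e-3, 1.5, 0.05),
                 tau_for_target_D(2e-4, 1.5, 0.05)))
cat("\nDepth tau at which D reaches 0.05 (lambda = 1.5):\n")
print(tau_needed)
cat("Small populations (theta = 2e-4) hit D = 0.05 at a 4x shallower",
    "depth:\nILS dilutes the homoplasy asymmetry, so less ILS means more",
    "spurious D.\n")

## Depth x rate surface (reduced grid):
grid <- expand.grid(tau = 10^seq(-3.5, -2, length.out = 7),
                    lambda = c(0.67, 1, 1.2, 1.5, 2))
grid$D <- mapply(function(tau, l) expected_D(depth_family(tau, 1e-3, l)),
                 grid$tau, grid$lambda)
write.table(grid, "results/theory_depth_surface.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## Outgroup-distance curve (tau1 = 1e-3, tau2 = 2e-3 fixed):
og <- data.frame(tau3_minus_tau2 = c(5e-4, 1e-3, 2e-3, 5e-3, 1e-2, 2e-2))
og$D <- vapply(og$tau3_minus_tau2, function(gap)
  expected_D(msci_params(1e-3, 2e-3, 2e-3 + gap, 1e-3, lambda_p1 = 1.5)),
  numeric(1))
write.table(og, "results/theory_outgroup_curve.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nExpected D rises monotonically with outgroup distance",
    "(results/theory_outgroup_curve.tsv):\n")
print(transform(og, D = round(D, 4)))

## Introgression case: with gamma > 0 and clock rates, D is negative;
## rate acceleration of P1 can cancel or reverse it.
intro <- expand.grid(lambda = c(1, 1.2, 1.5, 2), tau = c(5e-4, 1e-3, 2e-3))
intro$D <- mapply(function(l, tau)
  expected_D(msci_params(tau, 2 * tau, 3 * tau, 1e-3, gamma = 0.05,
                         tau_g = 0.95 * tau, lambda_p1 = l)),
  intro$lambda, intro$tau)
write.table(intro, "results/theory_introgression_surface.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nWith a true P1->P3 introgression (gamma = 0.05), accelerating P1",
    "\nshifts D from negative toward zero and beyond",
    "(results/theory_introgression_surface.tsv).\n")

write.table(cbind(anchors, what = "depth_anchor"),
            "results/theory_anchors.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
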