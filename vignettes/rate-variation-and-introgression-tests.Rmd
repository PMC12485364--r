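---
title: "How lineage rate variation misleads site-pattern tests for introgression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How lineage rate variation misleads site-pattern tests for introgression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homoplasyD)
```

## The problem

Site-pattern tests for introgression — Patterson's D (the ABBA–BABA test)
and HyDe-style tests — rest on a symmetry argument: on the asymmetric
species tree (((P1,P2),P3),O), incomplete lineage sorting (ILS) produces
the two discordant biallelic site patterns ABBA and BABA in equal expected
numbers, so an excess of one over the other is read as gene flow. The
argument implicitly assumes a molecular clock and at most one mutation per
site. When one sister lineage evolves faster than the other, *homoplasy*
(independent identical mutations on different branches) no longer cancels
between ABBA and BABA: the slower sister shares more derived states with
P3, and the faster sister shares more with the (necessarily long) outgroup
branch. The imbalance mimics introgression.

`homoplasyD` quantifies this failure mode at shallow phylogenetic depths:
it computes **exact** expected frequencies of ABBA, BABA and BBAA under
the multispecies coalescent with introgression (MSci) and Jukes–Cantor
(JC69) substitution with per-lineage rate multipliers, simulates
genome-scale data under the same model, and applies the block-jackknife D
test, a HyDe-style test, and the relative rate test.

## Model and parameterisation

The species tree is (((P1,P2),P3),O) with divergence times
$\tau_1 < \tau_2 < \tau_3$ and introgression time $\tau_g < \tau_1$, all
in expected mutations per site at the reference rate ($\tau = T\mu$);
the scaled population size is $\theta = 4N\mu$, equal in all populations.
An episodic P1$\to$P3 introgression event means the sampled P3 lineage
traces back through P1's population with probability $\gamma$. Each
terminal lineage $i \in \{P1, P3, O\}$ carries a relative substitution
rate $\lambda_i > 0$; P2 and all ancestral branches have rate 1.

Two unit conventions deserve explicit statement, because the simulation
grid quotes population sizes as "2N":

* **"2N" is the number of haploid gene copies.** The pairwise coalescent
  rate is $1/(2N)$ per generation and $\theta = 2\,(2N)\,\mu$. This
  reading was confirmed against the analytic depth-curve anchor: with
  $T_S = T_I = T_O = 10^5$ generations, $2N = 10^4$, $\mu = 2\times
  10^{-8}$ and $\lambda_{P1} = 1.5$, theory gives expected $D = 0.060$
  and simulations a mean $D \approx 0.063$; the diploid-individuals
  reading would double $\theta$ and visibly shrink $D$.
* **Rate multipliers attach to populations, not to gene-tree branches in
  the abstract.** A gene-tree segment resident in population `pop` for a
  duration $t$ accrues $\lambda_{pop}\, t\, \mu$ expected substitutions.
  Genealogical dynamics are untouched: in reference time the coalescent
  rate is $2/\theta$ in every population. Describing P1's branch in its
  own mutation-length coordinates stretches it to $\lambda\tau_1$ with
  population size $\lambda\theta$ — the same model in different
  coordinates. We apply the same rule to any rate-multiplied terminal
  population; for P3 and O this is moot here (they never host two
  lineages), but an introgressed lineage sitting in P1's population does
  mutate at $\lambda_{P1}$.

## Exact pattern frequencies without enumeration

Closed-form expressions exist for the ABBA–BABA *difference* when
$\gamma = 0$ and only P1 deviates from the clock:

$$P(\mathrm{ABBA}) - P(\mathrm{BABA}) =
\frac{3}{16}\,
\frac{1 - e^{-\frac{4}{3}(\lambda-1)\tau_1}}{1 + 4\theta/3}
\left(e^{-8\tau_2/3} - e^{-8\tau_3/3}\right),$$

implemented in `abba_baba_diff_eq1()`. The individual pattern
probabilities (and everything with $\gamma > 0$ or several non-unit
$\lambda$) require integrating JC69 transition products over all
coalescent histories. Rather than enumerating histories and quadrature,
`pattern_freqs()` uses a linear-algebra formulation:

* Fix a representative ordered nucleotide pair $(x, y)$, $x \neq y$; by
  JC69 symmetry each pattern probability is 12 times the probability of
  its representative assignment.
* Going backward in time, each ancestral lineage carries a conditional
  likelihood message for the tip states below it. Under JC69, messages
  stay in the 3-dimensional space spanned by $\{\mathbf{1}, e_x, e_y\}$.
* The expectation of the tensor product of all messages, jointly with the
  partition of tips into lineages, evolves **linearly**: mutation acts
  factor-wise through a $3\times 3$ generator, and a coalescence (rate
  $2/\theta$ per pair within a population) is a linear map that combines
  two factors through their Hadamard product.
* Each inter-node epoch of the species network therefore has a constant
  generator on a 309-dimensional space (15 partitions of four tips, 3
  dimensions per lineage), and propagation is a matrix exponential
  (`Matrix::expm`). The infinite root epoch is resolved exactly by an
  absorption solve: the reporting functional is invariant on the
  single-lineage class, so the answer is
  $f^\top X_A + f^\top G_{AT}(-G_{TT})^{-1} X_T$.

The result is exact up to numerical linear algebra (matrix exponentials
of modest, well-scaled matrices), typically agreeing with the closed form
to $10^{-12}$ or better; the test suite asserts $10^{-8}$ over random
parameter sweeps and cross-checks five parameter sets against Monte-Carlo
simulation ($10^7$ sites each, 3 binomial SE). Degenerate inputs are
handled structurally: zero-length epochs are skipped, $\tau_2 = \tau_3$
is allowed (and yields $D = 0$), and extreme regimes (e.g.
$\theta = 10^{-8}$, $\tau_3 = 10$) only make the exponentials stiffer,
which scaling-and-squaring absorbs.

`expected_D()` is the ratio $(P_{ABBA}-P_{BABA})/(P_{ABBA}+P_{BABA})$;
`tau_for_target_D()` brackets and solves $D(\tau) = D^\ast$ on the depth
family $\tau_1 = \tau, \tau_2 = 2\tau, \tau_3 = 3\tau$ after a numeric
monotonicity check, with `uniroot` to an effective $|D - D^\ast| <
10^{-6}$.

## The simulator

`sim_dataset()` emulates the study conditions: a genome of independent
100-bp loci (free recombination between loci, none within), one haploid
sample per taxon, JC69 mutation at $\mu = 2\times 10^{-8}$ per site per
generation, and per-population rate multipliers. Its defaults mirror the
simulation grid (Table-1 semantics via `table1_cells()`); genome size is
the only axis routinely reduced, because expected pattern *frequencies*
are genome-size-free — genome size only matters for test significance.

Internals, for the record:

* Gene trees for ~2&times;10^4 loci at a time are drawn by masked vector
  operations over the epoch structure of the species network; the
  introgression jump is a per-locus Bernoulli($\gamma$) at $T_G$.
* Site states are simulated **sparsely**: per locus and branch the number
  of sites with a net JC69 substitution is Binomial($100, p$) with
  $p = \tfrac{3}{4}(1 - e^{-4\ell/3})$; only hit sites (about 1% at these
  depths) have their states propagated. All unhit sites are invariant and
  classify as OTHER, so block counts are unaffected. This is what makes
  hundred-genome acceptance runs take minutes.
* The FASTA path reconstructs the full alignment from the same sparse
  states, drawing invariant-site root states from an isolated RNG stream;
  counts are therefore bit-identical whether or not FASTA is emitted, and
  re-counting the FASTA with `count_patterns()` reproduces the fast-path
  counts exactly (asserted in the suite).
* Reproducibility: one seed per dataset fully determines the stream
  (`derive_seed(master, ...)` gives sub-2^31 per-replicate seeds); the
  internal chunk size is a fixed constant for the same reason.

`time_shift_transform()` implements the equivalent uniform-rate
construction for a single non-unit tip rate and $\gamma = 0$: for
$\lambda > 1$ on a terminal branch of length $B$, divergence times shift
into the past by $(\lambda-1)B$, the affected tip is sampled at the
present and all others $(\lambda-1)B$ generations ago (for $\lambda < 1$,
the affected tip is sampled $(1-\lambda)B$ ago instead). With
introgression the construction cannot reproduce both the residence time
and the mutation length of the migrated lineage, so the transform refuses
$\gamma > 0$; the direct population-rate scaling is the primary path
throughout.

## Tests

* `d_test()`: $D = (N_{ABBA}-N_{BABA})/(N_{ABBA}+N_{BABA})$ with a
  delete-one block jackknife over contiguous genome blocks (default 100
  per genome), $z = D/SE$, normal two-sided $p$, significance at
  $\alpha = 0.01$. $D > 0$ is reported as P2&harr;P3, $D < 0$ as
  P1&harr;P3. The block size is a free choice — the block count is
  configurable and, at these shallow depths where informative sites are
  sparse and effectively unlinked, results are insensitive to it.
* `hyde_jk_test()`: identifies the two least frequent of the three
  informative-pattern totals (ties broken in the fixed order BABA, ABBA,
  BBAA), jackknifes their normalised difference, and on significance
  names the hybrid as the ingroup taxon absent from the smallest
  pattern's sharing pair. This is a jackknife equality test built on the
  operating principle of HyDe, not a re-implementation of the HyDe
  software's invariant statistic; published rejection rates for the
  latter may differ slightly.
* Both tests use two-sided normal p-values; the threshold convention is
  switchable (`alternative` argument on `d_test`).
* `relative_rate_test()`: JC69-corrected triplet distances give tip
  branch lengths $a = (d_{12}+d_{1O}-d_{2O})/2$,
  $b = (d_{12}+d_{2O}-d_{1O})/2$ and the rate difference
  $|a-b|/\max(a,b)$ (so multipliers $x$ and $1/x$ both give $1 - 1/x$).
  The clock z-test uses a delta-method variance of $d_{1O}-d_{2O}$ with
  the shared-outgroup covariance term. The variance estimate is a
  standard large-sample choice, not a replication of any published
  variance formula; the rate difference itself does not depend on it.

In introgression summaries (`summarize_records()`), a significant D test
naming P1–P3 counts as power; for the HyDe-style test we count P3-hybrid
calls as correct, so the characteristic misassignment of P1 as the hybrid
under P1$\to$P3 gene flow is tallied as a false positive.

## What the synthetic data does and does not emulate

The generator reproduces the model assumptions exactly — which is the
point: it isolates the rate-variation artifact. Real genomes differ in
ways that matter for the tests: intra-locus linkage and recombination
hotspots, mutation-rate heterogeneity along the genome, selection,
non-JC69 substitution dynamics, unequal and time-varying population
sizes, sequencing and alignment error, and multiple samples per species.
Passing tests therefore demonstrate correctness of the implementation and
the internal consistency of theory and simulation, not that real data
meet the model. In particular the block jackknife is exactly calibrated
here because informative sites are genuinely independent between loci;
with real linkage the block size becomes consequential.

## Problem sizes

Defaults are desk-scale, chosen once: 10-Mb genomes with 20 replicates
for mean-D grids (means are genome-size-free; at 10 Mb a replicate holds
a few hundred informative sites), 100 jackknife blocks, and $10^7$ sites
per parameter set for simulation-vs-theory checks. The acceptance script
uses 200 replicates of 20-Mb genomes per cell so the Monte-Carlo SE of a
reported mean D is ≈0.004 and the small finite-count bias of the
per-replicate ratio stays below that. Where a check compares a replicate
mean against theory at 3 Monte-Carlo SE, the SE uses the larger of the
empirical replicate SD and the parametric SD implied by the
theory-expected informative-site count, because a 20-replicate SD
estimate is itself noisy. False-positive *rates* at the
published 100–500 Mb scale are not asserted; the suite instead checks the
desk-scale signatures: calibration at $\alpha$ under a clock, monotone
growth of the FP rate with genome size, and the sign conventions linking
$\lambda \gtrless 1$ to the inferred introgression pair and hybrid.

## Known limitations

* JC69 only; no other substitution models, no indels, no rate variation
  among sites.
* Four taxa, one haploid sample each; no ghost lineages; a single
  episodic introgression edge (P1$\to$P3).
* Equal $\theta$ across populations.
* The HyDe-style test approximates the published tool's behaviour at the
  level of its defining principle (see above).
* `limit_D()` documents the analytic limit $D \to 1$ (long P1 and O,
  $\theta \ll 1$); convergence is monotone along admissible paths where
  $\tau_1$ decreases with $\lambda\tau_1$ held large, and the function
  checks the supplied sequence rather than constructing one.
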