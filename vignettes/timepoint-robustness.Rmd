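---
title: "Inferring lag-1 regulatory networks and measuring time-point importance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring lag-1 regulatory networks and measuring time-point importance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagnet)
```

## The problem

Short expression time courses — a dozen microarray or RNA-seq samples along a
diurnal cycle, a stress response, a developmental window — are the raw
material for reconstructing directed gene regulatory networks. Each sampled
time point is expensive, so experimenters face a design question that is
usually answered by habit: *which time points actually matter for the network
you will infer?* `lagnet` addresses that question operationally. It provides
a lag-1 dynamic-Bayesian-network estimator for the network itself, and a
perturbation harness that deletes time points one at a time (or in adjacent
pairs), re-fits the network on what remains, and quantifies the damage with a
panel of graph statistics, a relative diversity score, and edge-level
confusion and overlap measures.

## The model and the estimator

The data model is a first-order linear dynamical system on p genes. Writing
`x(t)` for the vector of expression values at the t-th retained observation,

    x(t) = b + A x(t-1) + e(t),     e(t) ~ N(0, sigma^2 I),

the directed regulatory network is the support of the p x p coefficient
matrix `A`: gene j regulates gene i when `A[i, j] != 0`. Unrolled over time
this is the standard lag-1 dynamic Bayesian network; collapsing the unrolled
edges onto the gene set yields a directed graph that may legitimately contain
cycles and feedback loops, which static Bayesian networks forbid.

One deliberate approximation deserves emphasis. Sampling designs like
`0, 1, 2, 4, 8, 12, 13, 14, 16, 20, 24` hours are irregular, and deleting a
time point makes them more so. `lagnet` treats **successive retained
observations as unit-lag transitions** regardless of the wall-clock gap
between them: `build_transitions()` simply pairs column k with column k + 1.
This is what makes a network fitted to a deletion-shortened series directly
comparable to the full-data fit — both are estimates of "dependence between
consecutive samples" — but it also means the coefficient estimates are not
rates per hour, and a gene whose dynamics are much faster than the local
sampling interval will be aliased. The deletion experiment itself inherits
this convention: deleting a point collapses the time axis rather than
widening a gap.

Structure learning follows the dependence-based (rather than
search-and-score) route, in two stages:

1. **Conditional-dependence screening** (`score_step1()`). For each ordered
   pair j -> i the score is the *largest* two-sided p-value of j's lagged
   coefficient across all bivariate regressions of i's responses on
   `{1, lagged j, lagged z}`, z ranging over the other genes. Taking the
   worst case over single conditioners means an edge survives only if no
   single third gene can explain it away; it also makes the scores
   deliberately conservative (stochastically larger than uniform under the
   null), which the test suite checks by Monte-Carlo calibration. Edges with
   score at most `alpha1` become candidates.
2. **Joint pruning** (`prune_step2()`). Each target is regressed once on all
   of its candidate parents together, and an edge is kept only if its
   coefficient's p-value is at most `alpha2`.

The defaults are a permissive screen and a strict prune: `alpha1 = 0.5`,
`alpha2 = 0.05`. Both are ordinary arguments of `grn_fit()`; there is
nothing canonical about them, and analyses of real data should report them
alongside the network. The estimator is ordinary least squares throughout
(`estimator: ols` in pipeline configs); all p-values come from the exact
t distribution with the appropriate residual degrees of freedom, which is
why at least five time points (four transitions) are required.

### Numerical conventions and degenerate inputs

* A predictor with zero variance across transitions scores 1 ("no
  evidence") with a warning instead of erroring — degenerate subsets appear
  routinely inside the deletion loop and must not abort a sweep.
* Collinear conditioning designs are skipped; if every conditioner is
  unusable the simple-regression p-value is used.
* If a target accumulates more candidate parents than the transition count
  can support (more than T - 3), parents are ranked by their screening score
  and truncated to fit, with a warning. This happens mostly on the shortest
  deletion entries.
* Exact fits (zero residual variance, possible on noise-free synthetic
  input) yield p-value 0 for nonzero coefficients and 1 for zero ones.
* Self-regulation is excluded by default — both from scoring and from the
  pair universe of the comparison module, which read the same switch — and
  can be restored with `allow_self = TRUE`.

## The statistics panel

`network_summary()` assembles, for any network over the full gene panel
(isolated genes included): average degree `K = 2 Rn / N`, diameter `Dia`,
average path length `l`, isolated-node count `N0`, edge count `Rn`, global
efficiency `E`, maximum vulnerability `Vu`, clustering coefficient `CC` and
degree centralization `Ce`.

Two conventions were genuinely open and are fixed as follows. Path-based
quantities (`Dia`, `l`, `E`, betweenness, `Vu`) are computed on the
**directed** graph, since a regulatory network is directed and a path
through it is a causal chain. Unreachable ordered pairs contribute zero to
`E` and are excluded from `l`'s average — on a sparse 800-gene network most
pairs are unreachable, and any other convention makes `l` infinite.
`CC` (the global transitivity, 3 x triangles / connected triples) and
Freeman degree centralization `Ce` (normalised by `(N-1)(N-2)` so a star
scores 1) are computed on the **undirected projection**, because triplet
counting and the star calibration are undirected constructs. Vulnerability
is the worst relative efficiency loss over single-node deletions,
`Vu = max_i (E - E_i)/E`, and is 0 when `E = 0`.

Degree distributions are summarised by a least-squares line on
`(log10 degree, log10 count)` over positive degrees (`fit_power_law()`);
its R² is the "goodness of power-law fit" used to rank networks. This is
the conventional quick scale-free check, not a maximum-likelihood tail fit,
and it is kept deliberately simple because it is only used comparatively
across networks that share a panel.

## The deletion experiment and the diversity score

`standard_design(T)` enumerates the reference entry G0 (nothing deleted),
the single deletions G1..GT, and any requested adjacent pairs (labelled
e.g. `G2_3`). `run_experiment()` re-fits each entry at the same thresholds
and stacks the statistics rows into a table with two extra rows: `ave`, the
per-column mean, and `d_score`, the relative diversity score

    d = sum_k |Q_k - ave| / ave,

where `Q_k` is one statistic on network `G_k`. A low score marks a
statistic that is insensitive to which time point was dropped — a robust
readout of the data — while a high score marks a fragile one. The score is
invariant to positive rescaling of the statistic, so exactly proportional
columns (K and Rn on a fixed panel) always agree; the test suite checks
this identity and also that the formula reproduces, to three decimals, the
published centralization diversity score (4.6882) of the 800-gene
Arabidopsis diurnal reference table shipped in `inst/extdata/`. Several
other published d_score values in that table are not reproduced by this (or
any simple) formula and are therefore carried as printed reference values
only, not as checks. Entries whose deletion leaves fewer than 5 time points
are recorded as failed rather than aborting the sweep, and the score is
reported as undefined for zero-mean columns.

Networks are compared at the edge level with `G0` as the standard:
`edge_confusion()` classifies every ordered gene pair (the universe is
`p(p-1)` pairs without self-loops), and `classification_metrics()` turns
the counts into sensitivity, precision and F-measure, each defined as 0
when its denominator vanishes so that sweep tables stay numeric.
`edge_overlap()` and `common_regulations()` aggregate edge occurrence
across the whole collection — the regulations present in all or nearly all
deletion networks are the ones insensitive to the measurement design.

## The synthetic-data generator

`generate_ground_truth()` and `simulate_expression()` exist so every stage
is testable end-to-end with a known answer. The generator draws a directed
Erdős–Rényi structure with an expected edge count, coefficients of
magnitude uniform in `coeff_range` with random sign, rescales to spectral
radius 0.95 if needed (stationarity), and simulates the VAR(1) recursion
from standard-Gaussian initial states with i.i.d. Gaussian innovations.
The defaults were chosen once to emulate the shape of the 800-gene diurnal
study that motivates the package: `expected_edges = round(0.56 p)` (447
regulations among 800 genes), `coeff_range = c(0.5, 1)`, `noise_sd = 0.5`,
and the 11-point design `0, 1, 2, 4, 8, 12, 13, 14, 16, 20, 24` h.

The generator matches the estimator's assumptions exactly — linear,
Gaussian, lag-1, stationary. That is intentional: it makes structure
recovery a meaningful acceptance surface (if the estimator cannot recover a
planted linear network from clean data, something is wrong). It also means
passing tests say nothing about nonlinear regulation, unobserved
confounders, measurement-specific noise, normalisation artefacts or
non-stationarity in real microarray data; results on real input depend
strongly on upstream preprocessing, which the loader deliberately does not
attempt (`read_series()` applies no transformation).

## Problem sizes used by the test suite

The suite verifies every graph statistic against brute-force oracles
(Floyd–Warshall distances, exhaustive geodesic enumeration, triple
counting, per-node efficiency recomputation) on random digraphs of up to 8
nodes, and every regression p-value against independent `lm()` fits to 10
significant digits. The simulation-based checks run at deliberately modest
scale: structure recovery uses 20 genes x 50 time points over 20 seeds
(median F-measure against the planted truth at least 0.7), and the
deletion-damage ordering — adjacent-pair deletions hurt at least as much as
the corresponding single deletions, on average — uses 50 genes x 11 time
points over 10 seeds. The full 800-gene scale is exercised only for
generation, simulation shape and degree arithmetic.

## Limitations

* Equal-spacing approximation: coefficients are per retained step, not per
  hour; strongly irregular designs blur their interpretation.
* The screening stage is O(p³) regressions; 800 genes is comfortable on a
  desktop, tens of thousands of genes is not the intended regime.
* The two thresholds are not calibrated to a false-discovery rate; the
  max-over-conditioners score is conservative, so screened p-values cannot
  be reused as nominal p-values.
* Edge comparison is strict on direction: a reversed edge counts as both a
  false positive and a false negative.
* The published reference table is used for arithmetic consistency checks
  only; reproducing the original 447-edge network would require the raw
  microarray data and the original (unpublished) threshold settings.
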