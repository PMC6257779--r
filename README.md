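# lagnet

Lag-1 dynamic-Bayesian-network inference for gene regulatory networks, with
a harness for measuring how much each sampled time point contributes to the
reconstruction.

## What it is for

Regulatory networks inferred from short expression time courses depend on
the sampling design: drop one time point and the inferred edge set, the
degree distribution and the graph statistics all move. `lagnet` is for
computational biologists who want to (a) reconstruct a directed gene
network from a genes × time-points expression matrix, and (b) find out
which time points the reconstruction actually relies on, and which network
statistics are robust to the design.

The core model is a first-order linear dynamical system on p genes,

    x(t) = b + A x(t−1) + e(t),    e(t) ~ N(0, σ² I),

whose support `A[i, j] ≠ 0` is the directed network (gene j regulates gene
i). Structure is learned by the dependence-based two-step route:

1. **Screen** — score each ordered pair j → i with the *maximum* p-value of
   j's lagged coefficient over all regressions `x_i(t) ~ 1 + x_j(t−1) +
   x_z(t−1)`, z ranging over single conditioning genes; keep pairs with
   score ≤ α₁ (default 0.5).
2. **Prune** — regress each target on all its candidate parents jointly and
   keep edges with coefficient p-value ≤ α₂ (default 0.05).

Around the estimator the package provides a VAR(1) simulator with known
ground truth, the statistics panel K, Dia, l, N0, Rn, E, Vu, CC, Ce,
power-law degree-distribution fits, a systematic time-point-deletion
experiment with a relative diversity score `d = Σ|Q_k − ave| / ave`,
sensitivity/precision/F-measure comparison of each deletion network against
the full-data reference, and cross-network edge-overlap tables.

## Worked example

```r
library(lagnet)

# a 30-gene ground truth and an 11-point diurnal series simulated from it
truth  <- generate_ground_truth(p = 30, expected_edges = 35,
                                noise_sd = 0.3, seed = 101)
series <- simulate_expression(truth, seed = 102)   # 0,1,2,4,8,12,13,14,16,20,24 h

fit <- grn_fit(series)          # alpha1 = 0.5, alpha2 = 0.05
fit
#> Lag-1 regulatory network fit
#> Call: grn_fit(series = series)
#> 30 genes, 11 time points, alpha1 = 0.5, alpha2 = 0.05
#> Inferred regulations: 24
```

`summary(fit)` appends the statistics panel:

```r
summary(fit)
#> Network statistics panel:
#>  label   K Dia     l N0 Rn       E     Vu CC      Ce
#>    fit 1.6   5 1.857  4 24 0.03921 0.1835  0 0.08867
```

With only 10 transitions the fit recovers part of the planted structure
(here sensitivity 0.20, precision 0.33 against `truth_network(truth)`);
this is exactly the data-poverty regime the deletion experiment probes.

```r
res <- run_experiment(series, standard_design(11, pairs = list(c(9, 10))))
print(res$stats_table[c(1:3, 13:15), c("label", "K", "Dia", "Ce", "Rn", "Vu")],
      digits = 3)
#>      label    K  Dia     Ce    Rn    Vu
#> 1       G0 1.60 5.00 0.0887 24.00 0.183
#> 2       G1 1.33 4.00 0.0985 20.00 0.231
#> 3       G2 0.80 3.00 0.1182 12.00 0.250
#> 13   G9_10 1.93 8.00 0.1158 29.00 0.314
#> 14     ave 1.39 4.85 0.1139 20.85 0.289
#> 15 d_score 2.38 3.27 2.4493  2.38 2.691
```

Each `G_k` row is the panel of the network re-fitted without the k-th time
point (`G9_10` drops two adjacent points); `ave` is the column mean and
`d_score` the relative diversity score — low for statistics that are
insensitive to the sampling design (K and Rn always share a score, being
proportional), high for fragile ones. Edge-level damage is quantified
against the full-data network:

```r
head(compare_collection(res), 3)
#>   label sensitivity precision f_measure
#> 1    G0       1.000     1.000     1.000
#> 2    G1       0.625     0.750     0.682
#> 3    G2       0.208     0.417     0.278
```

and `edge_overlap()` / `common_regulations()` list the regulations present
in (nearly) every deletion network — the design-insensitive core.
`run_pipeline(list(seed = 1, outdir = "out"))` runs the whole chain
(simulate → sweep → statistics → comparison → overlap) and writes every
artifact as diffable text.

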