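# ctdsnet

Directed coupling networks for multichannel time series by **time delay
stability** (TDS) and its **controlled** extension (CTDS).

Physiological systems — cortical rhythms, heart rate, respiration — interact
as a network, and a robust nonparametric way to quantify one pairwise
interaction is to ask whether the delay at which two signals are maximally
correlated stays constant over time. Concretely, both signals are cut into
half-overlapping windows of length *L*, each window is normalised, and in
every window *v* the delay

τ₀ᵛ = argmax over τ of | ρᵥ(τ) |,  ρᵥ(τ) = (1/L) Σᵢ x̃ᵢ ỹᵢ₊τ

is recorded. The pair counts as coupled wherever at least 4 of 5 consecutive
windows share (within a tolerance) the same optimal delay, and the **link
strength** is the percentage of analysis time spent in such stable stretches.
`ctdsnet` implements three estimators behind one interface:

| method | delay scan | correlation | matrix |
|---|---|---|---|
| `tds`  | τ ∈ [−τmax, τmax], stability on \|τ₀\| | plain | symmetric |
| `mtds` | τ ∈ [1, τmax], per ordering | plain | directed |
| `ctds` | τ ∈ [1, τmax], per ordering | Nth-order **partial** cross-correlation given all other channels | directed |

For CTDS, each pairwise link is estimated while controlling for every
remaining channel: by the recursive identity

ρ_xy|z(τ) = (ρ_xy(τ) − ρ_xz·ρ_zy(τ)) / √((1−ρ_xz²)(1−ρ_zy²(τ)))

applied once per control, equivalently as the correlation of the residuals of
x and y after regression on the controls (the package's default computes
these residuals on the full series, with each control entered at the lag
where it couples to the pair; see the methods vignette). This suppresses
indirect links — x→z→y chains that the uncontrolled estimators mistake for
direct x→y coupling.

The package also ships ground-truth simulators (a fixed five-node benchmark
system and random lagged-coefficient ensembles), a cross-subject surrogate
significance test with automatic threshold selection, consensus-network
construction across units, rank-sum / normality / correlation summaries, and
TSV/GraphML/JSON exporters. Everything is data-frame-in, tibble-out, with
`tidy()`, `glance()` and `autoplot()` methods on results.

## Worked example

Simulate the five-node benchmark network (seven true directed links, lags
1–3) and estimate its controlled coupling network:

```r
library(ctdsnet)

sim <- simulate_fixed_network(seed = 1)
net <- build_network(sim$record, method = "ctds")
net
#> <ctds_network> method=ctds, 5 nodes, 7/9 segments scanned (L=20, tau_max=10)
#>     x1    x2  x3    x4    x5
#> x1   0   0.0   0   0.0  85.7
#> x2 100   0.0 100 100.0  71.4
#> x3   0 100.0   0   0.0   0.0
#> x4   0  85.7 100   0.0 100.0
#> x5 100  85.7 100  71.4   0.0
```

Entry `[a, b]` is the strength of the directed link a→b in percent of
analysis time. The strongest links recover the simulated wiring with the
right delays — e.g. `x3 → x2` at delay 1 and `x4 → x3` at delay 3 are true
links of the generator:

```r
library(dplyr)
tidy(net) |> arrange(desc(strength))
#> # A tibble: 20 × 7
#>   source target strength delay n_stable n_usable method
#> 1 x2     x1          100     1        7        7 ctds
#> 2 x2     x3          100     4        7        7 ctds
#> 3 x2     x4          100     2        7        7 ctds
#> 4 x3     x2          100     1        7        7 ctds
#> ...
```

How well do true links separate from absent ones in this realization?

```r
delta_strength(sim, net)
#> # A tibble: 1 × 5
#>   delta mean_primary mean_other n_primary n_other
#> 1  36.4         83.7       47.3         7      13
```

True links average 83.7% strength, the thirteen absent ordered pairs 47.3% —
a 36-point gap in this single 100-sample realization. Averaged over 5 seeds,
the original undirected estimator scores the seven true links at 82%
strength:

```r
fixed_network_recovery(seeds = 1:5, method = "tds") |>
  summarise(mean(mean_true_strength))
#> 82
```

For cohort-level analysis, `surrogate_networks()` + `surrogate_test()` select
a significance threshold from cross-subject surrogates and
`consensus_network()` keeps links present in more than 40% of units;
`run_benchmark()` reproduces the random-network grid comparison of the
directional estimators. A thin command-line wrapper with `simulate`,
`analyze`, `benchmark`, `consensus` and `fixtures` subcommands lives at
`inst/cli/ctds.R`.

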