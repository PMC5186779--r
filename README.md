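# linkbrain

Link prediction for resting-state functional brain networks with
local-information similarity indices.

## The problem

Functional connectivity between brain regions falls off with anatomical
distance ("distance penalisation"), but distance alone cannot reproduce the
small-worldness, modularity and degree distribution of human functional
brain networks. `linkbrain` predicts the edges of a binary functional
network by combining the Euclidean distance `d_ij` between region centroids
with one of seven local-information similarity indices `s_ij` computed from
the network's immediate neighbourhoods:

| Index | Definition |
|-------|------------|
| CN    | `\|Γ_i ∩ Γ_j\|` (common neighbours) |
| HDI   | `\|Γ_i ∩ Γ_j\| / max(k_i, k_j)` |
| HPI   | `\|Γ_i ∩ Γ_j\| / min(k_i, k_j)` |
| LHN-I | `\|Γ_i ∩ Γ_j\| / (k_i k_j)` |
| PA    | `k_i k_j` (preferential attachment) |
| RA    | `Σ_{z ∈ Γ_i ∩ Γ_j} 1/k_z` (resource allocation) |
| SI    | `2\|Γ_i ∩ Γ_j\| / (k_i + k_j)` (Sørensen) |

Each node pair is scored `P_ij = s_ij^γ / d_ij` (distance penalty; the
literal product `d_ij · s_ij^γ` is available behind a flag), γ is scanned
over `[0, 3]` in steps of 0.1, and the top-`m` pairs form the predicted
network, edge-matched to the real one. Predictions are evaluated by

* **relative errors** `|(p_d − p_m)/p_d| · 100%` of eight topological
  properties (assortativity, clustering, characteristic path length,
  global/local efficiency, modularity, transitivity, and the
  exponent/cutoff of the truncated power-law degree distribution
  `P(k) ∝ k^(α−1) e^(−k/k_c)`), each summarised by its AUC over the
  sparsity grid 5–40%;
* the **energy** `E = 1 / Σ re` (equal property weights); and
* the **prediction power** `10 · log10(Pre_M / Pre_R)` in dB, where
  `Pre_M` is the fraction of real edges recovered and `Pre_R` the
  chance-level fraction `m / (n(n−1)/2)` — 0 dB means a random guess.

Group comparisons use exact Wilcoxon signed-rank tests with
Benjamini–Hochberg FDR correction (q = 0.05), one-way ANOVA across the
seven models, and the energy–prediction-power correlation.

Because no imaging data ship with the package, a synthetic-data module
generates spatially embedded modular small-world networks (90 regions,
distance-decaying and module-boosted edge probabilities) and correlated
regional time series (238 volumes, covariance `σ²I + wA`), so the whole
pipeline is testable end to end.

## Worked example

```r
library(linkbrain)

cfg    <- synthetic_config(seed = 7)          # 90 regions, 238 volumes
coords <- generate_coordinates(90, seed = 7)
truth  <- generate_spatial_modular_network(coords, cfg)
ts     <- generate_time_series(truth, cfg)
net    <- threshold_by_sparsity(pearson_correlation_matrix(ts), 0.15)
net
#> <brain_network> 90 nodes, 601 edges (sparsity 0.150)

d    <- euclidean_distance_matrix(coords)
scan <- gamma_scan(net, d, "CN")              # scan gamma over [0, 3]
scan$best_gamma
#> [1] 1.3
prediction_power(scan$predicted, net)
#> [1] 6.905962
small_world_scalar(net, n_random = 10, seed = 7)
#> [1] 2.992743
```

The CN model recovers the network's edges 6.9 dB above chance at its best
exponent, on a network that is clearly small-world (σ ≈ 3.0 > 1). The same
scan with the PA index reaches only 6.0 dB — degree products alone carry
less information about a clustered, spatially embedded network than shared
neighbourhoods do.

A full cohort analysis — seven models, per-subject energies and powers,
FDR-corrected group tests — is one call:

```r
report <- run_study(n_subjects = 20, seed = 1)
aggregate(cbind(energy, prediction_power) ~ index, report$per_subject, mean)
```

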