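---
title: "Predicting functional brain-network edges from distance and local information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting functional brain-network edges from distance and local information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkbrain)
```

## The model

A binary functional brain network is built by Pearson-correlating regional
time series (after ordinary-least-squares removal of nuisance signals) and
keeping the `m = round(S · n(n−1)/2)` strongest correlations at each
sparsity `S` of the grid 5–40% in 5% steps — the range over which binary
functional networks keep their small-world character. Every node pair is
then scored from two ingredients only: the Euclidean distance `d_ij`
between region centroids and a local-information similarity `s_ij` (one of
CN, HDI, HPI, LHN-I, PA, RA, SI), as

```
P_ij = s_ij^γ / d_ij        (distance_mode = "penalty", default)
P_ij = d_ij · s_ij^γ        (distance_mode = "literal")
```

with γ scanned over `[0, 3]` in steps of 0.1. The top-`m` scoring pairs
form the predicted network, so real and predicted networks always have
identical node and edge counts and their topological properties are
directly comparable. Similarity is computed from the very network being
predicted; this circularity is intrinsic to the method — its practical
value lies in completing or auditing partially observed networks, and here
it measures how much of a network's structure its own local topology
encodes.

Two conventions make the model total: `s^0 = 1` for every `s` (including
0), so `γ = 0` is the pure distance model; and ratio indices return 0 when
their denominator is 0 (isolated nodes), so no non-finite score ever
enters the ranking.

**Why a penalty by default.** The premise of the whole approach is that
connection probability *decreases* with distance. The literal product
`d · s^γ` rewards long edges; we treat it as a typographical inversion and
divide by `d`, but keep the literal form selectable so both behaviours
are available and logged.

**γ selection.** A per-subject, per-model exponent is chosen by
maximising prediction power at the reference sparsity of 15% (the
sparsity at which degree distributions are also compared), then applied
across the whole grid. Energy-based selection is available but costs a
full topology profile per γ. On ties the smallest γ wins, biasing toward
the simpler (more distance-like) model.

## Evaluation

Each of eight topological properties is summarised by its trapezoidal AUC
over the sparsity grid; predicted-vs-real agreement per property is the
relative error `|(p_d − p_m)/p_d| · 100%`. The degree distribution is
compared through the two parameters of a truncated power-law fit (below)
at the reference sparsity. The energy `E = 1/Σ re` (errors as fractions,
equal weights) summarises all eight; a perfect prediction would make `E`
infinite and is reported as a capped sentinel (10^6) with a warning.

Prediction power is `10·log10(Pre_M/Pre_R)` dB with the analytic baseline
`Pre_R = m/(n(n−1)/2)`, the expected recovery fraction of a uniformly
random m-edge prediction; a seeded Monte-Carlo baseline is available, in
which zero-overlap draws are excluded from the mean with a logged count. A
prediction recovering zero edges is floored at half an edge
(`Pre_M = 1/(2m)`) rather than −∞. Self-prediction gives the attainable
maximum, `10·log10(n(n−1)/(2m))` — 13.02 dB at n = 90, m = 200.

Group statistics follow the field's conventions: exact two-sided Wilcoxon
signed-rank tests on paired per-subject AUCs (exact null for ≤ 25
non-zero, tie-free differences; p = 1 when all differences vanish),
Benjamini–Hochberg FDR flags at q = 0.05 across the seven models within
each property, one-way fixed-effects ANOVA across models for energy and
for prediction power, and a Pearson correlation between energy and
prediction power per model.

## The truncated power-law degree fit

The complementary cumulative degree distribution is fitted to
`P(K ≥ k) ∝ k^(α−1) e^(−k/k_c)` by least squares on the log scale over the
observed positive degrees. On that scale the model is *linear* in
`(intercept, α−1, −1/k_c)`, so the optimum is unique and computed in
closed form — no iterative optimiser or multi-start is needed, and the fit
is fully deterministic. Points are weighted by the survival value itself
(proportional to the number of observations at or above `k`), which
stabilises the otherwise exploding variance of the log-scale residuals in
the sparse tail; unweighted fits mis-estimate α by up to ±0.6 at
n = 1000 where the weighted fit stays within ±0.2. A fitted slope
indistinguishable from zero (no exponential decay) reports `k_c = Inf`
with a warning. At least five distinct positive degrees are required.

## The synthetic cohort

No imaging data are redistributable, so the generator produces the
*statistical situation* the analysis assumes rather than BOLD physics:

* **Geometry** — centroids uniform in a 140 × 170 × 120 mm box, optionally
  mirrored in left/right pairs across the x midplane (cosmetic).
* **Networks** — nodes are k-means-partitioned into `n_modules = 6`
  contiguous spatial clusters; pair weights are
  `exp(−d/λ) · boost^{same module}` with `λ = 20` mm and `boost = 20` by
  default, and exactly `m` edges are drawn without replacement with
  probability proportional to weight. Distance decay supplies the distance
  penalty, the module boost supplies triadic clustering and hubs — the
  minimal features that make the seven indices distinguishable. The
  resulting ensembles are reliably small-world (σ ≈ 3 at S = 15%).
* **Time series** — 238 samples from `N(0, σ²I + wA)` with `σ = 1`,
  `w = 0.6`; when `σ²I + wA` is not positive definite a ridge of
  `|λ_min| + 10⁻⁶` is added and logged. The target covariance is chosen
  over autoregressive simulation for analytic transparency: connected
  pairs share covariance exactly `w`, unconnected pairs none, so
  correlation thresholding at the generating sparsity recovers planted
  edges far above chance for `w ≥ 0.5σ²`.

What the generator does **not** emulate: haemodynamics, autocorrelated or
band-limited noise, motion or drift, inter-subject anatomical
variability, or any particular empirical cohort. Passing
tests therefore demonstrate the pipeline's correctness and the
qualitative index ordering on networks with the assumed structure, not
agreement with any particular fMRI dataset's printed statistics.

## Numerical conventions

* **Edge-count rounding** — `m = round-half-away-from-zero(S·n(n−1)/2)`
  everywhere (e.g. 200 edges at n = 90, S = 5%); real and predicted
  networks always share `m`, so comparability never depends on the rule.
* **Ties** — at a thresholding or selection cutoff, ties are broken by a
  seeded uniform draw, logged through the `tie_seed` arguments; every run
  is reproducible from its seeds.
* **Signed vs absolute thresholding** — the default ranks signed
  correlations (keep the strongest positive ones), the dominant
  convention for AAL-based binary networks; `mode = "absolute"` is
  provided because the alternative cannot be ruled out.
* **Undefined metrics** — assortativity on degree-regular graphs,
  transitivity without connected triples, path length on edgeless graphs
  and failed degree fits propagate as `NA` with a `reason` attribute and
  are excluded pairwise from AUCs; they are never silently zeroed.
* **Disconnected graphs** — characteristic path length averages over
  connected pairs only (5%-sparsity networks are often fragmented) and
  flags the condition; global efficiency needs no special case.
* **Modularity** — Q of the best partition found by igraph's
  deterministic greedy agglomeration, scored by the Newman–Girvan
  formula; Q is optimiser-dependent and only comparable within this
  package.
* **Small-world σ** — uses degree-preserving rewiring nulls. Note σ of a
  ring lattice is ≫ 1 under this definition (the clustering ratio
  dominates); σ > 1 is evidence of high clustering relative to degree-
  matched randomness, not of short paths per se.

## Problem sizes

The shipped tests exercise graphs of 10–90 nodes, 100-graph oracle sweeps,
20-seed simulations, 1000-replicate calibration of the signed-rank test
and ANOVA, a 20-subject prediction-power cohort and a 3-subject full
pipeline determinism check; the acceptance script runs the complete
20-subject, 7-model study. These sizes give stable statistics at
interactive runtimes and match the scale of the emulated design (90
regions, 28 subjects).

## Limitations

Predictions are evaluated against the same network that supplied the
similarity scores, so reported powers measure self-consistency, not
out-of-sample accuracy. The energy depends on which properties are
defined; subjects with an undefined property yield `NA` energy rather
than a renormalised one. The degree-fit parameters are only meaningful
when the degree distribution really has a decaying tail — at high
sparsity the fit may report `k_c = Inf`. And all cohort-level conclusions
shipped here concern the synthetic ensemble; with real regional time
series the same functions apply unchanged, but their statistics will
reflect that data.
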