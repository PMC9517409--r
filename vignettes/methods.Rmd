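---
title: "Methods: principal-component spatiotemporal regression for station panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: principal-component spatiotemporal regression for station panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcagtwr)
```

## The model

Observations are long-format station-panel records: station `i` at planar or
geographic coordinates `(u, v)`, time `t` (days from an origin), twenty
covariates, and a particulate response (PM2.5 or PM10, μg/m³). The modelling
chain has two stages.

**Stage 1 — covariate reduction.** The covariates mix hPa, °C, m/s, mm and
unitless indices, so PCA is performed on the *correlation* matrix: each
column is centered and scaled (sample SD), and the eigendecomposition of
`R = cor(Z)` gives eigenvalues `λ₁ ≥ … ≥ λ_p` with `Σλ_k = p`. The smallest
`m` with cumulative variance proportion `Σ₁^m λ_k / p ≥ 0.85` (the default
threshold) is retained. Loadings are scaled eigenvectors,
`a_jk = v_jk √λ_k`, i.e. variable–component correlations in `[−1, 1]`. The
retained loadings are varimax-rotated for interpretability; rotation is
orthogonal, so communalities and the fitted rank-`m` projection of the data
are invariant. Before PCA, two adequacy diagnostics are computed: the
overall Kaiser–Meyer–Olkin measure
`KMO = Σr² / (Σr² + Σq²)` over off-diagonal simple correlations `r` and
anti-image partial correlations `q` (adequate above 0.5; for `p = 2` the
partial equals the simple correlation so KMO is exactly 0.5), and
Bartlett's sphericity statistic
`−(n − 1 − (2p + 5)/6)·ln det R` on `p(p−1)/2` degrees of freedom.

**Stage 2 — regression on component scores.** Scores are computed from the
standardized data, divided by `√λ` to unit sample variance, and rotated by
the same orthogonal matrix; they are exactly uncorrelated on the fit sample
before rotation and remain unit-variance after. Centered, near-orthogonal
regressors make the global intercept equal the response mean and make
coefficient magnitudes comparable across components. Four families share
the local linear model

```
y_i = β₀(u_i, v_i, t_i) + Σ_k β_k(u_i, v_i, t_i) x_ik + ε_i
```

- **OLS**: coefficients constant; solved by QR.
- **GWR / TWR / GTWR**: at each observation `i`, weighted least squares
  `β̂(i) = (XᵀW_i X)⁻¹ XᵀW_i y` with diagonal kernel weights computed from
  spatial distances (GWR), scaled temporal separations (TWR), or the
  combined metric `d² = λ d_S² + μ d_T²` (GTWR). Setting `μ = 0` collapses
  GTWR onto GWR and `λ = 0` onto TWR; these reductions are verified to
  1e-10 in the test suite.

The focal observation participates in its own local fit (the standard
convention); it is excluded only inside leave-one-out cross-validation.
The hat diagonal `S_ii = w_i x_iᵀ(XᵀW_i X)⁻¹x_i` accumulates to `tr S`, the
effective number of parameters, which is exactly the coefficient count for
OLS and grows toward `n` as bandwidths shrink.

## Tunable parameters

| Parameter | Units / default | Role |
|---|---|---|
| `threshold` | proportion, 0.85 | cumulative-variance cut for component retention |
| `kernel` | bisquare (GWR), Gaussian (TWR/GTWR) | weight decay shape |
| `neighbors` (k) | count, selected by AICc | adaptive bandwidth: distance to k-th nearest other observation |
| `tau` (τ = μ/λ) | (km/day)² under sphere coords | space–time balance in the GTWR metric |
| `coords` | `"sphere"` (great-circle km, Earth radius 6371.0088) or `"planar"` | distance geometry |
| `power` | 2 | IDW interpolation exponent |

Defaults follow common practice for this model family. The kernel default
differs by family because a compact-support bisquare on spatial distances
exploits station sparsity, while the Gaussian keeps all observations
weighted in time, where records are dense and evenly spaced; both kernels
are available for every family. The reparameterization `λ = 1`, `τ = μ/λ`
reflects that only the ratio matters once the bandwidth is adaptive; τ is
searched on a log-spaced grid centered at the squared ratio of spatial to
temporal spread, jointly with k. Ties in the bandwidth search go to larger
k (the smoother model).

## Bandwidth selection

`AICc = 2n ln σ̂ + n ln 2π + n(n + tr S)/(n − 2 − tr S)` with
`σ̂ = √(RSS/n)` is the default criterion; it requires `tr S < n − 2` and is
strictly increasing in `tr S` at fixed σ̂, penalizing effective complexity.
The leave-one-out CV score `Σ(y_i − ŷ_{≠i})²` is available as an
alternative; prediction at `i` zeroes only the focal observation's weight,
not its whole station. The search is an exhaustive grid evaluation —
simple, deterministic, and auditable via the returned criterion table.

## The synthetic generator

The generator provides ground truth that observational data cannot. It
emulates a provincial monitoring network: 57 stations uniform in a
121–135°E × 43–54°N box, 104 records per station at a 17.5-day cadence
(≈5 years, n = 5928), matching the scale of the network the package is
designed around.

Covariates are driven by six independent latent block factors —
temperature (6 temperature variables + O₃), wind (3), pressure (3),
co-pollutants (SO₂, NO₂, CO), humidity (ARH, HCP with sun hours SH loading
negatively), vegetation (NDVI) — each composed of a seasonal harmonic of
the annual cycle (45% of variance), a persistent station offset (15%) and
white noise (40%). A variable in block `b` is
`√ρ_b · factor + √(1−ρ_b) · uniqueness`, rescaled to realistic means and
SDs; within-block correlation targets are 0.92 for temperature and 0.78
elsewhere, chosen so that (a) strongly related variables correlate above
0.9 while cross-block pairs stay near zero, and (b) the 85% variance cut
robustly lands at six components — five would fall short at ≈84%. Block
seasonal signals use distinct harmonics with quarter-phase pairs so they
are mutually orthogonal over whole years; without this, shared annual
cycles induce cross-block correlation that merges components.

True coefficient fields come in four presets: `constant`, `space-only`
(east–west linear gradients), `time-only` (annual sinusoids) and
`space-time` (both). Relative amplitudes below 1 keep each field's sign
fixed, which is what makes the sign-consistency property (mean local sign
equals global sign) well defined. Two identifiability choices matter and
are deliberate:

- **Quadrature phases.** The intercept field's annual modulation is phased
  a quarter-cycle from the annual component of the seasonal scores. If the
  two are in phase, the intercept's seasonal swing is collinear with the
  temperature score and a global fit misattributes it to that regressor —
  a genuine confounding, not an estimator defect. The package's validation
  panels are generated identifiable.
- **Whole-year sampling in benchmarks.** Validation panels sample an
  integer number of years (cadence 365/20 d), so seasonal coefficient
  modulation averages out against seasonal regressors. Partial-year panels
  leave real seasonal confounding in the global fit.

What the generator does **not** emulate: spatially correlated noise fields
beyond the block structure, missing records, irregular station dropout,
heavy-tailed pollution episodes, or measurement error in coordinates.
Passing tests therefore demonstrate correctness of the estimators and the
pipeline under a known, well-posed data-generating process — not that any
particular real-world panel satisfies these assumptions.

Responses are simulated as the local linear model plus Gaussian noise
(default SD 5 μg/m³) and truncated at zero (concentrations are
non-negative); the truncation count is reported and is zero in noiseless
runs. All generators are pure functions of their arguments including the
seed.

## Numerical choices

- Local solves use Cholesky on the weighted cross-product `XᵀWX` (QR for
  the global OLS); a condition number above 1e12 or a failed factorization
  raises an error advising a larger neighbour count, never a silent
  pseudo-inverse.
- Bisquare weights are *exactly* zero beyond the bandwidth, and only
  positive-weight rows enter the local solve.
- The adaptive bandwidth is the k-th order statistic of distances to the
  other observations; tied distances share the bandwidth value. On station
  panels, purely spatial (GWR) distances tie at zero within a station, so
  k must exceed the per-station record count — the error message says so.
- Varimax uses Kaiser row normalization and classical pairwise Jacobi
  rotations, converging when the largest rotation angle in a sweep falls
  below 1e-10 rad (cap 1000 sweeps); each rotated component is sign-flipped
  so its dominant variable loads positively, and components are ordered by
  rotated variance explained.
- Degenerate inputs error early with the offending column or row named:
  zero-variance columns in standardization, rank-deficient designs (the
  dependent columns are listed), duplicate `(station, time)` keys, missing
  values in modelled columns.
- IDW surfaces are convex combinations (bounded by the input range) and
  take the exact station value within 1e-9 of a site.

## Validation problem sizes

The test suite validates formula-level oracles on randomized cases
(tolerance 1e-8), exact reductions between families (n = 300), exact
recovery of noiseless constant truth, and a four-family recovery benchmark
at n = 1500 (30 stations × 50 whole-year-sampled periods, noise SD
5 μg/m³) in which each family is fit with AICc-selected bandwidths and
scored by coefficient RMSE against the generator truth. On `space-only`
fields GWR beats OLS at every regressor; on `time-only` fields TWR beats
GWR overall; on `space-time` fields with dominant temporal modulation
(amplitudes 0.7 temporal / 0.35 spatial) GTWR attains the lowest
coefficient RMSE and AICc, with fit quality ordering
GTWR ≥ TWR ≥ GWR ≥ OLS. The PCA stage is validated on the full-size
n = 5928 panel. `scripts/acceptance.R` re-runs these computations from
scratch and writes the resulting numbers as JSON.

## Known limitations and open choices

- The spatial distance in GWR is plain Euclidean or great-circle; no
  projection is applied before planar distances, so planar mode is meant
  for simulated unit-box data, sphere mode for real coordinates.
- Whether scores should enter the regressions rotated or unrotated is not
  universally agreed; both are supported (`pca_scores(rotated = )`), with
  rotated, unit-variance scores the default because they keep the
  component interpretation of the loadings table.
- "Adaptive Gaussian" bandwidths use the k-th neighbour distance as the
  decay scale without truncation; an alternative truncated definition
  exists in the literature.
- Coefficient surfaces average local coefficients over all time points by
  default; an epoch selector (e.g. the October–April heating season via
  `is_heating_season()`) restricts the window, since a single map of a
  time-varying coefficient is necessarily a summary.
- Effective parameters for adjusted R² in local families use `tr S`,
  consistent with AICc; other effective-degrees-of-freedom conventions
  (e.g. `2 tr S − tr SᵀS`) would shift absolute values but not the family
  ordering checked here.
- No mixed (semiparametric) GWR, no robust standard errors, no spatial
  autocorrelation diagnostics, and no kriging/spline alternatives to IDW.
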