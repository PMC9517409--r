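# pcagtwr

Spatiotemporal regression of particulate-matter concentrations at fixed
monitoring stations, built on principal-component reduction of collinear
covariates.

## The problem and who this is for

Station networks measuring PM2.5 and PM10 also record co-pollutants (SO₂,
NO₂, CO, O₃), a battery of meteorological variables (temperatures, wind
speeds, pressures, humidity, precipitation, sun hours) and vegetation cover
(NDVI). Two features make naive regression of PM on these covariates
unreliable:

1. **Multicollinearity** — the covariates arrive in tightly correlated blocks
   (three pressures correlate at ~0.95, six temperatures likewise), so raw
   regression coefficients are unstable and uninterpretable.
2. **Spatiotemporal non-stationarity** — the effect of, say, wind speed on PM
   is not one number: it varies across a province and across the seasons,
   especially where winter coal heating drives strong annual cycles.

`pcagtwr` addresses both. Covariates are reduced by correlation-matrix PCA
with varimax rotation into a handful of interpretable components
(temperature, wind, pressure, pollutant, humidity, vegetation), and the
component scores enter a nested family of regressions estimated by locally
weighted least squares:

- **PCA-OLS** — one global coefficient vector,
  `β̂ = (XᵀX)⁻¹XᵀY`;
- **PCA-GWR** (geographically weighted) — a coefficient vector per
  observation, `β̂(uᵢ,vᵢ) = (XᵀW(uᵢ,vᵢ)X)⁻¹XᵀW(uᵢ,vᵢ)Y`, with W built from
  spatial distances;
- **PCA-TWR** (temporally weighted) — the same with purely temporal
  distances, `d²ᵢⱼ = μ(tᵢ − tⱼ)²`;
- **PCA-GTWR** (geographically and temporally weighted) — combined
  space–time distances, `d²ᵢⱼ = λd_S² + μd_T²`, so that GWR and TWR are the
  `μ = 0` and `λ = 0` special cases.

Kernels are adaptive: the bandwidth at each observation is the distance to
its k-th nearest neighbour (compact support for the bisquare kernel
`(1 − (d/h)²)²`, decay scale for the Gaussian kernel `exp(−d²/h²)`), and k —
together with the space–time ratio τ = μ/λ for GTWR — is selected by
minimizing the corrected AIC

```
AICc = 2n ln σ̂ + n ln 2π + n (n + tr S) / (n − 2 − tr S)
```

or the leave-one-out CV score, where `tr S` is the trace of the hat matrix
(the model's effective number of parameters). Fits are compared by adjusted
R², AICc, RMSE and MAE; local coefficients are summarized (min / mean / max /
SD / kurtosis / skewness), mapped by inverse-distance-weighted interpolation,
and traced through time as cross-station mean series.

Because real monitoring records of this kind are typically not
redistributable, the package ships a first-class synthetic generator:
station networks, covariate panels with the blocked correlation and seasonal
structure described above, and PM responses drawn from *known*
space–time-varying coefficient fields. Every stage of the pipeline is
validated against that ground truth.

## Worked example

```r
library(pcagtwr)

stations <- simulate_stations(30, seed = 1)
panel    <- simulate_covariates(stations, n_periods = 60, seed = 2)

pca <- fit_pca(panel, threshold = 0.85)
pca
#> PCA model: 20 variables, 1800 records
#>   components selected: 6 (cumulative variance 89.0% >= 85%)
#>   KMO = 0.895; Bartlett chi2 = 39841.2 (df 190, p 0)
#>   loadings: varimax-rotated
label_components(pca)
#> # A tibble: 6 x 4
#>   component label       n_markers markers
#> 1 PC1       temperature         7 O3,MaxT,AT,MinT,MaxST,AST,MinST
#> 2 PC2       humidity            3 ARH,HCP,SH
#> 3 PC3       pressure            3 MaxP,AP,MinP
#> 4 PC4       wind                3 MaxWS,AWS,EWS
#> 5 PC5       pollutant           3 SO2,NO2,CO
#> 6 PC6       vegetation          1 NDVI
```

The KMO statistic (0.895 > 0.5) and Bartlett test (p ≈ 0) confirm the panel
is suitable for PCA; six rotated components reach 89% cumulative variance and
each is labelled by the covariate block that dominates its loadings.

Simulate a response from known space–time coefficient fields on the first
three scores, then fit and compare a global and a local model:

```r
scores <- pca$scores[, 1:3]
truth  <- simulate_coefficients("space-time", beta = c(40, -7, 5, 25),
                                spatial_amplitude = 0.35,
                                temporal_amplitude = 0.7, noise_sd = 5)
panel  <- simulate_response(panel, scores, truth, seed = 3)
d <- dplyr::bind_cols(panel, scores)

ols <- fit_ols(d, "pm25", names(scores))
sel <- select_bandwidth(d, "pm25", names(scores), family = "gtwr",
                        k_grid = c(50, 100, 200, 400))
sel
#> GTWR bandwidth search (aicc): best k = 50, tau = 221.3, criterion = 13473.5351
gtwr <- fit_local_model(d, "pm25", names(scores), family = "gtwr",
                        neighbors = sel$best_k, tau = sel$best_tau)

compare_models(ols, gtwr)
#> # A tibble: 2 x 9
#>   family     n trace_S    r2 adjusted_r2   aicc  rmse   mae sigma_hat
#> 1 OLS     1800      4  0.570       0.569 16050. 20.8  17.1      20.8
#> 2 GTWR    1800    118. 0.910       0.904 13474.  9.52  7.57      9.52
```

Allowing the coefficients to vary over space and time raises adjusted R²
from 0.57 to 0.90 and roughly halves the RMSE: the simulated heterogeneity
is real structure that a single global coefficient vector cannot represent.
The effective parameter count (`trace_S` ≈ 118) is what AICc charges for
that flexibility. The sign check reproduces the qualitative agreement
between global and mean-local coefficients:

```r
sign_consistency(gtwr, ols)
#> # A tibble: 4 x 4
#>   term        mean_local global consistent
#> 1 (Intercept)      41.2   43.1  TRUE
#> 2 PC1              -5.41  -7.21 TRUE
#> 3 PC2               3.67   4.67 TRUE
#> 4 PC3              21.7   22.4  TRUE
```

Downstream products: `coefficient_surface(gtwr, "PC1")` grids the local
coefficients by IDW (`autoplot()` draws the map), `temporal_series(gtwr)`
gives the cross-station coefficient trajectories, `annual_mean_map()` maps
annual mean concentrations, and `tidy()`/`glance()` expose everything as
tibbles. `run_pipeline(out_dir, seed = ...)` executes the whole chain and
writes CSV/GeoJSON products deterministically; `inst/cli/pcagtwr.R` wraps it
for the shell.

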