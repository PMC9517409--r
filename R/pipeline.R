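#' Run the full synthetic analysis pipeline and write its outputs
#'
#' Simulates a station network and covariate panel, reduces the covariates by
#' varimax-rotated PCA, simulates a PM response from known space-time-varying
#' coefficient fields on the leading component scores, fits the requested
#' model families, and writes every product (panel CSV, loading table,
#' adequacy report, coefficient tables, model comparison, coefficient surface
#' CSV + GeoJSON, temporal series) into `out_dir`. All randomness derives
#' from `seed`, so a repeated run is byte-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for every stochastic stage.
#' @param n_stations,n_periods Synthetic panel size.
#' @param bounds Station bounding box.
#' @param preset Coefficient-field preset for the simulated response.
#' @param beta Baseline coefficients (intercept first); its length minus one
#'   sets how many leading component scores enter the regression.
#' @param noise_sd Response noise (ug/m3).
#' @param families Model families to fit, subset of
#'   `c("ols", "gwr", "twr", "gtwr")`.
#' @param neighbors Adaptive neighbour count for the local families.
#' @param tau Space-time ratio for GTWR.
#' @param coords Coordinate mode for distances.
#' @param grid_n Surface grid resolution per axis.
#' @return (Invisibly) a named list of output file paths plus the in-memory
#'   results (`panel`, `pca`, `fits`, `comparison`).
#' @export
run_pipeline <- function(out_dir, seed = 1, n_stations = 15, n_periods = 40,
                         bounds = c(121, 135, 43, 54),
                         preset = "space-time", beta = c(40, -7, 5, 25),
                         noise_sd = 5,
                         families = c("ols", "gtwr"),
                         neighbors = 80, tau = NULL,
                         coords = "sphere", grid_n = 25) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  families <- match.arg(families, c("ols", "gwr", "twr", "gtwr"),
                        several.ok = TRUE)
  stations <- simulate_stations(n_stations, bounds, seed = seed)
  panel <- simulate_covariates(stations, n_periods, seed = seed + 1)
  pca <- fit_pca(panel)
  m_use <- min(length(beta) - 1, pca$n_selected)
  scores <- pca$scores[, seq_len(m_use), drop = FALSE]
  truth <- simulate_coefficients(preset, beta = beta[seq_len(m_use + 1)],
                                 bounds = bounds, noise_sd = noise_sd)
  panel <- simulate_response(panel, scores, truth, seed = seed + 2)
  model_data <- dplyr::bind_cols(panel, scores)
  regs <- names(scores)
  if (is.null(tau)) {
    tau <- (spread_of(model_data, c("lon", "lat"), coords) /
              max(spread_of(model_data, "time"), .Machine$double.eps))^2
  }

  fits <- list()
  for (fam in families) {
    fits[[fam]] <- if (fam == "ols") {
      fit_ols(model_data, "pm25", regs)
    } else {
      fit_local_model(model_data, "pm25", regs, family = fam,
                      neighbors = neighbors, tau = tau, coords = coords)
    }
  }
  comparison <- purrr::map_dfr(fits, assess)

  paths <- list(
    panel = file.path(out_dir, "panel.csv"),
    loadings = file.path(out_dir, "loadings.csv"),
    adequacy = file.path(out_dir, "adequacy.csv"),
    comparison = file.path(out_dir, "model_comparison.csv")
  )
  write_panel_csv(panel, paths$panel)
  write_loadings_csv(pca, paths$loadings)
  readr::write_csv(glance(pca), paths$adequacy, progress = FALSE)
  write_assessment_csv(comparison, paths$comparison)

  local_fams <- setdiff(families, "ols")
  if (length(local_fams)) {
    fam <- local_fams[length(local_fams)]
    fit <- fits[[fam]]
    paths$coefficients <- file.path(out_dir, paste0(fam, "_coefficients.csv"))
    write_coefficients_csv(fit, paths$coefficients)
    surf <- coefficient_surface(fit, regs[1], nx = grid_n, ny = grid_n)
    paths$surface_csv <- file.path(out_dir, "surface_PC1.csv")
    paths$surface_geojson <- file.path(out_dir, "surface_PC1.geojson")
    write_surface_csv(surf, paths$surface_csv)
    write_surface_geojson(surf, paths$surface_geojson)
    if (fit$family %in% c("TWR", "GTWR")) {
      paths$series <- file.path(out_dir, "temporal_series.csv")
      readr::write_csv(temporal_series(fit), paths$series, progress = FALSE)
    }
  }
  invisible(list(paths = paths, panel = panel, pca = pca, fits = fits,
                 comparison = comparison))
}
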