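#' Read and validate a station panel CSV
#'
#' The expected layout is long format: one row per (station, time) record with
#' `station_id`, `lon`, `lat`, `time` (days), the covariates of
#' [covariate_names()] that are present, and response columns (`pm25`,
#' `pm10`). Validation errors name the offending column or row.
#'
#' @param path CSV path.
#' @param required Columns that must be present; default the four keys.
#' @param responses Response columns checked for non-negativity when present.
#' @return A validated tibble.
#' @export
read_panel_csv <- function(path,
                           required = c("station_id", "lon", "lat", "time"),
                           responses = c("pm25", "pm10")) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  panel <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(panel))
  if (length(missing)) {
    abort(paste0("Panel is missing column(s): ", paste(missing, collapse = ", ")))
  }
  modelled <- intersect(c("lon", "lat", "time", covariate_names(), responses),
                        names(panel))
  for (col in modelled) {
    bad <- which(!is.finite(panel[[col]]))
    if (length(bad)) {
      abort(sprintf("Column `%s` has missing/non-numeric value at row %d.",
                    col, bad[1]))
    }
  }
  dup <- duplicated(panel[, c("station_id", "time")])
  if (any(dup)) {
    abort(sprintf("Duplicate (station_id, time) pair at row %d.", which(dup)[1]))
  }
  for (col in intersect(responses, names(panel))) {
    bad <- which(panel[[col]] < 0)
    if (length(bad)) {
      abort(sprintf("Negative %s at row %d.", col, bad[1]))
    }
  }
  panel
}

#' @rdname read_panel_csv
#' @param panel A station panel tibble.
#' @export
write_panel_csv <- function(panel, path) {
  readr::write_csv(panel, path, progress = FALSE)
  invisible(path)
}

#' Write the rotated loading table as CSV
#'
#' One row per variable, one column per retained component, mirroring the
#' conventional loading-table layout.
#'
#' @param model A `pca_model`.
#' @param path Output CSV path.
#' @export
write_loadings_csv <- function(model, path) {
  stopifnot(inherits(model, "pca_model"))
  out <- tibble::as_tibble(model$loadings, rownames = "variable")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write per-observation local coefficients as CSV
#'
#' Keyed by `station_id` and `time`, one column per coefficient.
#'
#' @param fit A `local_fit`.
#' @param path Output CSV path.
#' @export
write_coefficients_csv <- function(fit, path) {
  stopifnot(inherits(fit, "local_fit"))
  keys <- intersect(c("station_id", "lon", "lat", "time"), names(fit$data))
  out <- dplyr::bind_cols(fit$data[, keys, drop = FALSE],
                          tibble::as_tibble(fit$coefficients))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a model-comparison table as CSV
#'
#' @param assessments A tibble of [assess()] rows (e.g. [compare_models()]).
#' @param path Output CSV path.
#' @export
write_assessment_csv <- function(assessments, path) {
  readr::write_csv(assessments, path, progress = FALSE)
  invisible(path)
}

#' Surface I/O: CSV and GeoJSON
#'
#' Surfaces are written either as plain CSV (`lon, lat, value`) or as a
#' GeoJSON FeatureCollection of point features with a `value` property.
#' Reading inverts either representation losslessly (full double precision).
#'
#' @param surface A `coef_surface` tibble.
#' @param path Output path.
#' @export
write_surface_csv <- function(surface, path) {
  readr::write_csv(tibble::as_tibble(surface)[, c("lon", "lat", "value")],
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_surface_csv
#' @export
write_surface_geojson <- function(surface, path) {
  features <- purrr::pmap(
    list(surface$lon, surface$lat, surface$value),
    function(lon, lat, value) {
      list(type = "Feature",
           geometry = list(type = "Point", coordinates = c(lon, lat)),
           properties = list(value = value,
                             term = attr(surface, "term") %||% "value"))
    })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_surface_csv
#' @export
read_surface_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) {
    abort("Not a GeoJSON FeatureCollection.")
  }
  out <- purrr::map_dfr(fc$features, function(f) {
    tibble::tibble(lon = as.numeric(f$geometry$coordinates[[1]]),
                   lat = as.numeric(f$geometry$coordinates[[2]]),
                   value = as.numeric(f$properties$value))
  })
  class(out) <- c("coef_surface", class(out))
  if (length(fc$features)) {
    attr(out, "term") <- fc$features[[1]]$properties$term
  }
  out
}

#' Read a key-value configuration file
#'
#' Plain-text `key = value` lines (`#` comments allowed); values are parsed
#' as numeric where possible.
#'
#' @param path Config file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2) abort(paste0("Malformed config line: ", ln))
    key <- trimws(parts[1])
    val <- trimws(parts[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
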