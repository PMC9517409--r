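#' Regular longitude/latitude grid
#'
#' @param bounds `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param nx,ny Number of cells along longitude and latitude.
#' @return A tibble of cell centres with columns `lon`, `lat`.
#' @export
make_grid <- function(bounds = c(121, 135, 43, 54), nx = 50, ny = 50) {
  bounds <- check_bounds(bounds)
  stopifnot(nx >= 1, ny >= 1)
  tidyr::expand_grid(lon = seq(bounds[1], bounds[2], length.out = nx),
                     lat = seq(bounds[3], bounds[4], length.out = ny))
}

#' Inverse-distance-weighted interpolation onto a grid
#'
#' Each grid cell takes the convex combination `sum(w_j z_j) / sum(w_j)` with
#' `w_j = d_j^(-power)` over the data points; a cell within 1e-9 of a data
#' point takes that point's value exactly. Distances are planar Euclidean in
#' coordinate units. The result is bounded by the range of the input values.
#'
#' @param points A data frame with `lon`, `lat`, `value`.
#' @param grid A grid tibble from [make_grid()].
#' @param power Positive IDW exponent (default 2).
#' @return A tibble of class `coef_surface` with `lon`, `lat`, `value`.
#' @examples
#' pts <- tibble::tibble(lon = c(0, 1), lat = c(0, 0), value = c(0, 10))
#' idw_interpolate(pts, make_grid(c(0, 1, -0.1, 0.1), 5, 2))
#' @export
idw_interpolate <- function(points, grid, power = 2) {
  if (nrow(points) < 1) abort("IDW requires at least one data point.")
  if (power <= 0) abort("`power` must be positive.")
  need <- c("lon", "lat", "value")
  if (!all(need %in% names(points))) abort("`points` needs lon, lat, value.")
  if (any(!is.finite(points$value))) abort("Point values must be finite.")
  dx <- outer(grid$lon, points$lon, "-")
  dy <- outer(grid$lat, points$lat, "-")
  d <- sqrt(dx^2 + dy^2)
  w <- d^(-power)
  exact <- d < 1e-9
  val <- as.numeric((w %*% points$value) / rowSums(w))
  hit <- which(rowSums(exact) > 0)
  if (length(hit)) {
    val[hit] <- vapply(hit, function(i) points$value[which(exact[i, ])[1]],
                       numeric(1))
  }
  out <- tibble::tibble(lon = grid$lon, lat = grid$lat, value = val)
  class(out) <- c("coef_surface", class(out))
  out
}

#' Gridded surface of a local coefficient
#'
#' Averages each station's local coefficient for one regressor over the
#' selected epoch and interpolates the station values onto a regular grid by
#' IDW — the map of where (and how strongly) that component drives the
#' response.
#'
#' @param fit A local-family `local_fit` (must carry `lon`/`lat`).
#' @param term Coefficient name (e.g. `"PC1"` or `"(Intercept)"`).
#' @param grid Grid tibble; default built from the station bounding box.
#' @param epoch Optional length-2 numeric `c(from, to)` restricting the time
#'   window averaged per station; default all times.
#' @param power IDW exponent.
#' @param nx,ny Grid resolution when `grid` is not supplied.
#' @return A `coef_surface` tibble with attribute `term`.
#' @export
coefficient_surface <- function(fit, term, grid = NULL, epoch = NULL,
                                power = 2, nx = 50, ny = 50) {
  stopifnot(inherits(fit, "local_fit"))
  if (fit$family == "OLS") abort("Coefficient surfaces require a local family.")
  if (!term %in% colnames(fit$coefficients)) {
    abort(paste0("Unknown coefficient `", term, "`; available: ",
                 paste(colnames(fit$coefficients), collapse = ", ")))
  }
  df <- fit$data
  if (!all(c("lon", "lat", "station_id") %in% names(df))) {
    abort("Fit data lacks station coordinates.")
  }
  df$.coef <- fit$coefficients[, term]
  if (!is.null(epoch)) {
    stopifnot(length(epoch) == 2)
    df <- df[df$time >= epoch[1] & df$time <= epoch[2], ]
    if (nrow(df) == 0) abort("No observations in the requested epoch.")
  }
  pts <- df |>
    dplyr::group_by(.data$station_id) |>
    dplyr::summarise(lon = .data$lon[1], lat = .data$lat[1],
                     value = mean(.data$.coef), .groups = "drop")
  if (is.null(grid)) {
    pad <- c(-1, 1, -1, 1) * 1e-6
    grid <- make_grid(c(range(pts$lon), range(pts$lat)) [c(1, 2, 3, 4)] + pad,
                      nx, ny)
  }
  out <- idw_interpolate(pts[, c("lon", "lat", "value")], grid, power = power)
  attr(out, "term") <- term
  attr(out, "stations") <- pts
  out
}

#' Cross-station temporal series of local coefficients
#'
#' For time-varying families (TWR, GTWR), averages each coefficient across
#' stations at every distinct time point — the trajectory of each component's
#' influence through the year(s).
#'
#' @param fit A TWR or GTWR `local_fit`.
#' @return A tibble of class `temporal_series` with `time`, `term`,
#'   `estimate`, ordered by time; one row per (time, term).
#' @export
temporal_series <- function(fit) {
  stopifnot(inherits(fit, "local_fit"))
  if (!fit$family %in% c("TWR", "GTWR")) {
    abort("Temporal series require a time-varying family (TWR or GTWR).")
  }
  df <- dplyr::bind_cols(fit$data["time"],
                         tibble::as_tibble(fit$coefficients))
  out <- df |>
    tidyr::pivot_longer(-"time", names_to = "term", values_to = "estimate") |>
    dplyr::group_by(.data$time, .data$term) |>
    dplyr::summarise(estimate = mean(.data$estimate), .groups = "drop") |>
    dplyr::arrange(.data$time, .data$term)
  class(out) <- c("temporal_series", class(out))
  out
}

#' Annual mean concentration map and regional trend
#'
#' Computes per-station annual mean concentrations, interpolates the selected
#' year onto a grid by IDW, and returns the regional (cross-station) annual
#' mean series alongside. Years are derived from the `time` column (days) via
#' a calendar origin.
#'
#' @param panel A station panel with a response column.
#' @param response Response column name.
#' @param year Optional year (integer) to map; default: all years pooled.
#' @param origin Calendar date (string) corresponding to `time = 0`.
#' @param grid,power,nx,ny As in [coefficient_surface()].
#' @return A list with `surface` (a `coef_surface`), `annual_means` (tibble of
#'   `year`, `mean`) and `station_means`.
#' @export
annual_mean_map <- function(panel, response = "pm25", year = NULL,
                            origin = "2014-01-01", grid = NULL, power = 2,
                            nx = 50, ny = 50) {
  need <- c("station_id", "lon", "lat", "time", response)
  missing <- setdiff(need, names(panel))
  if (length(missing)) {
    abort(paste0("Panel lacks column(s): ", paste(missing, collapse = ", ")))
  }
  df <- panel
  df$year <- as.integer(format(as.Date(origin) + floor(df$time), "%Y"))
  annual <- df |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(mean = mean(.data[[response]]), .groups = "drop")
  sel <- if (is.null(year)) df else df[df$year == year, ]
  if (nrow(sel) == 0) abort("No observations for the requested year.")
  stations <- sel |>
    dplyr::group_by(.data$station_id) |>
    dplyr::summarise(lon = .data$lon[1], lat = .data$lat[1],
                     value = mean(.data[[response]]), .groups = "drop")
  if (is.null(grid)) {
    pad <- c(-1, 1, -1, 1) * 1e-6
    grid <- make_grid(c(range(stations$lon), range(stations$lat)) + pad,
                      nx, ny)
  }
  surface <- idw_interpolate(stations[, c("lon", "lat", "value")], grid,
                             power = power)
  attr(surface, "term") <- response
  list(surface = surface, annual_means = annual, station_means = stations)
}

#' Heating-season selector (October through April)
#'
#' @param time Days since `origin`.
#' @param origin Calendar date for `time = 0`.
#' @return Logical vector: does each record fall in the heating season?
#' @export
is_heating_season <- function(time, origin = "2014-01-01") {
  month <- as.integer(format(as.Date(origin) + floor(time), "%m"))
  month >= 10 | month <= 4
}

#' Raster map of an interpolated surface
#'
#' @param object A `coef_surface`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coef_surface <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lon, y = .data$lat,
                                       fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = attr(object, "term") %||% "surface",
                  x = "longitude", y = "latitude", fill = "value")
}

#' Line plot of a temporal coefficient series
#'
#' @param object A `temporal_series`.
#' @param ... Unused.
#' @return A ggplot object faceted by coefficient.
#' @export
autoplot.temporal_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$term), scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = "mean local coefficient")
}
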