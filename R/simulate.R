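#' Simulate a monitoring-station network
#'
#' Draws station locations uniformly at random inside a longitude/latitude
#' rectangle. The default box and station count emulate a provincial network of
#' 57 sites spanning roughly 121-135 degrees E and 43-54 degrees N.
#'
#' @param n_stations Number of stations (>= 2).
#' @param bounds Numeric vector `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param seed Integer seed; identical arguments give identical output.
#' @return A tibble with columns `station_id`, `lon`, `lat`.
#' @examples
#' simulate_stations(5, bounds = c(0, 1, 0, 1), seed = 1)
#' @export
simulate_stations <- function(n_stations = 57,
                              bounds = c(121, 135, 43, 54),
                              seed = 1) {
  if (n_stations < 2) abort("`n_stations` must be at least 2.")
  bounds <- check_bounds(bounds)
  withr::with_seed(as.integer(seed), {
    tibble::tibble(
      station_id = sprintf("S%03d", seq_len(n_stations)),
      lon = runif(n_stations, bounds[1], bounds[2]),
      lat = runif(n_stations, bounds[3], bounds[4])
    )
  })
}

check_bounds <- function(bounds) {
  if (length(bounds) != 4 || any(!is.finite(bounds))) {
    abort("`bounds` must be c(lon_min, lon_max, lat_min, lat_max), all finite.")
  }
  if (bounds[2] <= bounds[1] || bounds[4] <= bounds[3]) {
    abort("Degenerate `bounds`: require lon_min < lon_max and lat_min < lat_max.")
  }
  unname(bounds)
}

#' Configuration for the synthetic covariate panel
#'
#' Controls the latent-factor construction behind [simulate_covariates()]. Each
#' covariate block is driven by one latent factor composed of a seasonal
#' harmonic of the annual cycle (block-specific harmonic and phase, chosen so
#' different blocks' cycles are mutually orthogonal over whole years), a
#' station-level offset and white noise (variance shares
#' `seasonal_share`, `station_share` and the remainder); a covariate in block
#' `b` is `sqrt(rho_b) * factor + noise_scale * sqrt(1 - rho_b) * unique noise`,
#' then rescaled to the block's realistic mean and standard deviation.
#'
#' @param block_cor Named numeric vector of within-block correlation targets.
#' @param seasonal_share,station_share Variance shares of the latent factor
#'   attributed to the annual cycle and to persistent station offsets; the
#'   remainder is white noise. Must sum to at most 1.
#' @param period Seasonal period in days (365 = annual cycle).
#' @param cadence Days between successive records at a station.
#' @param origin Time of the first record, in days.
#' @param time_jitter Uniform jitter half-width (days) on sampling times; 0
#'   gives a regular cadence.
#' @param noise_scale Multiplier on covariate-specific uniqueness; 0 makes
#'   block members perfectly collinear with their factor.
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(block_cor = c(temperature = 0.92, wind = 0.78,
                                       pressure = 0.78, pollutant = 0.78,
                                       humidity = 0.78, vegetation = 1.00),
                         seasonal_share = 0.45,
                         station_share = 0.15,
                         period = 365,
                         cadence = 17.5,
                         origin = 0,
                         time_jitter = 0,
                         noise_scale = 1) {
  stopifnot(all(block_cor >= 0 & block_cor <= 1),
            seasonal_share >= 0, station_share >= 0,
            seasonal_share + station_share <= 1,
            period > 0, cadence > 0, time_jitter >= 0, noise_scale >= 0)
  structure(list(block_cor = block_cor, seasonal_share = seasonal_share,
                 station_share = station_share, period = period,
                 cadence = cadence, origin = origin,
                 time_jitter = time_jitter, noise_scale = noise_scale),
            class = "panel_config")
}

#' Simulate a station covariate panel with block correlation and seasonality
#'
#' Generates the 20-covariate long-format panel: each station is observed at
#' `n_periods` times, and covariates are built from six independent latent
#' seasonal factors (temperature, wind, pressure, co-pollutants, humidity,
#' vegetation) so that a correlation-matrix PCA on the output recovers the
#' blocks as interpretable components. Sun hours (`SH`) load negatively on the
#' humidity factor.
#'
#' @param stations A station tibble from [simulate_stations()].
#' @param n_periods Number of records per station (>= 2).
#' @param seed Integer seed.
#' @param config A [panel_config()].
#' @return A tibble with columns `station_id`, `lon`, `lat`, `time` (days) and
#'   the 20 covariates of [covariate_names()].
#' @examples
#' st <- simulate_stations(5, seed = 1)
#' panel <- simulate_covariates(st, n_periods = 10, seed = 1)
#' dim(panel)
#' @export
simulate_covariates <- function(stations, n_periods = 104, seed = 1,
                                config = panel_config()) {
  if (n_periods < 2) abort("`n_periods` must be at least 2.")
  stopifnot(inherits(config, "panel_config"))
  blocks <- covariate_blocks()
  if (!setequal(names(config$block_cor), names(blocks))) {
    abort("`config$block_cor` must name exactly the covariate blocks.")
  }
  scales <- covariate_scales()
  n_st <- nrow(stations)

  withr::with_seed(as.integer(seed), {
    times0 <- config$origin + (seq_len(n_periods) - 1) * config$cadence
    panel <- tidyr::expand_grid(station_id = stations$station_id,
                                .t0 = times0)
    if (config$time_jitter > 0) {
      panel$time <- panel$.t0 +
        runif(nrow(panel), -config$time_jitter, config$time_jitter)
    } else {
      panel$time <- panel$.t0
    }
    panel$.t0 <- NULL
    panel <- dplyr::left_join(panel, stations, by = "station_id")
    n <- nrow(panel)
    st_index <- match(panel$station_id, stations$station_id)

    s_seas <- sqrt(config$seasonal_share)
    s_stat <- sqrt(config$station_share)
    s_nois <- sqrt(max(0, 1 - config$seasonal_share - config$station_share))

    # block seasonal signals use distinct harmonics of the annual cycle with
    # quarter-phase pairs, so different blocks' cycles are (near-)orthogonal
    # over whole years and the latent factors stay mutually uncorrelated
    harmonics <- c(temperature = 1, vegetation = 1, pressure = 2,
                   pollutant = 2, wind = 3, humidity = 3)
    phases <- c(temperature = 0, vegetation = pi / 2, pressure = 0,
                pollutant = pi / 2, wind = 0, humidity = pi / 2)

    for (b in names(blocks)) {
      offsets <- rnorm(n_st)
      factor_b <- s_seas * sqrt(2) *
        sin(2 * pi * harmonics[[b]] * panel$time / config$period + phases[[b]]) +
        s_stat * offsets[st_index] +
        s_nois * rnorm(n)
      rho <- config$block_cor[[b]]
      for (v in blocks[[b]]) {
        sgn <- if (v %in% negative_loading_vars()) -1 else 1
        z <- sgn * sqrt(rho) * factor_b +
          config$noise_scale * sqrt(1 - rho) * rnorm(n)
        row <- scales[scales$variable == v, ]
        panel[[v]] <- row$mean + row$sd * z
      }
    }
    panel <- panel[, c("station_id", "lon", "lat", "time", covariate_names())]
    tibble::as_tibble(panel)
  })
}

#' Define true coefficient fields for response simulation
#'
#' Builds the ground-truth coefficient functions `beta_k(lon, lat, time)` used
#' by [simulate_response()]. Presets mirror the heterogeneity regimes the
#' regression families are designed to capture: `"constant"` (a global linear
#' model), `"space-only"` (east-west linear gradients), `"time-only"` (annual
#' sinusoids) and `"space-time"` (both). Relative amplitudes below 1 keep each
#' field's sign fixed everywhere, so the sign of the mean local coefficient is
#' well defined.
#'
#' @param preset One of `"constant"`, `"space-only"`, `"time-only"`,
#'   `"space-time"`.
#' @param beta Numeric vector of baseline coefficients, intercept first.
#'   Names (after the intercept) are used as regressor labels.
#' @param spatial_amplitude,temporal_amplitude Relative modulation amplitudes
#'   (fraction of the baseline magnitude).
#' @param period Seasonal period of the temporal modulation, in days.
#' @param bounds Longitude/latitude rectangle over which the spatial gradient
#'   spans `[-spatial_amplitude, +spatial_amplitude]` relative modulation.
#' @param noise_sd Default response noise standard deviation (ug/m3) carried to
#'   [simulate_response()].
#' @return An object of class `true_coefficients`: a list of vectorised
#'   functions `f(lon, lat, time)`, one per coefficient, plus metadata.
#' @examples
#' truth <- simulate_coefficients("constant", beta = c(40, -7, 5))
#' truth$fields[[1]](125, 48, 100)
#' @export
simulate_coefficients <- function(preset = c("constant", "space-only",
                                             "time-only", "space-time"),
                                  beta = c(40, -7, 5, 25),
                                  spatial_amplitude = 0.5,
                                  temporal_amplitude = 0.5,
                                  period = 365,
                                  bounds = c(121, 135, 43, 54),
                                  noise_sd = 5) {
  preset <- match.arg(preset)
  bounds <- check_bounds(bounds)
  stopifnot(is.numeric(beta), length(beta) >= 1, all(is.finite(beta)),
            spatial_amplitude >= 0, temporal_amplitude >= 0, period > 0,
            noise_sd >= 0)
  mid <- (bounds[1] + bounds[2]) / 2
  half <- (bounds[2] - bounds[1]) / 2
  p <- length(beta)
  labels <- names(beta)
  if (is.null(labels)) {
    labels <- c("(Intercept)", paste0("X", seq_len(p - 1)))
  } else {
    labels[1] <- "(Intercept)"
  }
  # each coefficient gets its own phase so the fields are not proportional;
  # the quarter-cycle offset keeps the intercept's annual swing orthogonal to
  # the annual component of seasonal regressors, so a global fit stays
  # identifiable (no intercept-to-slope leakage)
  make_field <- function(k) {
    b <- beta[k]
    phase <- pi / 2 + (k - 1) * pi / 4
    force(b); force(phase)
    switch(preset,
      "constant" = function(lon, lat, time) {
        rep_len(b, max(length(lon), length(time)))
      },
      "space-only" = function(lon, lat, time) {
        b * (1 + spatial_amplitude * (lon - mid) / half) +
          0 * time
      },
      "time-only" = function(lon, lat, time) {
        b * (1 + temporal_amplitude *
               sin(2 * pi * time / period + phase)) + 0 * lon
      },
      "space-time" = function(lon, lat, time) {
        b * (1 + spatial_amplitude * (lon - mid) / half +
               temporal_amplitude * sin(2 * pi * time / period + phase))
      }
    )
  }
  fields <- lapply(seq_len(p), make_field)
  names(fields) <- labels
  structure(list(fields = fields, preset = preset, beta = beta,
                 labels = labels, spatial_amplitude = spatial_amplitude,
                 temporal_amplitude = temporal_amplitude, period = period,
                 bounds = bounds, noise_sd = noise_sd),
            class = "true_coefficients")
}

#' Evaluate true coefficient fields at panel records
#'
#' @param truth A [simulate_coefficients()] object.
#' @param data A data frame with `lon`, `lat`, `time` columns.
#' @return A numeric matrix (records x coefficients), intercept first.
#' @export
true_coefficient_matrix <- function(truth, data) {
  stopifnot(inherits(truth, "true_coefficients"))
  need <- c("lon", "lat", "time")
  if (!all(need %in% names(data))) {
    abort("`data` must contain lon, lat and time columns.")
  }
  out <- vapply(truth$fields,
                function(f) {
                  v <- f(data$lon, data$lat, data$time)
                  if (!all(is.finite(v))) abort("Coefficient field evaluated non-finite.")
                  v
                },
                numeric(nrow(data)))
  out <- matrix(out, nrow = nrow(data),
                dimnames = list(NULL, truth$labels))
  out
}

#' Simulate a PM response from known coefficient fields
#'
#' Adds a response column to the panel following the local linear model
#' `y_i = beta_0(u_i, v_i, t_i) + sum_k beta_k(u_i, v_i, t_i) x_ik + eps_i`
#' with independent Gaussian noise. Negative draws are truncated at zero
#' (particulate concentrations are non-negative); the truncation count is
#' recorded in the `"n_truncated"` attribute and is zero when `noise_sd = 0`.
#'
#' @param panel A station panel (must have `lon`, `lat`, `time`).
#' @param X Regressor matrix (no intercept column), row-aligned with `panel`;
#'   typically principal-component scores. Must have
#'   `length(truth$beta) - 1` columns.
#' @param truth A [simulate_coefficients()] object.
#' @param noise_sd Noise standard deviation in ug/m3; defaults to the value
#'   stored in `truth`.
#' @param seed Integer seed.
#' @param response Name of the response column to create.
#' @return `panel` with the response column added; attributes `n_truncated`
#'   (count of zero-truncated records) and `true_beta` (the evaluated
#'   coefficient matrix).
#' @export
simulate_response <- function(panel, X, truth, noise_sd = NULL, seed = 1,
                              response = "pm25") {
  X <- as.matrix(X)
  if (nrow(X) != nrow(panel)) {
    abort("`X` must be row-aligned with `panel` (row counts differ).")
  }
  B <- true_coefficient_matrix(truth, panel)
  if (ncol(B) != ncol(X) + 1) {
    abort(sprintf("Truth has %d coefficients but X has %d columns (+1 intercept expected).",
                  ncol(B), ncol(X)))
  }
  noise_sd <- noise_sd %||% truth$noise_sd
  mu <- B[, 1] + rowSums(B[, -1, drop = FALSE] * X)
  y <- withr::with_seed(as.integer(seed), mu + rnorm(nrow(panel), 0, noise_sd))
  n_trunc <- sum(y < 0)
  y[y < 0] <- 0
  out <- panel
  out[[response]] <- y
  attr(out, "n_truncated") <- n_trunc
  attr(out, "true_beta") <- B
  out
}

#' Normalized difference vegetation index
#'
#' `NDVI = (IR - R) / (IR + R)` from near-infrared and red reflectances.
#'
#' @param ir,r Non-negative reflectances (vectorised).
#' @return NDVI values in `[-1, 1]`.
#' @examples
#' ndvi(0.6, 0.2)
#' @export
ndvi <- function(ir, r) {
  if (any(ir < 0 | r < 0, na.rm = TRUE)) {
    abort("Reflectances must be non-negative.")
  }
  if (any(ir + r == 0, na.rm = TRUE)) {
    abort("NDVI undefined where ir + r = 0.")
  }
  (ir - r) / (ir + r)
}
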