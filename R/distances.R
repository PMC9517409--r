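# Earth radius (km) used for great-circle distances
EARTH_RADIUS_KM <- 6371.0088

#' Spatial, temporal and spatio-temporal separations
#'
#' `spatial_distance()` returns the planar Euclidean or great-circle
#' (haversine, km) separation between points. `temporal_distance()` returns
#' `sqrt(mu) * |t_i - t_j|`. `st_distance()` combines them as
#' `sqrt(lambda * dS^2 + mu * dT^2)`: with `mu = 0, lambda = 1` it reduces to
#' the spatial distance, with `lambda = 0` to the temporal distance.
#'
#' @param a,b Numeric vectors `c(lon, lat)` (or two-column matrices) for
#'   `spatial_distance()`; `c(lon, lat, time)` (or three-column matrices) for
#'   `st_distance()`.
#' @param mode `"planar"` (Euclidean on the coordinates) or `"sphere"`
#'   (haversine great-circle, kilometres).
#' @return Non-negative distances, vectorised over rows.
#' @examples
#' spatial_distance(c(0, 0), c(3, 4), mode = "planar")
#' temporal_distance(0, 30, mu = 4)
#' @export
spatial_distance <- function(a, b, mode = c("sphere", "planar")) {
  mode <- match.arg(mode)
  a <- matrix(as.numeric(a), ncol = 2)
  b <- matrix(as.numeric(b), ncol = 2)
  if (any(!is.finite(a)) || any(!is.finite(b))) abort("Coordinates must be finite.")
  if (mode == "planar") {
    sqrt((a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2)
  } else {
    as.numeric(geosphere::distHaversine(a, b, r = EARTH_RADIUS_KM))
  }
}

#' @rdname spatial_distance
#' @param t_i,t_j Times in days.
#' @param mu Temporal scaling factor (>= 0).
#' @export
temporal_distance <- function(t_i, t_j, mu = 1) {
  if (any(mu < 0)) abort("`mu` must be non-negative.")
  sqrt(mu) * abs(t_i - t_j)
}

#' @rdname spatial_distance
#' @param lambda Spatial scaling factor (>= 0).
#' @export
st_distance <- function(a, b, lambda = 1, mu = 1,
                        mode = c("sphere", "planar")) {
  if (all(lambda == 0) && all(mu == 0)) {
    abort("`lambda` and `mu` cannot both be zero.")
  }
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  ds <- spatial_distance(a[, 1:2, drop = FALSE], b[, 1:2, drop = FALSE],
                         mode = mode)
  dt <- abs(a[, 3] - b[, 3])
  sqrt(lambda * ds^2 + mu * dt^2)
}

# pairwise spatial distance matrix between coordinate rows (lon, lat)
spatial_distance_matrix <- function(coords, mode = c("sphere", "planar")) {
  mode <- match.arg(mode)
  coords <- as.matrix(coords)
  if (mode == "planar") {
    as.matrix(stats::dist(coords))
  } else {
    m <- geosphere::distm(coords, fun = function(p1, p2) {
      geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM)
    })
    m
  }
}

#' Kernel weight functions
#'
#' `bisquare_weight()` is the compact-support kernel
#' `(1 - (d/h)^2)^2` for `d < h` and exactly 0 beyond the bandwidth.
#' `gaussian_weight()` is `exp(-(d/h)^2)`, strictly positive everywhere.
#' `gaussian_st_weight()` is the separable space-time Gaussian kernel
#' `exp(-dS^2/hS^2) * exp(-dT^2/hT^2)`, identical to the single-kernel form
#' on the combined spatio-temporal distance.
#'
#' @param d,d_s,d_t Non-negative distances.
#' @param h,h_s,h_t Positive bandwidths.
#' @return Weights in `[0, 1]`.
#' @examples
#' bisquare_weight(0.5, 1)   # (1 - 0.25)^2
#' gaussian_st_weight(1, 0, 1, 1)  # exp(-1)
#' @export
bisquare_weight <- function(d, h) {
  if (any(h <= 0)) abort("Bandwidth `h` must be positive.")
  if (any(d < 0)) abort("Distances must be non-negative.")
  ifelse(d < h, (1 - (d / h)^2)^2, 0)
}

#' @rdname bisquare_weight
#' @export
gaussian_weight <- function(d, h) {
  if (any(h <= 0)) abort("Bandwidth `h` must be positive.")
  if (any(d < 0)) abort("Distances must be non-negative.")
  exp(-(d / h)^2)
}

#' @rdname bisquare_weight
#' @export
gaussian_st_weight <- function(d_s, d_t, h_s, h_t) {
  if (any(h_s <= 0) || any(h_t <= 0)) abort("Bandwidths must be positive.")
  gaussian_weight(d_s, h_s) * gaussian_weight(d_t, h_t)
}

#' Adaptive bandwidth: distance to the k-th nearest neighbour
#'
#' Given the distances from a focal observation to the other observations,
#' returns the k-th order statistic. With tied distances the common tied value
#' is returned, so all equidistant points fall on the bandwidth.
#'
#' @param distances Distances from the focal observation (focal excluded).
#' @param k Neighbour count, `1 <= k <= length(distances)`.
#' @return The bandwidth `h`.
#' @examples
#' adaptive_bandwidth(c(4, 1, 3, 2), k = 2)
#' @export
adaptive_bandwidth <- function(distances, k) {
  n <- length(distances)
  if (k < 1 || k > n) abort(sprintf("`k` must be in [1, %d].", n))
  sort(distances, partial = k)[k]
}
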