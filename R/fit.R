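#' Global ordinary least squares fit (PCA-OLS)
#'
#' Fits `y = X beta + eps` by QR-decomposed least squares on an intercept plus
#' the named regressor columns. With centered, mutually orthogonal regressors
#' (component scores), the intercept equals the response mean. The result is a
#' `local_fit` whose coefficient matrix repeats the global row at every
#' observation, so all downstream tooling applies uniformly.
#'
#' @param data A station panel containing the response and regressor columns
#'   (and `station_id`, `lon`, `lat`, `time` where available).
#' @param response Response column name (e.g. `"pm25"`).
#' @param regressors Character vector of regressor column names.
#' @return An object of class `local_fit`.
#' @examples
#' d <- tibble::tibble(x = 1:10, y = 2 + 3 * (1:10))
#' fit <- fit_ols(d, "y", "x")
#' fit$coefficients[1, ]
#' @export
fit_ols <- function(data, response, regressors) {
  xy <- model_inputs(data, response, regressors)
  X <- xy$X
  y <- xy$y
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) abort("OLS requires more observations than coefficients.")
  qrX <- qr(X)
  if (qrX$rank < p) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    abort(paste0("Rank-deficient design; dependent column(s): ",
                 paste(dep, collapse = ", ")))
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  Q <- qr.Q(qrX)
  hat <- rowSums(Q^2)
  new_local_fit(
    family = "OLS", data = data, response = response, regressors = regressors,
    coefficients = matrix(beta, n, p, byrow = TRUE,
                          dimnames = list(NULL, colnames(X))),
    fitted = fitted, hat = hat, kernel = NULL, neighbors = NA_integer_,
    tau = NA_real_, lambda = NA_real_, coords = NA_character_
  )
}

# shared input assembly/validation for all families
model_inputs <- function(data, response, regressors) {
  missing <- setdiff(c(response, regressors), names(data))
  if (length(missing)) {
    abort(paste0("Missing column(s): ", paste(missing, collapse = ", ")))
  }
  X <- cbind("(Intercept)" = 1,
             as.matrix(data[, regressors, drop = FALSE]))
  y <- as.numeric(data[[response]])
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    abort("Model columns must be finite (no missing values).")
  }
  list(X = X, y = y)
}

new_local_fit <- function(family, data, response, regressors, coefficients,
                          fitted, hat, kernel, neighbors, tau, lambda, coords) {
  y <- as.numeric(data[[response]])
  residuals <- y - fitted
  n <- length(y)
  keep <- intersect(c("station_id", "lon", "lat", "time", response),
                    names(data))
  structure(list(
    family = family,
    response = response,
    regressors = regressors,
    coefficients = coefficients,
    fitted = fitted,
    residuals = residuals,
    hat = hat,
    trace_S = sum(hat),
    sigma_hat = sqrt(sum(residuals^2) / n),
    n = n,
    p_model = ncol(coefficients),
    kernel = kernel,
    neighbors = neighbors,
    tau = tau,
    lambda = lambda,
    coords = coords,
    data = tibble::as_tibble(data[, keep, drop = FALSE])
  ), class = "local_fit")
}

#' Weighted least squares at a single focal observation
#'
#' Solves the local normal equations
#' `beta(i) = (X' W X)^{-1} X' W y` for one focal observation via QR on the
#' square-root-weighted design, and returns the focal row of the hat matrix
#' `x_i' (X' W X)^{-1} X' W`, whose inner product with `y` is the local fitted
#' value.
#'
#' @param X Regressor matrix including the intercept column.
#' @param y Response vector.
#' @param w Non-negative weight vector (the focal observation's kernel
#'   weights).
#' @param focal Row index of the focal observation.
#' @return A list with `coefficients`, `hat_row` (length `nrow(X)`), `fitted`
#'   (focal fitted value) and `hat_diag` (the focal hat-diagonal entry).
#' @export
fit_local_point <- function(X, y, w, focal = which.max(w)) {
  X <- as.matrix(X)
  p <- ncol(X)
  idx <- which(w > 0)
  if (length(idx) < p) {
    abort(sprintf(
      "Only %d observations with positive weight but %d coefficients; increase the neighbour count.",
      length(idx), p))
  }
  sw <- sqrt(w[idx])
  Xs <- X[idx, , drop = FALSE] * sw
  A <- crossprod(Xs)                        # X' W X
  ch <- tryCatch(chol(A), error = function(e) {
    abort("Singular weighted cross-product; increase the neighbour count.")
  })
  kap <- kappa(ch, exact = FALSE)
  if (!is.finite(kap) || kap^2 > 1e12) {
    abort("Ill-conditioned weighted cross-product; increase the neighbour count.")
  }
  solve_A <- function(b) backsolve(ch, backsolve(ch, b, transpose = TRUE))
  beta <- drop(solve_A(crossprod(Xs, y[idx] * sw)))   # (X'WX)^{-1} X'Wy
  xi <- X[focal, ]
  z <- solve_A(xi)                                    # (X'WX)^{-1} x_i
  hat_row <- as.numeric(X %*% z) * w
  list(coefficients = setNames(as.numeric(beta), colnames(X)),
       hat_row = hat_row,
       fitted = sum(xi * beta),
       hat_diag = hat_row[focal])
}

#' Fit a locally weighted regression family (GWR, TWR or GTWR)
#'
#' Fits the local linear model `y_i = beta_0(u_i, v_i, t_i) + sum_k
#' beta_k(u_i, v_i, t_i) x_ik + eps_i` by weighted least squares at every
#' observation. The weighting distance is purely spatial for GWR, purely
#' temporal for TWR, and the combined `sqrt(lambda dS^2 + tau dT^2)` for GTWR
#' (with `lambda` fixed at 1 and `tau` the space-time balance ratio by
#' default). The kernel bandwidth is adaptive: the distance to the `neighbors`-th
#' nearest other observation, used as compact support for the bisquare kernel
#' and as the decay scale for the Gaussian kernel. GTWR reduces to GWR when
#' `tau = 0` and to TWR when `lambda = 0`.
#'
#' @inheritParams fit_ols
#' @param family `"gwr"`, `"twr"` or `"gtwr"`.
#' @param kernel `"bisquare"` or `"gaussian"`; defaults to bisquare for GWR
#'   and Gaussian for TWR/GTWR.
#' @param neighbors Adaptive neighbour count `k` (>= number of coefficients
#'   + 1 recommended). See [select_bandwidth()] for data-driven choice.
#' @param tau Temporal scaling ratio `mu / lambda` for GTWR (ignored for GWR
#'   and TWR).
#' @param lambda Spatial scaling for GTWR; 0 collapses GTWR onto TWR.
#' @param coords `"sphere"` (great-circle km on lon/lat) or `"planar"`.
#' @return An object of class `local_fit` with per-observation coefficients,
#'   fitted values, residuals, hat diagonal, `trace_S` and `sigma_hat`.
#' @examples
#' st <- simulate_stations(8, bounds = c(0, 1, 0, 1), seed = 2)
#' panel <- simulate_covariates(st, n_periods = 12, seed = 2)
#' truth <- simulate_coefficients("constant", beta = c(40, -7), noise_sd = 0)
#' sc <- pca_scores(fit_pca(panel))
#' panel <- simulate_response(panel, sc[, 1], truth, seed = 2)
#' fit <- fit_local_model(cbind(panel, sc[, 1]), "pm25", "PC1",
#'                        family = "gtwr", neighbors = 30, coords = "planar")
#' fit$trace_S
#' @export
fit_local_model <- function(data, response, regressors,
                            family = c("gwr", "twr", "gtwr"),
                            kernel = NULL, neighbors,
                            tau = 1, lambda = 1,
                            coords = c("sphere", "planar")) {
  family <- match.arg(family)
  coords <- match.arg(coords)
  kernel <- kernel %||% if (family == "gwr") "bisquare" else "gaussian"
  kernel <- match.arg(kernel, c("bisquare", "gaussian"))
  eng <- local_engine(data, response, regressors, family, kernel,
                      neighbors, tau, lambda, coords, loo = FALSE)
  new_local_fit(
    family = toupper(family), data = data, response = response,
    regressors = regressors, coefficients = eng$coefficients,
    fitted = eng$fitted, hat = eng$hat, kernel = kernel,
    neighbors = as.integer(neighbors), tau = tau, lambda = lambda,
    coords = coords
  )
}

# core loop shared by fitting and leave-one-out prediction
local_engine <- function(data, response, regressors, family, kernel,
                         neighbors, tau, lambda, coords, loo = FALSE) {
  xy <- model_inputs(data, response, regressors)
  X <- xy$X
  y <- xy$y
  n <- nrow(X)
  p <- ncol(X)
  k <- as.integer(neighbors)
  if (is.na(k) || k < p + 1 || k > n - loo) {
    abort(sprintf("`neighbors` must be in [%d, %d].", p + 1, n - loo))
  }
  if (family == "gtwr" && lambda == 0 && tau == 0) {
    abort("GTWR requires lambda and tau not both zero.")
  }
  need <- switch(family, gwr = c("lon", "lat"), twr = "time",
                 gtwr = c("lon", "lat", "time"))
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    abort(paste0("Family ", toupper(family), " needs column(s): ",
                 paste(missing, collapse = ", ")))
  }

  if (family != "twr") {
    key <- paste(data$lon, data$lat)
    ukey <- unique(key)
    uidx <- match(key, ukey)
    ucoords <- cbind(data$lon, data$lat)[match(ukey, key), , drop = FALSE]
    DSu <- spatial_distance_matrix(ucoords, mode = coords)
  }
  tvec <- if (family != "gwr") as.numeric(data$time)

  coefficients <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(X)))
  fitted <- numeric(n)
  hat <- numeric(n)

  for (i in seq_len(n)) {
    d <- switch(family,
      gwr  = DSu[uidx[i], uidx],
      twr  = abs(tvec - tvec[i]),
      gtwr = sqrt(lambda * DSu[uidx[i], uidx]^2 + tau * (tvec - tvec[i])^2)
    )
    dd <- d
    dd[i] <- Inf
    h <- adaptive_bandwidth(dd, k)
    if (h <= 0) {
      abort(sprintf(
        "Observation %d: bandwidth is zero (>= %d coincident points); increase the neighbour count.",
        i, k))
    }
    w <- if (kernel == "bisquare") bisquare_weight(d, h) else gaussian_weight(d, h)
    if (loo) w[i] <- 0
    res <- withCallingHandlers(
      tryCatch(fit_local_point(X, y, w, focal = i),
               error = function(e) {
                 abort(sprintf("Local fit failed at observation %d: %s",
                               i, conditionMessage(e)))
               }),
      warning = function(w) invokeRestart("muffleWarning")
    )
    coefficients[i, ] <- res$coefficients
    fitted[i] <- res$fitted
    hat[i] <- res$hat_diag
  }
  list(coefficients = coefficients, fitted = fitted, hat = hat)
}

#' @export
print.local_fit <- function(x, ...) {
  cat(sprintf("%s fit: n = %d, %d coefficients (%s)\n", x$family, x$n,
              x$p_model, paste(colnames(x$coefficients), collapse = ", ")))
  if (x$family != "OLS") {
    cat(sprintf("  kernel: adaptive %s, k = %d%s\n", x$kernel, x$neighbors,
                if (x$family == "GTWR")
                  sprintf(", tau = %g, lambda = %g", x$tau, x$lambda) else ""))
  }
  cat(sprintf("  trace(S) = %.2f, sigma_hat = %.3f\n", x$trace_S, x$sigma_hat))
  invisible(x)
}

#' Per-observation coefficients in long form
#'
#' @param x A `local_fit`.
#' @param ... Unused.
#' @return A tibble with the panel keys, `term` and `estimate`.
#' @export
tidy.local_fit <- function(x, ...) {
  out <- dplyr::bind_cols(x$data,
                          tibble::as_tibble(x$coefficients))
  tidyr::pivot_longer(out, dplyr::all_of(colnames(x$coefficients)),
                      names_to = "term", values_to = "estimate")
}

#' One-row goodness-of-fit summary of a fitted model
#'
#' Equivalent to [assess()].
#'
#' @param x A `local_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.local_fit <- function(x, ...) {
  assess(x)
}
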