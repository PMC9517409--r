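#' Corrected Akaike information criterion of a local fit
#'
#' `AICc = 2 n ln(sigma_hat) + n ln(2 pi) + n (n + trS) / (n - 2 - trS)`,
#' with `sigma_hat = sqrt(RSS / n)` and `trS` the trace of the hat matrix
#' (effective number of parameters).
#'
#' @param fit A `local_fit`.
#' @return The AICc value.
#' @export
aicc <- function(fit) {
  stopifnot(inherits(fit, "local_fit"))
  n <- fit$n
  trS <- fit$trace_S
  if (n - 2 - trS <= 0) {
    abort("Over-parameterized fit: trace(S) >= n - 2, AICc undefined.")
  }
  2 * n * log(fit$sigma_hat) + n * log(2 * pi) +
    n * (n + trS) / (n - 2 - trS)
}

#' Leave-one-out cross-validation score for a local family
#'
#' Predicts each observation from a local fit in which the focal observation's
#' own weight is set to zero, and returns the sum of squared prediction
#' errors.
#'
#' @inheritParams fit_local_model
#' @return The CV score (sum of squared leave-one-out errors).
#' @export
loocv_score <- function(data, response, regressors,
                        family = c("gwr", "twr", "gtwr"),
                        kernel = NULL, neighbors, tau = 1, lambda = 1,
                        coords = c("sphere", "planar")) {
  family <- match.arg(family)
  coords <- match.arg(coords)
  kernel <- kernel %||% if (family == "gwr") "bisquare" else "gaussian"
  kernel <- match.arg(kernel, c("bisquare", "gaussian"))
  eng <- local_engine(data, response, regressors, family, kernel,
                      neighbors, tau, lambda, coords, loo = TRUE)
  y <- as.numeric(data[[response]])
  sum((y - eng$fitted)^2)
}

#' Select the adaptive neighbour count (and space-time ratio) by grid search
#'
#' Evaluates AICc (default) or the leave-one-out CV score on an exhaustive
#' grid of neighbour counts `k` (crossed with the temporal ratio `tau` for
#' GTWR) and returns the minimizer. Ties are broken toward larger `k`
#' (the smoother model). Grid points whose local fits fail (for example, `k`
#' too small for the station layout) are recorded as `NA` and skipped.
#'
#' @inheritParams fit_local_model
#' @param k_grid Integer vector of neighbour counts; default 20 log-spaced
#'   values between `p + 2` and `n - 1`.
#' @param tau_grid Numeric vector of temporal ratios (GTWR only); default 7
#'   log-spaced values spanning 1e-3 to 1e3 times the squared space/time
#'   spread ratio.
#' @param criterion `"aicc"` or `"cv"`.
#' @return An object of class `bandwidth_search`: a list with the evaluated
#'   `grid` (tibble of `k`, `tau`, `criterion`), `best_k`, `best_tau`,
#'   `criterion_name` and `family`.
#' @export
select_bandwidth <- function(data, response, regressors,
                             family = c("gwr", "twr", "gtwr"),
                             kernel = NULL, k_grid = NULL, tau_grid = NULL,
                             lambda = 1, coords = c("sphere", "planar"),
                             criterion = c("aicc", "cv")) {
  family <- match.arg(family)
  coords <- match.arg(coords)
  criterion <- match.arg(criterion)
  n <- nrow(data)
  p <- length(regressors) + 1
  if (is.null(k_grid)) {
    k_grid <- unique(round(exp(seq(log(p + 2), log(n - 1), length.out = 20))))
  }
  if (length(k_grid) == 0) abort("`k_grid` is empty.")
  if (family == "gtwr") {
    if (is.null(tau_grid)) {
      ratio <- (spread_of(data, c("lon", "lat"), coords) /
                  max(spread_of(data, "time"), .Machine$double.eps))^2
      tau_grid <- ratio * 10^seq(-3, 3, length.out = 7)
    }
  } else {
    tau_grid <- 1
  }
  if (length(tau_grid) == 0) abort("`tau_grid` is empty.")

  grid <- tidyr::expand_grid(k = sort(as.integer(k_grid)),
                             tau = sort(as.numeric(tau_grid)))
  grid$criterion <- purrr::pmap_dbl(grid, function(k, tau) {
    tryCatch({
      if (criterion == "aicc") {
        aicc(fit_local_model(data, response, regressors, family = family,
                             kernel = kernel, neighbors = k, tau = tau,
                             lambda = lambda, coords = coords))
      } else {
        loocv_score(data, response, regressors, family = family,
                    kernel = kernel, neighbors = k, tau = tau,
                    lambda = lambda, coords = coords)
      }
    }, error = function(e) NA_real_)
  })
  ok <- which(is.finite(grid$criterion))
  if (length(ok) == 0) abort("No feasible grid point: every local fit failed.")
  best_val <- min(grid$criterion[ok])
  cand <- ok[grid$criterion[ok] <= best_val + 1e-12]
  best <- cand[which.max(grid$k[cand])]   # ties toward larger k
  structure(list(grid = grid,
                 best_k = grid$k[best],
                 best_tau = grid$tau[best],
                 best_criterion = grid$criterion[best],
                 criterion_name = criterion,
                 family = toupper(family)),
            class = "bandwidth_search")
}

# crude scale of a coordinate set: mean distance to the centroid
spread_of <- function(data, cols, coords = "planar") {
  if (identical(cols, "time")) {
    t <- as.numeric(data$time)
    return(mean(abs(t - mean(t))))
  }
  xy <- cbind(data$lon, data$lat)
  ctr <- colMeans(xy)
  mean(spatial_distance(xy, matrix(ctr, nrow(xy), 2, byrow = TRUE),
                        mode = coords))
}

#' @export
print.bandwidth_search <- function(x, ...) {
  cat(sprintf("%s bandwidth search (%s): best k = %d", x$family,
              x$criterion_name, x$best_k))
  if (x$family == "GTWR") cat(sprintf(", tau = %.4g", x$best_tau))
  cat(sprintf(", criterion = %.4f\n", x$best_criterion))
  invisible(x)
}

#' Criterion profile of a bandwidth search
#'
#' @param object A `bandwidth_search`.
#' @param ... Unused.
#' @return A ggplot of criterion against neighbour count (one line per tau).
#' @export
autoplot.bandwidth_search <- function(object, ...) {
  df <- object$grid
  df$tau_label <- factor(signif(df$tau, 3))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$criterion,
                                   colour = .data$tau_label)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "neighbours k", y = object$criterion_name,
                  colour = "tau",
                  title = sprintf("%s bandwidth profile", object$family))
}
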