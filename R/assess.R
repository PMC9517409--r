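#' Adjusted coefficient of determination
#'
#' `Ra2 = 1 - (n - 1)(1 - R2) / (n - p)`, where `p` counts all coefficients
#' including the intercept (for local families, the effective count
#' `trace(S)`). Unlike `R2`, it does not inflate with model complexity.
#'
#' @param r2 Coefficient of determination.
#' @param n Sample size.
#' @param p Number of (effective) coefficients including the intercept.
#' @return The adjusted R-squared.
#' @examples
#' adjusted_r2(0.61, 100, 7)
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (any(n <= p)) abort("`adjusted_r2` requires n > p.")
  1 - (n - 1) * (1 - r2) / (n - p)
}

#' Root mean squared error
#' @param y,yhat Observed and fitted vectors of equal length.
#' @return RMSE (same units as `y`, e.g. ug/m3).
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) abort("`y` and `yhat` lengths differ.")
  if (length(y) < 1) abort("Need at least one observation.")
  sqrt(mean((y - yhat)^2))
}

#' Mean absolute error
#' @inheritParams rmse
#' @return MAE (same units as `y`).
#' @export
mae <- function(y, yhat) {
  if (length(y) != length(yhat)) abort("`y` and `yhat` lengths differ.")
  if (length(y) < 1) abort("Need at least one observation.")
  mean(abs(y - yhat))
}

#' Goodness-of-fit assessment of a fitted model
#'
#' Computes the model-comparison metrics from the fitted values and the hat
#' trace: `R2` (about the response mean), adjusted `R2` with the effective
#' coefficient count (`trace(S)`, which equals the plain coefficient count for
#' OLS), AICc, RMSE and MAE.
#'
#' @param fit A `local_fit`.
#' @return A one-row tibble with `family`, `n`, `trace_S`, `r2`,
#'   `adjusted_r2`, `aicc`, `rmse`, `mae`, `sigma_hat`.
#' @export
assess <- function(fit) {
  stopifnot(inherits(fit, "local_fit"))
  y <- fit$fitted + fit$residuals
  tss <- sum((y - mean(y))^2)
  if (tss == 0) abort("Zero response variance; R2 undefined.")
  rss <- sum(fit$residuals^2)
  r2 <- 1 - rss / tss
  tibble::tibble(
    family = fit$family,
    n = fit$n,
    trace_S = fit$trace_S,
    r2 = r2,
    adjusted_r2 = adjusted_r2(r2, fit$n, fit$trace_S),
    aicc = aicc(fit),
    rmse = rmse(y, fit$fitted),
    mae = mae(y, fit$fitted),
    sigma_hat = fit$sigma_hat
  )
}

#' Distribution summary of local coefficients
#'
#' Per-regressor order statistics and moments of the per-observation
#' coefficient estimates: min, mean, max, standard deviation, excess (Fisher)
#' kurtosis and sample skewness. A constant coefficient column reports zero
#' SD with undefined (`NA`) skewness and kurtosis.
#'
#' @param fit A `local_fit` from a local family (GWR/TWR/GTWR).
#' @return A tibble with columns `term`, `min`, `mean`, `max`, `sd`,
#'   `kurtosis`, `skewness`.
#' @export
summarize_coefficients <- function(fit) {
  stopifnot(inherits(fit, "local_fit"))
  if (fit$family == "OLS") {
    abort("Coefficient summaries describe local families; OLS coefficients are global.")
  }
  B <- fit$coefficients
  purrr::map_dfr(colnames(B), function(term) {
    b <- B[, term]
    s <- sd(b)
    tibble::tibble(
      term = term,
      min = min(b), mean = mean(b), max = max(b), sd = s,
      kurtosis = if (s == 0) NA_real_ else e1071::kurtosis(b, type = 2),
      skewness = if (s == 0) NA_real_ else e1071::skewness(b, type = 2)
    )
  })
}

#' Sign consistency between local and global coefficients
#'
#' Checks the qualitative property that the sign of each global OLS
#' coefficient matches the sign of the mean local coefficient for the same
#' regressor — i.e. the local model follows the same overall trend as the
#' global one.
#'
#' @param local_fit A local-family `local_fit`.
#' @param ols_fit The OLS `local_fit` on the same data and regressors.
#' @return A tibble with `term`, `mean_local`, `global`, `consistent`.
#' @export
sign_consistency <- function(local_fit, ols_fit) {
  stopifnot(inherits(local_fit, "local_fit"), inherits(ols_fit, "local_fit"))
  terms <- colnames(local_fit$coefficients)
  if (!identical(terms, colnames(ols_fit$coefficients))) {
    abort("Fits have different coefficient sets.")
  }
  tibble::tibble(
    term = terms,
    mean_local = colMeans(local_fit$coefficients),
    global = ols_fit$coefficients[1, ],
    consistent = sign(colMeans(local_fit$coefficients)) ==
      sign(ols_fit$coefficients[1, ])
  )
}

#' Compare several fitted families in one table
#'
#' @param ... Named or unnamed `local_fit` objects.
#' @return A tibble with one [assess()] row per fit.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  purrr::map_dfr(fits, assess)
}
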