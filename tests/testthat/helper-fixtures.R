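# Shared synthetic fixtures, all generated in code at test time.

UNIT_BOX <- c(0, 1, 0, 1)

# Small station panel on the unit box with PCA scores attached as regressors
# and a PM response simulated from `preset` truth on the leading scores.
make_model_panel <- function(n_stations = 8, n_periods = 12, seed = 42,
                             preset = "constant",
                             beta = c(40, -7, 5), noise_sd = 0,
                             n_scores = length(beta) - 1,
                             config = panel_config(), ...) {
  st <- simulate_stations(n_stations, UNIT_BOX, seed = seed)
  panel <- simulate_covariates(st, n_periods, seed = seed + 1,
                               config = config)
  pca <- fit_pca(panel)
  scores <- pca$scores[, seq_len(n_scores), drop = FALSE]
  truth <- simulate_coefficients(preset, beta = beta, bounds = UNIT_BOX,
                                 noise_sd = noise_sd, ...)
  panel <- simulate_response(panel, scores, truth, seed = seed + 2)
  list(data = dplyr::bind_cols(panel, scores),
       regressors = names(scores),
       truth = truth, pca = pca,
       true_beta = attr(panel, "true_beta"))
}

# coefficient RMSE per slope term against the generator's truth
coef_rmse <- function(fit, true_beta) {
  terms <- colnames(fit$coefficients)
  vapply(seq_along(terms), function(j) {
    sqrt(mean((fit$coefficients[, j] - true_beta[, j])^2))
  }, numeric(1)) |> setNames(terms)
}
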