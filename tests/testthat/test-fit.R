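test_that("OLS matches the normal-equation oracle and its hat trace", {
  set.seed(11)
  d <- tibble::tibble(x1 = rnorm(50), x2 = rnorm(50), x3 = rnorm(50))
  d$y <- 1 + 2 * d$x1 - d$x2 + 0.5 * d$x3 + rnorm(50)
  fit <- fit_ols(d, "y", c("x1", "x2", "x3"))
  X <- cbind(1, as.matrix(d[, c("x1", "x2", "x3")]))
  beta_oracle <- solve(t(X) %*% X) %*% t(X) %*% d$y
  expect_equal(unname(fit$coefficients[1, ]), unname(drop(beta_oracle)),
               tolerance = 1e-8)
  # all rows identical; trace(S) equals the coefficient count
  expect_true(all(apply(fit$coefficients, 2, function(col) all(col == col[1]))))
  expect_equal(fit$trace_S, 4, tolerance = 1e-10)
  expect_equal(fit$fitted, drop(X %*% beta_oracle), tolerance = 1e-8)

  # noiseless data: exact fit
  d$y0 <- 3 - d$x1
  f0 <- fit_ols(d, "y0", c("x1"))
  expect_equal(max(abs(f0$residuals)), 0, tolerance = 1e-10)
  expect_equal(assess(f0)$r2, 1, tolerance = 1e-12)

  # rank deficiency names the dependent column
  d$x1dup <- d$x1
  expect_error(fit_ols(d, "y", c("x1", "x1dup")), "x1dup")
})

test_that("with centered orthogonal score regressors the intercept is the response mean", {
  fx <- make_model_panel(n_stations = 10, n_periods = 20, seed = 61,
                         preset = "constant", noise_sd = 5)
  fit <- fit_ols(fx$data, "pm25", fx$regressors)
  expect_equal(unname(fit$coefficients[1, "(Intercept)"]),
               mean(fx$data$pm25), tolerance = 1e-8)
})

test_that("local WLS matches the sqrt-weight-transformed oracle", {
  set.seed(12)
  n <- 40
  X <- cbind(1, rnorm(n), runif(n))
  y <- X %*% c(2, -1, 3) + rnorm(n)
  w <- runif(n)
  w[sample(n, 5)] <- 0
  res <- fit_local_point(X, y, w, focal = 1)
  W <- diag(w)
  beta_oracle <- solve(t(X) %*% W %*% X) %*% t(X) %*% W %*% y
  expect_equal(unname(res$coefficients), drop(beta_oracle), tolerance = 1e-8)
  hat_oracle <- t(X[1, ]) %*% solve(t(X) %*% W %*% X) %*% t(X) %*% W
  expect_equal(res$hat_row, drop(hat_oracle), tolerance = 1e-8)
  expect_equal(res$fitted, drop(hat_oracle %*% y), tolerance = 1e-8)

  # uniform weights reduce to OLS
  res1 <- fit_local_point(X, y, rep(1, n), focal = 3)
  beta_ols <- solve(t(X) %*% X) %*% t(X) %*% y
  expect_equal(unname(res1$coefficients), drop(beta_ols), tolerance = 1e-8)

  # weights concentrated on exactly p points interpolate them
  w2 <- rep(0, n); w2[1:3] <- 1
  res2 <- fit_local_point(X, y, w2, focal = 1)
  expect_equal(res2$fitted, y[1], tolerance = 1e-8)

  # too few positive weights
  expect_error(fit_local_point(X, y, c(1, 1, rep(0, n - 2))), "neighbour")
})

test_that("noiseless constant truth is recovered exactly by every family", {
  fx <- make_model_panel(n_stations = 8, n_periods = 12, seed = 71,
                         preset = "constant", beta = c(40, -7, 5),
                         noise_sd = 0)
  d <- fx$data
  truth <- c(40, -7, 5)

  for (fam in c("gwr", "twr", "gtwr")) {
    for (k in c(30, 60, 90)) {
      fit <- fit_local_model(d, "pm25", fx$regressors, family = fam,
                             neighbors = k, coords = "planar")
      expect_lt(max(abs(sweep(fit$coefficients, 2, truth))), 1e-8)
      expect_equal(assess(fit)$adjusted_r2, 1, tolerance = 1e-10)
    }
  }
})

test_that("GTWR reduces to GWR when tau = 0 and to TWR when lambda = 0", {
  fx <- make_model_panel(n_stations = 6, n_periods = 50, seed = 81,
                         preset = "space-time", beta = c(40, -7, 5),
                         noise_sd = 5)
  d <- fx$data
  regs <- fx$regressors

  gwr <- fit_local_model(d, "pm25", regs, family = "gwr",
                         kernel = "bisquare", neighbors = 120,
                         coords = "planar")
  gtwr_s <- fit_local_model(d, "pm25", regs, family = "gtwr",
                            kernel = "bisquare", neighbors = 120,
                            tau = 0, lambda = 1, coords = "planar")
  expect_equal(gtwr_s$coefficients, gwr$coefficients, tolerance = 1e-10)
  expect_equal(gtwr_s$hat, gwr$hat, tolerance = 1e-10)

  twr <- fit_local_model(d, "pm25", regs, family = "twr",
                         kernel = "gaussian", neighbors = 40,
                         coords = "planar")
  gtwr_t <- fit_local_model(d, "pm25", regs, family = "gtwr",
                            kernel = "gaussian", neighbors = 40,
                            tau = 1, lambda = 0, coords = "planar")
  expect_equal(gtwr_t$coefficients, twr$coefficients, tolerance = 1e-10)
})

test_that("hat matrix is consistent: fitted = S y and trace in range", {
  fx <- make_model_panel(n_stations = 6, n_periods = 10, seed = 91,
                         preset = "space-time", beta = c(40, -7),
                         noise_sd = 3)
  d <- fx$data
  fit <- fit_local_model(d, "pm25", fx$regressors, family = "gtwr",
                         neighbors = 25, coords = "planar")
  # rebuild full hat rows via fit_local_point and verify fitted = S y
  X <- cbind("(Intercept)" = 1, as.matrix(d[, fx$regressors]))
  y <- d$pm25
  DS <- as.matrix(dist(cbind(d$lon, d$lat)))
  S <- matrix(0, nrow(d), nrow(d))
  tau <- fit$tau
  for (i in seq_len(nrow(d))) {
    dd <- sqrt(DS[i, ]^2 + tau * (d$time - d$time[i])^2)
    di <- dd; di[i] <- Inf
    h <- sort(di)[25]
    w <- exp(-(dd / h)^2)
    S[i, ] <- fit_local_point(X, y, w, focal = i)$hat_row
  }
  expect_equal(drop(S %*% y), fit$fitted, tolerance = 1e-10)
  expect_equal(sum(diag(S)), fit$trace_S, tolerance = 1e-10)
  expect_gte(fit$trace_S, ncol(X))
})

test_that("local families degrade to checkable errors on infeasible setups", {
  fx <- make_model_panel(n_stations = 4, n_periods = 10, seed = 101,
                         preset = "constant", beta = c(40, -7), noise_sd = 1)
  d <- fx$data
  # GWR with k below the per-station record count -> zero bandwidth
  expect_error(fit_local_model(d, "pm25", fx$regressors, family = "gwr",
                               neighbors = 5, coords = "planar"),
               "neighbour|bandwidth")
  expect_error(fit_local_model(d, "pm25", fx$regressors, family = "gtwr",
                               neighbors = 2, coords = "planar"),
               "neighbors")
  expect_error(fit_local_model(d, "pm25", fx$regressors, family = "gtwr",
                               neighbors = 20, tau = 0, lambda = 0,
                               coords = "planar"),
               "both")
})

test_that("tidy and glance expose local fits", {
  fx <- make_model_panel(seed = 111, preset = "constant", noise_sd = 1)
  fit <- fit_local_model(fx$data, "pm25", fx$regressors, family = "gtwr",
                         neighbors = 40, coords = "planar")
  td <- tidy(fit)
  expect_equal(nrow(td), fit$n * fit$p_model)
  expect_true(all(c("station_id", "time", "term", "estimate") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$family, "GTWR")
  expect_true(gl$rmse >= gl$mae)
})
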