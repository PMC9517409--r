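test_that("standardization centers, scales, validates and round-trips", {
  set.seed(1)
  d <- tibble::tibble(a = rnorm(50, 10, 3), b = runif(50, -5, 5),
                      c = rnorm(50, 0, 0.01))
  std <- standardize(d, c("a", "b", "c"))
  expect_lt(max(abs(colMeans(std$z))), 1e-10)
  expect_equal(unname(apply(std$z, 2, sd)), c(1, 1, 1), tolerance = 1e-10)
  back <- destandardize(std)
  expect_equal(unname(back), unname(as.matrix(d)), tolerance = 1e-10)

  d$const <- 1
  expect_error(standardize(d, c("a", "const")), "const")
})

test_that("KMO equals 0.5 for any 2-variable dataset and stays in [0,1]", {
  # p = 2: the anti-image partial correlation equals the simple correlation,
  # so the ratio collapses to 1/2 no matter the data
  set.seed(2)
  for (i in 1:5) {
    x <- rnorm(40)
    y <- 0.5 * x + rnorm(40)
    expect_equal(kmo_statistic(cbind(x, y)), 0.5, tolerance = 1e-12)
  }
  # brute-force anti-image oracle on a random 4-variable problem
  z <- matrix(rnorm(200), 50, 4)
  R <- cor(z)
  P <- solve(R)
  q <- -P / sqrt(outer(diag(P), diag(P)))
  off <- upper.tri(R)
  oracle <- sum(R[off]^2) / (sum(R[off]^2) + sum(q[off]^2))
  expect_equal(kmo_statistic(z), oracle, tolerance = 1e-12)

  for (i in 1:50) {
    z <- matrix(rnorm(30 * 5), 30, 5)
    k <- kmo_statistic(z)
    expect_true(k >= 0 && k <= 1)
  }
})

test_that("Bartlett sphericity matches the closed form and its null", {
  # independent columns, large n: statistic near dof, p not small
  set.seed(3)
  z <- matrix(rnorm(4000 * 4), ncol = 4)
  bt <- bartlett_sphericity(z)
  expect_equal(bt$dof, 6)
  expect_gt(bt$p_value, 1e-4)
  expect_lt(bt$statistic, 30)

  # direct formula oracle on arbitrary data
  z <- matrix(rnorm(100 * 3), 100, 3)
  z[, 2] <- z[, 1] * 0.7 + z[, 2]
  bt <- bartlett_sphericity(z)
  R <- cor(z)
  expect_equal(bt$statistic,
               -(100 - 1 - (2 * 3 + 5) / 6) * log(det(R)),
               tolerance = 1e-10)
  expect_equal(bt$p_value,
               pchisq(bt$statistic, 3, lower.tail = FALSE),
               tolerance = 1e-12)

  # collinear pair -> not positive definite
  z <- cbind(z, z[, 1])
  expect_error(bartlett_sphericity(z), "positive definite")
})

test_that("correlation-matrix PCA selects components at the variance cut", {
  # rank-1 limit: duplicated variable -> one component carries everything
  set.seed(4)
  x <- rnorm(60)
  d <- tibble::tibble(a = x, b = 2 * x + 1e-8 * rnorm(60),
                      c = -x + 1e-8 * rnorm(60))
  m <- fit_pca(d, c("a", "b", "c"), threshold = 0.85)
  expect_equal(m$n_selected, 1)
  expect_gt(m$proportions[1], 0.999)

  # proportions always sum to 1; eigenvalues sum to p; cumulative monotone
  z <- tibble::as_tibble(matrix(rnorm(300), 50, 6), .name_repair = "minimal")
  names(z) <- letters[1:6]
  m <- fit_pca(z, letters[1:6], threshold = 0.85)
  expect_equal(sum(m$proportions), 1, tolerance = 1e-10)
  expect_equal(sum(m$eigenvalues), 6, tolerance = 1e-8)
  expect_true(all(diff(m$cumulative) >= -1e-12))
  expect_true(m$cumulative[m$n_selected] >= 0.85 - 1e-12)

  # isotropic null: all eigenvalues near 1, m near ceiling(0.85 p)
  z <- tibble::as_tibble(matrix(rnorm(20000 * 8), ncol = 8),
                         .name_repair = "minimal")
  names(z) <- letters[1:8]
  m <- fit_pca(z, letters[1:8])
  expect_true(all(abs(m$eigenvalues - 1) < 0.1))
  expect_true(abs(m$n_selected - ceiling(0.85 * 8)) <= 1)

  expect_error(fit_pca(z, letters[1:8], threshold = 1.2), "threshold")
})

test_that("eigendecomposition loadings agree with an SVD route", {
  set.seed(5)
  fx <- make_model_panel(seed = 31)
  m <- fx$pca
  z <- m$standardizer$z
  sv <- svd(z / sqrt(nrow(z) - 1))
  L_svd <- sv$v %*% diag(sv$d)
  L_eig <- m$loadings_unrotated
  for (k in seq_len(ncol(L_eig))) {
    s <- sign(sum(L_svd[, k] * L_eig[, k]))
    expect_equal(unname(L_eig[, k]), unname(s * L_svd[, k]), tolerance = 1e-8)
  }
})

test_that("varimax rotation ascends the criterion, preserves communalities,
           and matches the reference implementation", {
  set.seed(6)
  for (i in 1:5) {
    L <- matrix(rnorm(18), 6, 3)
    vr <- varimax_rotate(L)
    # orthogonality of the rotation
    expect_equal(crossprod(vr$rotmat), diag(3), tolerance = 1e-10)
    # ascent of the varimax criterion
    expect_gte(vr$criterion, varimax_criterion(L) - 1e-12)
    # communalities preserved
    expect_equal(rowSums(vr$loadings^2), rowSums(L^2), tolerance = 1e-8)
    # loadings = input %*% rotation
    expect_equal(L %*% vr$rotmat, unname(vr$loadings), tolerance = 1e-10)

    # independent reference: stats::varimax, aligned up to sign/permutation
    ref <- stats::varimax(L, normalize = TRUE, eps = 1e-12)
    refL <- unclass(ref$loadings)
    expect_equal(vr$criterion, varimax_criterion(refL), tolerance = 1e-9)
    cost <- abs(crossprod(vr$loadings, refL))   # column correspondence
    perm <- apply(cost, 1, which.max)
    expect_identical(sort(perm), 1:3)
    for (k in 1:3) {
      a <- vr$loadings[, k]
      b <- refL[, perm[k]]
      if (sum(a * b) < 0) b <- -b
      expect_equal(a, b, tolerance = 1e-5)
    }
    # the reference accepts our solution as a fixed point
    ref2 <- unclass(stats::varimax(vr$loadings, normalize = TRUE,
                                   eps = 1e-12)$loadings)
    expect_equal(unname(ref2), unname(vr$loadings), tolerance = 1e-7)
  }
})

test_that("perfect simple structure is a varimax fixed point", {
  L <- rbind(c(0.9, 0), c(0.8, 0), c(0, 0.7), c(0, 0.95))
  vr <- varimax_rotate(L)
  cost <- abs(crossprod(vr$loadings, L))
  perm <- apply(cost, 1, which.max)
  expect_identical(sort(perm), 1:2)
  for (k in 1:2) {
    a <- abs(vr$loadings[, k])
    expect_equal(a, abs(L[, perm[k]]), tolerance = 1e-8)
  }
  # single component: returned unchanged with identity rotation
  one <- varimax_rotate(L[, 1, drop = FALSE])
  expect_identical(one$rotmat, diag(1))
  expect_equal(one$loadings, L[, 1, drop = FALSE])
})

test_that("scores are uncorrelated unrotated, unit variance standardized,
           deterministic, and reconstruct the data to the variance bound", {
  fx <- make_model_panel(n_stations = 10, n_periods = 30, seed = 41)
  m <- fx$pca

  raw <- as.matrix(pca_scores(m, rotated = FALSE, scale = "raw"))
  C <- cov(raw)
  expect_lt(max(abs(C[upper.tri(C)])), 1e-8)

  s1 <- pca_scores(m)
  s2 <- pca_scores(m, data = fx$data)
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_equal(unname(apply(as.matrix(s1), 2, sd)),
               rep(1, m$n_selected), tolerance = 1e-8)

  # truncated reconstruction: relative error bounded by 1 - cumulative share
  z <- m$standardizer$z
  zhat <- as.matrix(s1) %*% t(m$loadings)
  rel_err <- sum((z - zhat)^2) / sum(z^2)
  expect_lte(rel_err, 1 - m$cumulative[m$n_selected] + 1e-8)

  # rotation preserves the fitted projection
  unrot <- as.matrix(pca_scores(m, rotated = FALSE))
  m_sel <- m$n_selected
  zhat_unrot <- unrot %*% t(m$loadings_unrotated[, seq_len(m_sel)])
  expect_equal(zhat, zhat_unrot, tolerance = 1e-8)

  expect_error(pca_scores(m, data = fx$data[, 1:4]), "lacks model columns")
})

test_that("rotated components recover and label the generating blocks", {
  st <- simulate_stations(30, seed = 8)
  panel <- simulate_covariates(st, 60, seed = 8)
  m <- fit_pca(panel)
  expect_gte(m$n_selected, 5)
  lab <- label_components(m)
  # every selected component labelled by a distinct generating block
  expect_true(all(lab$label %in% names(covariate_blocks())))
  expect_false(any(duplicated(lab$label)))
  if (m$n_selected == 6) {
    expect_setequal(lab$label, names(covariate_blocks()))
  }

  # all loadings below threshold -> unlabeled
  L <- matrix(0.3, 4, 2, dimnames = list(letters[1:4], c("PC1", "PC2")))
  expect_true(all(label_components(L)$label == "unlabeled"))
})

test_that("tidy and glance expose loadings and adequacy", {
  fx <- make_model_panel(seed = 51)
  m <- fx$pca
  td <- tidy(m)
  expect_equal(nrow(td), 20 * m$n_selected)
  expect_named(td, c("variable", "component", "loading"))
  gl <- glance(m)
  expect_equal(gl$n_selected, m$n_selected)
  expect_true(gl$kmo > 0 && gl$kmo < 1)
  expect_equal(gl$bartlett_dof, 190)
})
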