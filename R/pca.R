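#' Standardize covariate columns
#'
#' Centers and scales each column to mean 0, standard deviation 1 (sample sd,
#' n - 1 divisor). Required before a correlation-matrix PCA because the
#' covariates carry incommensurate units (hPa, degC, m/s, ...).
#'
#' @param data A data frame.
#' @param columns Character vector of column names to standardize; defaults to
#'   the intersection of [covariate_names()] with `names(data)`.
#' @return A list of class `standardizer` with elements `z` (matrix), `center`,
#'   `scale` and `columns`.
#' @export
standardize <- function(data, columns = NULL) {
  columns <- columns %||% intersect(covariate_names(), names(data))
  if (length(columns) == 0) abort("No columns to standardize.")
  missing <- setdiff(columns, names(data))
  if (length(missing)) {
    abort(paste0("Columns not found: ", paste(missing, collapse = ", ")))
  }
  x <- as.matrix(data[, columns, drop = FALSE])
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort("Standardization requires finite numeric columns.")
  }
  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  zero <- scale == 0 | !is.finite(scale)
  if (any(zero)) {
    abort(paste0("Zero-variance column(s): ",
                 paste(columns[zero], collapse = ", ")))
  }
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  structure(list(z = z, center = center, scale = scale, columns = columns),
            class = "standardizer")
}

#' @rdname standardize
#' @param z A standardized matrix (or a `standardizer`, in which case its own
#'   `z` is back-transformed).
#' @param std The `standardizer` carrying the stored means and sds.
#' @return `destandardize()`: the matrix on the original scale.
#' @export
destandardize <- function(z, std) {
  if (inherits(z, "standardizer")) {
    std <- z
    z <- z$z
  }
  stopifnot(inherits(std, "standardizer"))
  sweep(sweep(z, 2, std$scale, "*"), 2, std$center, "+")
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall MSA: `sum(r^2) / (sum(r^2) + sum(q^2))` over off-diagonal simple
#' correlations `r` and anti-image partial correlations `q`. Values above 0.5
#' are conventionally deemed adequate for PCA.
#'
#' @param x A numeric matrix or data frame of observations x variables (or a
#'   `standardizer`).
#' @return A single number in `[0, 1]`.
#' @export
kmo_statistic <- function(x) {
  z <- if (inherits(x, "standardizer")) x$z else as.matrix(x)
  if (nrow(z) < 3) abort("KMO requires at least 3 records.")
  R <- cor(z)
  Rinv <- tryCatch(solve(R), error = function(e) {
    abort("Correlation matrix is singular; KMO undefined.")
  })
  d <- 1 / sqrt(diag(Rinv))
  Q <- -Rinv * outer(d, d)        # anti-image partial correlations
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
}

#' Bartlett's test of sphericity
#'
#' Tests the null that the correlation matrix is the identity, via
#' `chi2 = -(n - 1 - (2p + 5)/6) * log det(R)` on `p(p-1)/2` degrees of
#' freedom.
#'
#' @inheritParams kmo_statistic
#' @return A tibble with `statistic`, `dof` and `p_value`.
#' @export
bartlett_sphericity <- function(x) {
  z <- if (inherits(x, "standardizer")) x$z else as.matrix(x)
  n <- nrow(z)
  p <- ncol(z)
  if (n <= p) abort("Bartlett's test requires more records than variables.")
  R <- cor(z)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12) {
    abort("Correlation matrix is not positive definite (collinear variables?).")
  }
  logdet <- sum(log(ev))
  stat <- -(n - 1 - (2 * p + 5) / 6) * logdet
  dof <- p * (p - 1) / 2
  tibble::tibble(statistic = stat, dof = dof,
                 p_value = pchisq(stat, dof, lower.tail = FALSE))
}

#' Principal component analysis with varimax rotation for covariate reduction
#'
#' Standardizes the covariates, eigendecomposes their correlation matrix,
#' retains the smallest number of components whose cumulative variance
#' proportion reaches `threshold`, varimax-rotates the retained loadings for
#' interpretability, and computes standardized component scores to be used as
#' regressors. Loadings are scaled as variable-component correlations
#' (eigenvector times sqrt eigenvalue); each rotated component is sign-flipped
#' so its dominant variable loads positively. KMO and Bartlett diagnostics are
#' computed alongside.
#'
#' @param data A data frame (station panel).
#' @param columns Covariate columns; defaults as in [standardize()].
#' @param threshold Cumulative variance proportion required (in (0, 1]);
#'   default 0.85.
#' @param rotate Varimax-rotate the retained components? Default `TRUE`.
#' @return An object of class `pca_model` with eigenvalues, variance
#'   proportions, (rotated) loadings, the orthogonal rotation matrix, the
#'   standardizer, adequacy diagnostics and a tibble of scores (`PC1`...).
#' @examples
#' st <- simulate_stations(10, seed = 1)
#' panel <- simulate_covariates(st, n_periods = 30, seed = 1)
#' fit <- fit_pca(panel)
#' fit$n_selected
#' @export
fit_pca <- function(data, columns = NULL, threshold = 0.85, rotate = TRUE) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    abort("`threshold` must lie in (0, 1].")
  }
  std <- standardize(data, columns)
  z <- std$z
  n <- nrow(z)
  p <- ncol(z)
  if (n <= p) abort("PCA requires more records than variables.")
  R <- cor(z)
  eig <- eigen(R, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  V <- eig$vectors
  prop <- lambda / p
  cumprop <- cumsum(prop)
  m <- which(cumprop >= threshold - 1e-12)[1]
  if (is.na(m)) m <- p
  loadings_all <- V %*% diag(sqrt(lambda), p)
  dimnames(loadings_all) <- list(std$columns, paste0("PC", seq_len(p)))

  L <- loadings_all[, seq_len(m), drop = FALSE]
  if (rotate && m >= 2) {
    vr <- varimax_rotate(L)
    L_rot <- vr$loadings
    rotmat <- vr$rotmat
  } else {
    L_rot <- L
    rotmat <- diag(m)
  }
  # sign convention: dominant variable of each component loads positively
  flips <- apply(L_rot, 2, function(col) sign(col[which.max(abs(col))]))
  flips[flips == 0] <- 1
  L_rot <- sweep(L_rot, 2, flips, "*")
  rotmat <- sweep(rotmat, 2, flips, "*")
  # order components by rotated variance explained (sum of squared loadings)
  ord <- order(colSums(L_rot^2), decreasing = TRUE)
  L_rot <- L_rot[, ord, drop = FALSE]
  rotmat <- rotmat[, ord, drop = FALSE]
  colnames(L_rot) <- paste0("PC", seq_len(m))
  colnames(rotmat) <- paste0("PC", seq_len(m))

  model <- structure(list(
    standardizer = std,
    correlation = R,
    eigenvalues = lambda,
    proportions = prop,
    cumulative = cumprop,
    threshold = threshold,
    n_selected = m,
    loadings_unrotated = loadings_all,
    loadings = L_rot,
    rotmat = rotmat,
    rotated = rotate && m >= 2,
    # adequacy diagnostics are advisory: undefined (NA) for singular inputs
    kmo = tryCatch(kmo_statistic(z), error = function(e) NA_real_),
    bartlett = tryCatch(bartlett_sphericity(z), error = function(e) {
      tibble::tibble(statistic = NA_real_, dof = p * (p - 1) / 2,
                     p_value = NA_real_)
    }),
    n = n
  ), class = "pca_model")
  model$scores <- pca_scores(model)
  model
}

#' Varimax rotation by pairwise planar rotations
#'
#' Maximizes the varimax criterion (the summed column variances of squared
#' loadings) over orthogonal rotations, using classical pairwise Jacobi sweeps
#' with Kaiser row normalization. Communalities are invariant under the
#' rotation. A single-column input is returned unchanged with an identity
#' rotation.
#'
#' @param loadings A variables x components loading matrix (>= 1 column).
#' @param normalize Kaiser-normalize rows before rotating? Default `TRUE`.
#' @param eps Convergence tolerance on the largest pairwise rotation angle
#'   (radians) within a sweep.
#' @param max_sweeps Maximum number of full pairwise sweeps.
#' @return A list with `loadings` (rotated), `rotmat` (orthogonal, such that
#'   `loadings_in %*% rotmat = loadings_out`) and `criterion`.
#' @export
varimax_rotate <- function(loadings, normalize = TRUE, eps = 1e-10,
                           max_sweeps = 1000) {
  L <- as.matrix(loadings)
  m <- ncol(L)
  if (m < 1) abort("Need at least one component.")
  if (m == 1) {
    return(list(loadings = L, rotmat = diag(1),
                criterion = varimax_criterion(L, normalize = normalize)))
  }
  h <- sqrt(rowSums(L^2))
  if (normalize) {
    h[h == 0] <- 1
    A <- L / h
  } else {
    A <- L
  }
  nr <- nrow(A)
  rotmat <- diag(m)
  crit_old <- varimax_crit_raw(A)
  for (sweep_i in seq_len(max_sweeps)) {
    max_theta <- 0
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        x <- A[, i]; y <- A[, j]
        u <- x^2 - y^2
        v <- 2 * x * y
        Asum <- sum(u); Bsum <- sum(v)
        Csum <- sum(u^2 - v^2); Dsum <- 2 * sum(u * v)
        num <- Dsum - 2 * Asum * Bsum / nr
        den <- Csum - (Asum^2 - Bsum^2) / nr
        theta <- atan2(num, den) / 4
        max_theta <- max(max_theta, abs(theta))
        if (abs(theta) > 1e-14) {
          cs <- cos(theta); sn <- sin(theta)
          A[, i] <- cs * x + sn * y
          A[, j] <- -sn * x + cs * y
          ri <- rotmat[, i]; rj <- rotmat[, j]
          rotmat[, i] <- cs * ri + sn * rj
          rotmat[, j] <- -sn * ri + cs * rj
        }
      }
    }
    crit_new <- varimax_crit_raw(A)
    crit_old <- crit_new
    if (max_theta < eps) break   # quadratic convergence near the optimum
  }
  out <- if (normalize) A * h else A
  dimnames(out) <- dimnames(L)
  list(loadings = out, rotmat = rotmat,
       criterion = varimax_criterion(out, normalize = normalize))
}

varimax_crit_raw <- function(A) {
  nr <- nrow(A)
  sq <- A^2
  sum(colSums(sq^2) - colSums(sq)^2 / nr)
}

#' @rdname varimax_rotate
#' @export
varimax_criterion <- function(loadings, normalize = TRUE) {
  A <- as.matrix(loadings)
  if (normalize) {
    h <- sqrt(rowSums(A^2))
    h[h == 0] <- 1
    A <- A / h
  }
  varimax_crit_raw(A)
}

#' Component scores from a fitted PCA model
#'
#' Scores are computed from standardized data. Unrotated raw scores are the
#' projections `z %*% V_m` (variance = eigenvalue, pairwise uncorrelated on
#' the fit sample); standardized scores divide by `sqrt(lambda)` so each
#' column has unit sample variance; rotated scores apply the orthogonal
#' varimax rotation to the standardized scores, preserving unit variance.
#' The rotated, standardized scores are the regressors used downstream.
#'
#' @param model A `pca_model`.
#' @param data Optional new data containing the model's covariate columns;
#'   defaults to the fit sample.
#' @param rotated Apply the varimax rotation (default: as fitted)?
#' @param scale `"standardized"` (unit variance, default) or `"raw"`
#'   (variance = eigenvalue; only meaningful unrotated).
#' @return A tibble of scores with columns `PC1` ... `PCm`.
#' @export
pca_scores <- function(model, data = NULL, rotated = model$rotated,
                       scale = c("standardized", "raw")) {
  stopifnot(inherits(model, "pca_model"))
  scale <- match.arg(scale)
  std <- model$standardizer
  if (is.null(data)) {
    z <- std$z
  } else {
    missing <- setdiff(std$columns, names(data))
    if (length(missing)) {
      abort(paste0("`data` lacks model columns: ",
                   paste(missing, collapse = ", ")))
    }
    x <- as.matrix(data[, std$columns, drop = FALSE])
    z <- sweep(sweep(x, 2, std$center), 2, std$scale, "/")
  }
  m <- model$n_selected
  lam <- model$eigenvalues[seq_len(m)]
  V <- model$loadings_unrotated[, seq_len(m), drop = FALSE] %*%
    diag(1 / sqrt(lam), m)                 # back to eigenvectors
  raw <- z %*% V                           # projections, variance = lambda
  if (scale == "raw") {
    if (rotated) abort("Raw-scale scores are only defined unrotated.")
    colnames(raw) <- paste0("PC", seq_len(m))
    return(tibble::as_tibble(raw))
  }
  std <- sweep(raw, 2, sqrt(lam), "/")     # unit sample variance
  s <- if (rotated) std %*% model$rotmat else std
  colnames(s) <- paste0("PC", seq_len(m))
  tibble::as_tibble(s)
}

#' Label rotated components by their dominant covariate block
#'
#' A component's markers are the variables whose absolute rotated loading
#' meets `threshold`; the label is the block containing the majority of the
#' markers, or `"unlabeled"` when no variable passes.
#'
#' @param model A `pca_model` (or a loading matrix).
#' @param blocks Named list mapping block labels to variable names.
#' @param threshold Absolute-loading cutoff, default 0.7.
#' @return A tibble with `component`, `label`, `n_markers`, `markers`.
#' @export
label_components <- function(model, blocks = covariate_blocks(),
                             threshold = 0.7) {
  L <- if (inherits(model, "pca_model")) model$loadings else as.matrix(model)
  vars <- rownames(L)
  if (is.null(vars)) abort("Loadings must have variable row names.")
  purrr::map_dfr(seq_len(ncol(L)), function(k) {
    markers <- vars[abs(L[, k]) >= threshold]
    if (length(markers) == 0) {
      label <- "unlabeled"
    } else {
      counts <- vapply(blocks, function(b) sum(markers %in% b), integer(1))
      label <- if (max(counts) == 0) "unlabeled" else
        names(counts)[which.max(counts)]
    }
    tibble::tibble(component = colnames(L)[k] %||% paste0("PC", k),
                   label = label, n_markers = length(markers),
                   markers = paste(markers, collapse = ","))
  })
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA model: %d variables, %d records\n",
              length(x$standardizer$columns), x$n))
  cat(sprintf("  components selected: %d (cumulative variance %.1f%% >= %.0f%%)\n",
              x$n_selected, 100 * x$cumulative[x$n_selected],
              100 * x$threshold))
  cat(sprintf("  KMO = %.3f; Bartlett chi2 = %.1f (df %d, p %.3g)\n",
              x$kmo, x$bartlett$statistic, x$bartlett$dof, x$bartlett$p_value))
  cat(if (x$rotated) "  loadings: varimax-rotated\n" else "  loadings: unrotated\n")
  invisible(x)
}

#' Tidy a PCA model into a long loading table
#'
#' @param x A `pca_model`.
#' @param ... Unused.
#' @return A tibble with `variable`, `component`, `loading`.
#' @export
tidy.pca_model <- function(x, ...) {
  L <- x$loadings
  tibble::as_tibble(L, rownames = "variable") |>
    tidyr::pivot_longer(-"variable", names_to = "component",
                        values_to = "loading")
}

#' One-row summary of a PCA model
#'
#' @param x A `pca_model`.
#' @param ... Unused.
#' @return A tibble with selection and adequacy diagnostics.
#' @export
glance.pca_model <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    p = length(x$standardizer$columns),
    n_selected = x$n_selected,
    cumulative_variance = x$cumulative[x$n_selected],
    kmo = x$kmo,
    bartlett_statistic = x$bartlett$statistic,
    bartlett_dof = x$bartlett$dof,
    bartlett_p = x$bartlett$p_value
  )
}

#' Heatmap of rotated loadings
#'
#' @param object A `pca_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pca_model <- function(object, ...) {
  df <- tidy(object)
  df$variable <- factor(df$variable, levels = rev(rownames(object$loadings)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component, y = .data$variable,
                                   fill = .data$loading)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "loading",
                  title = "Varimax-rotated component loadings")
}
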