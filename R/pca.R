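#' Principal component analysis of spectra
#'
#' PCA of the mean-centered intensity rows via singular value decomposition.
#' Explained-variance fractions use all eigenvalues in the denominator.
#' Sign convention: the largest-magnitude element of every loading row is
#' made positive, so loadings are bit-reproducible across runs.
#'
#' @param dataset A [spectral_dataset()].
#' @param n_components Components to retain;
#'   `<= min(n_spectra - 1, n_points)`.
#' @return A `pca_model`: `mean`, `loadings` (k x p, orthonormal rows),
#'   `eigenvalues` (all), `explained_variance` (fractions for the retained
#'   components), `wavenumbers`.
#' @export
fit_pca <- function(dataset, n_components = 2L) {
  X <- dataset$intensities
  n <- nrow(X); p <- ncol(X)
  n_components <- as.integer(n_components)
  if (n_components > min(n - 1L, p)) {
    stop("n_components (", n_components, ") exceeds min(n_spectra - 1, n_points) = ",
         min(n - 1L, p))
  }
  mu <- colMeans(X)
  sv <- svd(sweep(X, 2, mu))
  lambda <- sv$d^2 / (n - 1)
  P <- t(sv$v[, seq_len(n_components), drop = FALSE])   # k x p
  for (j in seq_len(nrow(P))) {
    if (P[j, which.max(abs(P[j, ]))] < 0) P[j, ] <- -P[j, ]
  }
  structure(list(mean = mu, loadings = P, eigenvalues = lambda,
                 explained_variance = (lambda / sum(lambda))[seq_len(n_components)],
                 wavenumbers = dataset$wavenumbers),
            class = "pca_model")
}

#' Project spectra onto a fitted PCA model
#'
#' Subtracts the model mean (never the new data's mean), then applies the
#' loadings.
#'
#' @param model A `pca_model`.
#' @param dataset A [spectral_dataset()] on the model grid.
#' @return Score matrix (n x k) with columns `PC1, PC2, ...` and rownames
#'   set to spectrum ids.
#' @export
project_pca <- function(model, dataset) {
  X <- dataset$intensities
  if (ncol(X) != length(model$mean)) stop("grid mismatch with PCA model")
  scores <- sweep(X, 2, model$mean) %*% t(model$loadings)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  rownames(scores) <- dataset$meta$spectrum_id
  scores
}

#' Group confidence ellipse in a 2-D score plane
#'
#' Center = group mean; axes and orientation from the eigen-decomposition of
#' the 2x2 sample covariance, scaled by the chi-square(2) quantile at
#' `level`.
#'
#' @param scores Two-column matrix of scores for one group (>= 3 rows).
#' @param level Confidence level in (0, 1).
#' @return An `ellipse` list: `center`, `semi_axes` (descending), `angle`
#'   (radians, orientation of the major axis), `level`.
#' @export
confidence_ellipse <- function(scores, level = 0.95) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 2L, level > 0, level < 1)
  if (nrow(scores) < 3L) stop("confidence ellipse needs at least 3 points")
  S <- stats::cov(scores)
  if (!all(is.finite(S)) || det(S) <= 0) {
    stop("singular score covariance; ellipse undefined")
  }
  e <- eigen(S, symmetric = TRUE)
  q <- stats::qchisq(level, df = 2)
  structure(list(center = colMeans(scores),
                 semi_axes = sqrt(e$values * q),
                 angle = atan2(e$vectors[2L, 1L], e$vectors[1L, 1L]),
                 level = level),
            class = "ellipse")
}

#' Mardia's multivariate normality test
#'
#' Multivariate skewness `b1 = mean over all observation pairs of g_ij^3`
#' and kurtosis `b2 = mean of g_ii^2`, with `g` the centered Mahalanobis
#' inner-product matrix (MLE covariance). The skewness statistic
#' `n b1 / 6` is referred to chi-square with `d(d+1)(d+2)/6` df; the
#' kurtosis z-statistic compares `b2` with `d(d+2)` at variance
#' `8 d (d+2) / n`.
#'
#' @param x Numeric matrix, observations x variables, `n > d`.
#' @param pca_fallback If the covariance is singular (e.g. spectra with
#'   `p >= n`), run the test on this many leading PCA scores instead
#'   (`NULL` disables the fallback and singularity becomes an error).
#' @return A `mardia_test` list: `b1`, `b2`, `skew_stat`, `skew_df`,
#'   `skew_p`, `kurt_z`, `kurt_p`, `d`, `n`, `used_pca` flag.
#' @export
mardia_test <- function(x, pca_fallback = 10L) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  S <- crossprod(sweep(x, 2, colMeans(x))) / n
  ok <- n > d && is.finite(rcond_sym(S)) && rcond_sym(S) > 1e-12
  used_pca <- FALSE
  if (!ok) {
    if (is.null(pca_fallback)) {
      stop("singular covariance; enable the PCA-score fallback or reduce d")
    }
    k <- min(pca_fallback, n - 2L)
    sv <- svd(sweep(x, 2, colMeans(x)))
    x <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
    d <- k
    S <- crossprod(sweep(x, 2, colMeans(x))) / n
    used_pca <- TRUE
  }
  xc <- sweep(x, 2, colMeans(x))
  G <- xc %*% solve(S, t(xc))
  b1 <- mean(G^3)
  b2 <- mean(diag(G)^2)
  skew_stat <- n * b1 / 6
  skew_df <- d * (d + 1) * (d + 2) / 6
  kurt_z <- (b2 - d * (d + 2)) / sqrt(8 * d * (d + 2) / n)
  structure(list(b1 = b1, b2 = b2,
                 skew_stat = skew_stat, skew_df = skew_df,
                 skew_p = stats::pchisq(skew_stat, skew_df, lower.tail = FALSE),
                 kurt_z = kurt_z,
                 kurt_p = 2 * stats::pnorm(-abs(kurt_z)),
                 d = d, n = n, used_pca = used_pca),
            class = "mardia_test")
}

rcond_sym <- function(S) {
  ev <- tryCatch(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NA_real_)
  if (anyNA(ev) || min(ev) <= 0) return(0)
  min(ev) / max(ev)
}
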