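#' Quality-test thresholds
#'
#' Defaults are calibrated to the synthetic generator's default artifact
#' levels: serum films with fingerprint-region maxima around 0.5 AU, a
#' signal-to-noise ratio of order 200, and residual water-vapor lines well
#' below the amide bands. The water-vapor criterion is a gross-contamination
#' guard: at the default noise level the smoothed second derivative only
#' rises clearly above its noise floor for strong residual water vapor.
#'
#' @param absorbance_min,absorbance_max Acceptable range (AU) for the
#'   maximum absorbance in the 1800-900 cm^-1 fingerprint window.
#' @param snr_min Minimum signal-to-noise ratio (amide-I signal in
#'   1700-1600 over detrended noise in 2200-1900).
#' @param water_vapor_max Maximum peak-to-peak of the Savitzky-Golay second
#'   derivative within the 1847-1837 cm^-1 water-vapor window (AU/(cm^-1)^2).
#' @return A `quality_thresholds` list.
#' @export
quality_thresholds <- function(absorbance_min = 0.05, absorbance_max = 1.5,
                               snr_min = 50, water_vapor_max = 3e-4) {
  stopifnot(absorbance_min < absorbance_max, snr_min > 0, water_vapor_max > 0)
  structure(list(absorbance_min = absorbance_min,
                 absorbance_max = absorbance_max,
                 snr_min = snr_min, water_vapor_max = water_vapor_max),
            class = "quality_thresholds")
}

QC_WINDOWS <- list(absorbance = c(900, 1800), signal = c(1600, 1700),
                   noise = c(1900, 2200), water = c(1837, 1847))

#' Per-spectrum quality test
#'
#' Re-specification of the classical three-criterion spectral quality check:
#' (i) maximum fingerprint-window absorbance within bounds, (ii)
#' signal-to-noise ratio = (amide-I maximum above a straight line through the
#' 1700-1600 window edges) / (sd of the linearly detrended 2200-1900
#' residual), (iii) water-vapor score = peak-to-peak of the Savitzky-Golay
#' second derivative inside 1847-1837 cm^-1.
#'
#' @param dataset A [spectral_dataset()] whose grid covers the 2200-1900 and
#'   1700-1600 cm^-1 windows.
#' @param thresholds A [quality_thresholds()].
#' @return Data frame: `spectrum_id`, `max_absorbance`, `snr`, `water_score`,
#'   `absorbance_ok`, `snr_ok`, `water_ok`.
#' @export
quality_test <- function(dataset, thresholds = quality_thresholds()) {
  w <- dataset$wavenumbers
  for (win in c("signal", "noise")) {
    r <- QC_WINDOWS[[win]]
    if (min(w) > r[1L] || max(w) < r[2L]) {
      stop("grid does not cover the required ", win, " window (",
           r[1L], "-", r[2L], " cm^-1)")
    }
  }
  X <- dataset$intensities
  iabs <- window_index(w, QC_WINDOWS$absorbance[1L], QC_WINDOWS$absorbance[2L])
  isig <- window_index(w, QC_WINDOWS$signal[1L], QC_WINDOWS$signal[2L])
  inoi <- window_index(w, QC_WINDOWS$noise[1L], QC_WINDOWS$noise[2L])

  max_abs <- apply(X[, iabs, drop = FALSE], 1, max)

  # signal: peak height above the chord through the window edges
  ws <- w[isig]
  Xs <- X[, isig, drop = FALSE]
  t_sig <- (ws - ws[1L]) / (ws[length(ws)] - ws[1L])
  chord <- outer(Xs[, 1L], 1 - t_sig) + outer(Xs[, ncol(Xs)], t_sig)
  signal <- apply(Xs - chord, 1, max)

  # noise: sd of the least-squares linearly detrended residual
  wn <- w[inoi]
  Xn <- X[, inoi, drop = FALSE]
  B <- cbind(1, wn)
  H <- B %*% solve(crossprod(B), t(B))
  resid <- Xn - Xn %*% t(H)
  noise <- apply(resid, 1, stats::sd)
  snr <- signal / noise

  # water-vapor score from the second derivative around the water window
  ider <- window_index(w, QC_WINDOWS$water[1L] - 15, QC_WINDOWS$water[2L] + 15)
  sub <- spectral_dataset(w[ider], X[, ider, drop = FALSE], dataset$meta)
  der <- sg_second_derivative(sub, 15L, 3L)
  iwat <- window_index(der$wavenumbers, QC_WINDOWS$water[1L], QC_WINDOWS$water[2L])
  D <- der$intensities[, iwat, drop = FALSE]
  water <- apply(D, 1, function(v) diff(range(v)))

  data.frame(spectrum_id = dataset$meta$spectrum_id,
             max_absorbance = max_abs, snr = snr, water_score = water,
             absorbance_ok = max_abs >= thresholds$absorbance_min &
                             max_abs <= thresholds$absorbance_max,
             snr_ok = snr >= thresholds$snr_min,
             water_ok = water <= thresholds$water_vapor_max)
}

#' Fit the Hotelling T2 / Q-residual outlier model
#'
#' PCA of the mean-centered intensities; the component count `k` is the
#' smallest with cumulative explained variance >= `variance_fraction`.
#' Per spectrum, `T2 = sum(t_j^2 / lambda_j)` over the `k` retained scores
#' and `Q` is the squared reconstruction residual. The T2 control limit is
#' `k (n-1) / (n-k) * F_(1-alpha)(k, n-k)`; the Q limit uses the
#' Jackson-Mudholkar approximation on the residual eigenvalues.
#'
#' @param dataset A [spectral_dataset()] with more spectra than retained
#'   components.
#' @param variance_fraction Cumulative explained-variance cut in (0, 1).
#' @param alpha Control-chart significance level in (0, 1).
#' @return An `outlier_model`: `mean`, `loadings` (k x p), `eigenvalues`
#'   (all), `k`, `T2_threshold`, `Q_threshold`, `alpha`,
#'   `variance_fraction`, and per-training-spectrum `T2`/`Q`.
#' @export
fit_outlier_model <- function(dataset, variance_fraction = 0.95, alpha = 0.05) {
  stopifnot(variance_fraction > 0, variance_fraction < 1,
            alpha > 0, alpha < 1)
  X <- dataset$intensities
  n <- nrow(X)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  lambda <- sv$d^2 / (n - 1)
  frac <- cumsum(lambda) / sum(lambda)
  k <- which(frac >= variance_fraction)[1L]
  if (is.na(k)) k <- length(lambda)
  if (k >= n) {
    stop("retained components (", k, ") reach the sample count; ",
         "lower variance_fraction")
  }
  resid_l <- lambda[-seq_len(k)]
  resid_l <- resid_l[resid_l > 1e-12 * lambda[1L]]
  if (length(resid_l) == 0L) {
    stop("all residual eigenvalues are ~0; Q threshold undefined -- ",
         "lower variance_fraction")
  }
  P <- sv$v[, seq_len(k), drop = FALSE]          # p x k loadings
  scores <- Xc %*% P
  T2 <- rowSums(sweep(scores^2, 2, lambda[seq_len(k)], `/`))
  Q <- rowSums((Xc - scores %*% t(P))^2)
  T2_threshold <- k * (n - 1) / (n - k) * stats::qf(1 - alpha, k, n - k)
  Q_threshold <- jackson_mudholkar_limit(resid_l, alpha)
  structure(list(mean = mu, loadings = t(P), eigenvalues = lambda, k = k,
                 T2 = T2, Q = Q,
                 T2_threshold = T2_threshold, Q_threshold = Q_threshold,
                 alpha = alpha, variance_fraction = variance_fraction),
            class = "outlier_model")
}

jackson_mudholkar_limit <- function(resid_eigenvalues, alpha) {
  th1 <- sum(resid_eigenvalues)
  th2 <- sum(resid_eigenvalues^2)
  th3 <- sum(resid_eigenvalues^3)
  h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
  q <- NA_real_
  if (is.finite(h0) && h0 > 0) {
    z <- stats::qnorm(1 - alpha)
    q <- th1 * (z * sqrt(2 * th2 * h0^2) / th1 + 1 +
                  th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
  }
  if (!is.finite(q) || q <= 0) {
    # the normal-power approximation degenerates when h0 <= 0 (heavy-tailed
    # residual eigenvalue spectra); fall back to the matched-moment
    # g * chi-square(h) limit
    q <- (th2 / th1) * stats::qchisq(1 - alpha, th1^2 / th2)
  }
  q
}

#' T2 and Q statistics of spectra under a fitted outlier model
#'
#' @param model An `outlier_model` from [fit_outlier_model()].
#' @param dataset A [spectral_dataset()] on the training grid.
#' @return Data frame: `spectrum_id`, `T2`, `Q`, `T2_ok`, `Q_ok`.
#' @export
score_outlier_model <- function(model, dataset) {
  X <- dataset$intensities
  if (ncol(X) != length(model$mean)) stop("grid mismatch with outlier model")
  Xc <- sweep(X, 2, model$mean)
  P <- t(model$loadings)
  scores <- Xc %*% P
  T2 <- rowSums(sweep(scores^2, 2, model$eigenvalues[seq_len(model$k)], `/`))
  Q <- rowSums((Xc - scores %*% t(P))^2)
  data.frame(spectrum_id = dataset$meta$spectrum_id, T2 = T2, Q = Q,
             T2_ok = T2 <= model$T2_threshold, Q_ok = Q <= model$Q_threshold)
}

#' Full two-stage QC report
#'
#' Combines the three-criterion quality test with the Hotelling T2 /
#' Q-residual chart. A spectrum passes iff all three quality booleans hold
#' and both `T2 <= T2_threshold` and `Q <= Q_threshold`.
#'
#' @inheritParams quality_test
#' @inheritParams fit_outlier_model
#' @return List: `report` (one row per spectrum with all statistics, flags
#'   and `pass`), `model` (the fitted `outlier_model`),
#'   `thresholds`.
#' @export
qc_report <- function(dataset, thresholds = quality_thresholds(),
                      variance_fraction = 0.95, alpha = 0.05) {
  qt <- quality_test(dataset, thresholds)
  model <- fit_outlier_model(dataset, variance_fraction, alpha)
  tq <- score_outlier_model(model, dataset)
  report <- cbind(qt, tq[, c("T2", "Q", "T2_ok", "Q_ok")])
  report$T2_threshold <- model$T2_threshold
  report$Q_threshold <- model$Q_threshold
  report$pass <- with(report, absorbance_ok & snr_ok & water_ok & T2_ok & Q_ok)
  list(report = report, model = model, thresholds = thresholds)
}

#' Exclude QC failures from a dataset
#'
#' @param dataset A [spectral_dataset()].
#' @param report The `report` data frame of [qc_report()] (or any frame
#'   with `spectrum_id` and `pass`), aligned to the dataset rows.
#' @return List: `dataset` (passing rows, order preserved), `excluded`
#'   (character vector of excluded spectrum ids).
#' @export
apply_outlier_filter <- function(dataset, report) {
  if (!identical(report$spectrum_id, dataset$meta$spectrum_id)) {
    stop("QC report is not aligned to the dataset rows")
  }
  keep <- report$pass
  if (!any(keep)) stop("no spectra survive QC; check thresholds")
  list(dataset = dataset[which(keep)],
       excluded = dataset$meta$spectrum_id[!keep])
}
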