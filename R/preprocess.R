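#' Truncate a dataset to a closed wavenumber window
#'
#' Retains exactly the grid points `w` with `low <= w <= high`; metadata is
#' untouched.
#'
#' @param dataset A [spectral_dataset()].
#' @param window_low,window_high Window bounds (cm^-1), `window_low <
#'   window_high`.
#' @return Truncated [spectral_dataset()].
#' @export
truncate_window <- function(dataset, window_low = 900, window_high = 1800) {
  idx <- window_index(dataset$wavenumbers, window_low, window_high,
                      "truncation window")
  spectral_dataset(dataset$wavenumbers[idx],
                   dataset$intensities[, idx, drop = FALSE], dataset$meta)
}

#' Savitzky-Golay second derivative
#'
#' Replaces each spectrum by its SG second derivative in AU/(cm^-1)^2,
#' computed with the physical grid step. Edge policy: the `(sg_points-1)/2`
#' points at each end, where no full window exists, are dropped (no padded
#' or fabricated values enter later stages); the grid shrinks accordingly.
#'
#' @param dataset A [spectral_dataset()] on a uniform grid (relative step
#'   tolerance 1e-6).
#' @param sg_points Odd window length (default 15).
#' @param sg_polyorder Fitting polynomial order (default 3); must satisfy
#'   `sg_points >= sg_polyorder + 2` and `sg_polyorder >= 2`.
#' @return Dataset of second-derivative spectra on the shrunken grid.
#' @export
sg_second_derivative <- function(dataset, sg_points = 15L, sg_polyorder = 3L) {
  sg_points <- as.integer(sg_points)
  sg_polyorder <- as.integer(sg_polyorder)
  if (sg_points %% 2L == 0L || sg_points < sg_polyorder + 2L) {
    stop("sg_points must be odd and >= sg_polyorder + 2")
  }
  if (sg_polyorder < 2L) stop("second derivative needs sg_polyorder >= 2")
  w <- dataset$wavenumbers
  if (length(w) < sg_points) stop("fewer grid points than sg_points")
  steps <- diff(w)
  h <- mean(steps)
  if (max(abs(steps - h)) > 1e-6 * h) {
    stop("grid is not uniform; interpolate to a uniform grid first")
  }
  # central row of the SG projection matrix = convolution coefficients for
  # the 2nd derivative at physical spacing h
  fm <- unclass(signal::sgolay(p = sg_polyorder, n = sg_points, m = 2, ts = h))
  cc <- fm[(sg_points + 1L) %/% 2L, ]
  half <- (sg_points - 1L) %/% 2L
  n <- length(w)
  keep <- (half + 1L):(n - half)
  X <- dataset$intensities
  out <- matrix(0, nrow(X), length(keep))
  for (j in seq_along(keep)) {
    cols <- (keep[j] - half):(keep[j] + half)
    out[, j] <- X[, cols, drop = FALSE] %*% cc
  }
  spectral_dataset(w[keep], out, dataset$meta)
}

#' Multiplicative scatter correction
#'
#' Per spectrum, ordinary least squares of `x = a + b * ref`; the corrected
#' spectrum is `(x - a) / b`. Coefficients are returned so the same
#' reference can be reused on held-out data.
#'
#' @param dataset A [spectral_dataset()].
#' @param reference Reference spectrum on the dataset grid; defaults to the
#'   dataset mean.
#' @return List: `dataset` (corrected), `coefficients` (data frame with
#'   `spectrum_id`, `offset`, `slope`), `reference`.
#' @export
msc <- function(dataset, reference = NULL) {
  X <- dataset$intensities
  if (is.null(reference)) reference <- colMeans(X)
  if (length(reference) != ncol(X)) {
    stop("MSC reference is not on the dataset grid")
  }
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  if (denom <= 0) stop("MSC reference has zero variance")
  xm <- rowMeans(X)
  b <- drop(X %*% rc) / denom           # OLS slope per spectrum
  a <- xm - b * mean(reference)
  bad <- which(abs(b) < 1e-12)
  if (length(bad)) {
    stop("degenerate scatter fit (|slope| < 1e-12) for spectrum ",
         dataset$meta$spectrum_id[bad[1L]])
  }
  corrected <- (X - a) / b
  list(dataset = spectral_dataset(dataset$wavenumbers, corrected, dataset$meta),
       coefficients = data.frame(spectrum_id = dataset$meta$spectrum_id,
                                 offset = a, slope = b),
       reference = reference)
}

#' Unit-vector normalization
#'
#' Scales every spectrum to Euclidean norm 1.
#'
#' @param dataset A [spectral_dataset()].
#' @return Normalized [spectral_dataset()].
#' @export
vector_normalize <- function(dataset) {
  X <- dataset$intensities
  nrm <- sqrt(rowSums(X^2))
  bad <- which(nrm == 0)
  if (length(bad)) {
    stop("zero-norm spectrum cannot be normalized: ",
         dataset$meta$spectrum_id[bad[1L]])
  }
  spectral_dataset(dataset$wavenumbers, X / nrm, dataset$meta)
}

#' Fit / apply per-wavenumber scaling
#'
#' `fit_scaler` records per-wavenumber means (and, for
#' `scale_mode = "standardize"`, standard deviations) on one dataset;
#' `apply_scaler` applies those recorded statistics to any dataset on the
#' same grid -- held-out data is scaled with the training statistics, never
#' refit.
#'
#' @param dataset A [spectral_dataset()].
#' @param scale_mode `"mean-center"`, `"standardize"` or `"none"`.
#' @return `fit_scaler`: a `scaler_state`; `apply_scaler`: a scaled dataset.
#' @export
fit_scaler <- function(dataset, scale_mode = c("mean-center", "standardize", "none")) {
  scale_mode <- match.arg(scale_mode)
  X <- dataset$intensities
  mu <- colMeans(X)
  sd <- rep(1, ncol(X))
  if (scale_mode == "standardize") {
    sd <- apply(X, 2, stats::sd)
    bad <- which(sd == 0)
    if (length(bad)) {
      stop("zero-variance wavenumber in standardize mode: ",
           format(dataset$wavenumbers[bad[1L]]), " cm^-1")
    }
  }
  structure(list(mean = mu, sd = sd, mode = scale_mode,
                 wavenumbers = dataset$wavenumbers), class = "scaler_state")
}

#' @rdname fit_scaler
#' @param state A `scaler_state` from `fit_scaler`.
#' @export
apply_scaler <- function(state, dataset) {
  stopifnot(inherits(state, "scaler_state"))
  if (state$mode == "none") return(dataset)
  if (length(state$mean) != n_points(dataset) ||
      max(abs(state$wavenumbers - dataset$wavenumbers)) > 1e-8) {
    stop("scaler was fitted on a different grid")
  }
  X <- sweep(dataset$intensities, 2, state$mean)
  if (state$mode == "standardize") X <- sweep(X, 2, state$sd, `/`)
  spectral_dataset(dataset$wavenumbers, X, dataset$meta)
}

#' Preprocessing parameters
#'
#' @param window_low,window_high Truncation window (cm^-1).
#' @param sg_points,sg_polyorder Savitzky-Golay settings (derivative order
#'   fixed at 2).
#' @param scale_mode Final scaling step; `"none"` defers scaling to the
#'   consumer stage (as done inside cross-validated classification).
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(window_low = 900, window_high = 1800,
                              sg_points = 15L, sg_polyorder = 3L,
                              scale_mode = c("none", "mean-center", "standardize")) {
  scale_mode <- match.arg(scale_mode)
  stopifnot(window_low < window_high)
  structure(list(window_low = window_low, window_high = window_high,
                 sg_points = as.integer(sg_points),
                 sg_polyorder = as.integer(sg_polyorder),
                 sg_deriv = 2L, scale_mode = scale_mode),
            class = "preprocess_params")
}

#' Five-step preprocessing chain
#'
#' Fixed order: (i) truncation to the fingerprint window, (ii)
#' Savitzky-Golay second derivative, (iii) multiplicative scatter
#' correction, (iv) unit-vector normalization, (v) scaling (skipped when
#' `scale_mode = "none"`, e.g. when a train-fitted scaler is applied by the
#' classification stage). The ordered step log is attached as attribute
#' `"steps"`.
#'
#' @param dataset A [spectral_dataset()].
#' @param params A [preprocess_params()].
#' @param msc_reference Optional explicit MSC reference on the
#'   post-derivative grid (e.g. a training-set mean); default is the mean of
#'   the data being processed.
#' @return Preprocessed [spectral_dataset()] with attribute `"steps"` and,
#'   when MSC ran, `"msc_reference"`.
#' @export
preprocess_pipeline <- function(dataset, params = preprocess_params(),
                                msc_reference = NULL) {
  steps <- character(0)
  out <- truncate_window(dataset, params$window_low, params$window_high)
  steps <- c(steps, sprintf("truncate[%g,%g]", params$window_low, params$window_high))
  out <- sg_second_derivative(out, params$sg_points, params$sg_polyorder)
  steps <- c(steps, sprintf("sg_second_derivative[n=%d,p=%d]",
                            params$sg_points, params$sg_polyorder))
  m <- msc(out, msc_reference)
  out <- m$dataset
  steps <- c(steps, if (is.null(msc_reference)) "msc[dataset-mean]" else "msc[explicit]")
  out <- vector_normalize(out)
  steps <- c(steps, "vector_normalize")
  if (params$scale_mode != "none") {
    out <- apply_scaler(fit_scaler(out, params$scale_mode), out)
    steps <- c(steps, sprintf("scale[%s]", params$scale_mode))
  }
  attr(out, "steps") <- steps
  attr(out, "msc_reference") <- m$reference
  out
}
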