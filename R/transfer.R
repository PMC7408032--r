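#' Fit a piecewise direct standardization (PDS) model
#'
#' For every target wavenumber `j`, regresses the master value at `j` on the
#' slave window `[j-h, j+h]` (plus intercept) across the paired transfer
#' samples, solving each local least-squares problem by truncated SVD
#' (singular values below `rank_tol` times the largest are discarded). The
#' local maps assemble into a banded linear operator plus intercept vector.
#'
#' @param master,slave [spectral_dataset()]s holding the same transfer
#'   samples in the same row order on one common grid; at least 3 pairs.
#' @param half_width Window half-width in grid points (default 7).
#' @param rank_tol Relative singular-value cutoff (default 1e-6).
#' @return A `pds_model`: `wavenumbers`, `half_width`, `rank_tol`,
#'   `coefficients` (p x (2h+1) band matrix, edge-clipped windows
#'   zero-padded), `intercepts`, and `fit_rms` = c(before, after) on the
#'   training pairs.
#' @export
fit_pds <- function(master, slave, half_width = 7L, rank_tol = 1e-6) {
  check_same_grid(master, slave, "master and slave")
  if (n_spectra(master) != n_spectra(slave)) {
    stop("pairing error: master has ", n_spectra(master),
         " spectra, slave has ", n_spectra(slave))
  }
  n <- n_spectra(master)
  if (n < 3L) stop("PDS needs at least 3 transfer pairs")
  half_width <- as.integer(half_width)
  p <- n_points(master)
  M <- master$intensities
  S <- slave$intensities
  B <- matrix(0, p, 2L * half_width + 1L)
  a0 <- numeric(p)
  degenerate <- integer(0)
  for (j in seq_len(p)) {
    lo <- max(1L, j - half_width)
    hi <- min(p, j + half_width)
    W <- S[, lo:hi, drop = FALSE]
    y <- M[, j]
    Wc <- sweep(W, 2, colMeans(W))
    yc <- y - mean(y)
    if (max(abs(Wc)) < 1e-14) {          # all-constant window
      a0[j] <- mean(y)
      degenerate <- c(degenerate, j)
      next
    }
    sv <- svd(Wc)
    keep <- sv$d >= rank_tol * sv$d[1L]
    beta <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% yc) / sv$d[keep])
    B[j, (lo - j + half_width + 1L):(hi - j + half_width + 1L)] <- beta
    a0[j] <- mean(y) - sum(colMeans(W) * beta)
  }
  if (length(degenerate)) {
    warning(length(degenerate),
            " degenerate (constant) PDS window(s), e.g. at ",
            format(master$wavenumbers[degenerate[1L]]),
            " cm^-1; intercept-only maps used there")
  }
  model <- structure(list(wavenumbers = master$wavenumbers,
                          half_width = half_width, rank_tol = rank_tol,
                          coefficients = B, intercepts = a0),
                     class = "pds_model")
  before <- sqrt(mean((S - M)^2))
  after <- sqrt(mean((apply_pds(model, slave)$intensities - M)^2))
  model$fit_rms <- c(before = before, after = after)
  model
}

#' Map spectra through a PDS model
#'
#' @param model A `pds_model` from [fit_pds()].
#' @param dataset A [spectral_dataset()] on the model grid.
#' @return Standardized [spectral_dataset()]; batch ids are annotated with a
#'   `">std"` suffix.
#' @export
apply_pds <- function(model, dataset) {
  if (n_points(dataset) != length(model$wavenumbers) ||
      max(abs(dataset$wavenumbers - model$wavenumbers)) > 1e-8) {
    stop("grid mismatch: dataset is not on the PDS model grid")
  }
  X <- dataset$intensities
  p <- ncol(X)
  h <- model$half_width
  out <- matrix(0, nrow(X), p)
  for (j in seq_len(p)) {
    lo <- max(1L, j - h)
    hi <- min(p, j + h)
    beta <- model$coefficients[j, (lo - j + h + 1L):(hi - j + h + 1L)]
    out[, j] <- X[, lo:hi, drop = FALSE] %*% beta + model$intercepts[j]
  }
  meta <- dataset$meta
  meta$batch <- ifelse(grepl(">std$", meta$batch), meta$batch,
                       paste0(meta$batch, ">std"))
  spectral_dataset(dataset$wavenumbers, out, meta)
}
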