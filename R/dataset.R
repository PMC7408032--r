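#' Construct a spectral dataset
#'
#' The container every stage of the workflow consumes and produces: a shared
#' strictly ascending wavenumber grid, an intensity matrix with one spectrum
#' per row, and a metadata table aligned to rows.
#'
#' @param wavenumbers Numeric vector of wavenumbers (cm^-1), strictly
#'   monotone. Descending input is reversed (together with the intensity
#'   columns) so that storage is always ascending.
#' @param intensities Numeric matrix, `n_spectra x length(wavenumbers)`,
#'   absorbance units (AU). A single spectrum may be given as a vector.
#' @param meta Data frame with one row per spectrum and columns
#'   `spectrum_id`, `subject_id`, `group`, `batch`, `replicate`. Missing
#'   columns are filled with defaults; `spectrum_id` defaults to
#'   `spec_0001, ...`.
#'
#' @return An object of class `spectral_dataset` with elements
#'   `wavenumbers`, `intensities` (rownames = spectrum ids) and `meta`.
#' @export
spectral_dataset <- function(wavenumbers, intensities, meta = NULL) {
  wavenumbers <- as.numeric(wavenumbers)
  if (is.vector(intensities)) intensities <- matrix(intensities, nrow = 1L)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (length(wavenumbers) != ncol(intensities)) {
    stop("length(wavenumbers) [", length(wavenumbers),
         "] must equal ncol(intensities) [", ncol(intensities), "]")
  }
  if (length(wavenumbers) < 2L) stop("a spectrum needs at least 2 grid points")
  if (all(diff(wavenumbers) < 0)) {   # normalize descending input once
    wavenumbers <- rev(wavenumbers)
    intensities <- intensities[, ncol(intensities):1, drop = FALSE]
  }
  if (any(diff(wavenumbers) <= 0)) {
    stop("wavenumbers must be strictly monotone")
  }
  if (!all(is.finite(intensities))) stop("intensities must be finite")

  n <- nrow(intensities)
  meta <- normalize_meta(meta, n)
  # subject -> group mapping must be single-valued
  map <- unique(meta[, c("subject_id", "group")])
  if (anyDuplicated(map$subject_id)) {
    bad <- map$subject_id[duplicated(map$subject_id)][1L]
    stop("subject '", bad, "' is assigned to more than one group")
  }
  rownames(intensities) <- meta$spectrum_id
  structure(list(wavenumbers = wavenumbers, intensities = intensities,
                 meta = meta),
            class = "spectral_dataset")
}

normalize_meta <- function(meta, n) {
  if (is.null(meta)) meta <- data.frame(row.names = seq_len(n))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) == 0L && n > 0L) meta <- data.frame(.dummy = seq_len(n))[, 0, drop = FALSE]
  if (nrow(meta) != n) {
    if (nrow(meta) == 0L) {
      meta <- data.frame(spectrum_id = sprintf("spec_%04d", seq_len(n)))
    } else {
      stop("metadata has ", nrow(meta), " rows but there are ", n, " spectra")
    }
  }
  if (is.null(meta$spectrum_id)) meta$spectrum_id <- sprintf("spec_%04d", seq_len(n))
  if (anyDuplicated(meta$spectrum_id)) stop("duplicate spectrum_id in metadata")
  if (is.null(meta$subject_id)) meta$subject_id <- meta$spectrum_id
  if (is.null(meta$group))      meta$group <- "unknown"
  if (is.null(meta$batch))      meta$batch <- "batch1"
  if (is.null(meta$replicate))  meta$replicate <- 1L
  meta$spectrum_id <- as.character(meta$spectrum_id)
  meta$subject_id  <- as.character(meta$subject_id)
  meta$group       <- as.character(meta$group)
  meta$batch       <- as.character(meta$batch)
  meta$replicate   <- as.integer(meta$replicate)
  rownames(meta) <- NULL
  meta
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat("<spectral_dataset> ", n_spectra(x), " spectra x ", n_points(x),
      " points, ", sprintf("%.1f-%.1f", min(x$wavenumbers), max(x$wavenumbers)),
      " cm^-1\n", sep = "")
  cat("  groups: ", paste(sprintf("%s (%d)", names(table(x$meta$group)),
                                  table(x$meta$group)), collapse = ", "), "\n", sep = "")
  cat("  batches: ", paste(unique(x$meta$batch), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of spectra / grid points in a dataset
#' @param x A `spectral_dataset`.
#' @return Integer count.
#' @export
n_spectra <- function(x) nrow(x$intensities)

#' @rdname n_spectra
#' @export
n_points <- function(x) ncol(x$intensities)

#' Subset spectra (rows) of a dataset
#'
#' @param x A `spectral_dataset`.
#' @param i Row index vector (integer, logical, or spectrum ids).
#' @param ... Unused.
#' @return A `spectral_dataset` with the selected spectra, order preserved.
#' @export
`[.spectral_dataset` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$meta$spectrum_id)
  if (anyNA(i)) stop("unknown spectrum id in subset")
  spectral_dataset(x$wavenumbers, x$intensities[i, , drop = FALSE],
                   x$meta[i, , drop = FALSE])
}

#' Check two datasets share one grid
#' @keywords internal
#' @noRd
check_same_grid <- function(a, b, what = "datasets") {
  if (length(a$wavenumbers) != length(b$wavenumbers) ||
      max(abs(a$wavenumbers - b$wavenumbers)) > 1e-8) {
    stop("grid mismatch: ", what, " must share one wavenumber grid")
  }
  invisible(TRUE)
}

#' Indices of grid points inside a closed wavenumber window
#' @keywords internal
#' @noRd
window_index <- function(wavenumbers, low, high, what = "window") {
  if (low >= high) stop(what, ": low bound (", low,
                        ") must be below high bound (", high, ")")
  idx <- which(wavenumbers >= low & wavenumbers <= high)
  if (length(idx) == 0L) {
    stop(what, " [", low, ", ", high, "] cm^-1 does not intersect the grid (",
         min(wavenumbers), "-", max(wavenumbers), ")")
  }
  idx
}
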