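#' Write a spectral dataset to disk
#'
#' `wide-csv` emits `<path>.csv` (first column `wavenumber`, one column per
#' spectrum, >= 9 significant digits) plus a companion metadata TSV
#' `<path>_meta.tsv` keyed by column name. `jcamp-dx` emits a single
#' compound `<path>.jdx` file with one `##TITLE=` block per spectrum
#' (XYDATA `(X++(Y..Y))`, AFFN) carrying the metadata as `##$`-labels.
#'
#' @param dataset A [spectral_dataset()] with at least one spectrum.
#' @param path Output path prefix (extensions are appended).
#' @param format `"wide-csv"` or `"jcamp-dx"`.
#' @return Invisibly, the character vector of files written.
#' @export
write_dataset <- function(dataset, path, format = c("wide-csv", "jcamp-dx")) {
  format <- match.arg(format)
  if (n_spectra(dataset) == 0L) stop("refusing to write an empty dataset")
  if (format == "wide-csv") {
    csv <- paste0(path, ".csv")
    tsv <- paste0(path, "_meta.tsv")
    m <- cbind(wavenumber = dataset$wavenumbers, t(dataset$intensities))
    df <- as.data.frame(signif(m, 12))
    names(df) <- c("wavenumber", dataset$meta$spectrum_id)
    utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                     csv, row.names = FALSE, quote = FALSE)
    utils::write.table(dataset$meta, tsv, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(c(csv, tsv))
  } else {
    jdx <- paste0(path, ".jdx")
    write_jcamp(dataset, jdx)
    invisible(jdx)
  }
}

#' Read a spectral dataset from disk
#'
#' Accepts what [write_dataset()] emits. The grid is normalized to ascending
#' order (descending input is reversed together with the intensities);
#' spectra lacking a metadata row raise an error naming the offenders. For
#' `wide-csv`, `path` may be the prefix used at write time or the `.csv`
#' file itself; the companion `<prefix>_meta.tsv` must exist.
#'
#' @param path Path prefix, `.csv` file, or `.jdx` file.
#' @param format `"wide-csv"` or `"jcamp-dx"`.
#' @return A [spectral_dataset()].
#' @export
read_dataset <- function(path, format = c("wide-csv", "jcamp-dx")) {
  format <- match.arg(format)
  if (format == "wide-csv") {
    csv <- if (grepl("\\.csv$", path)) path else paste0(path, ".csv")
    tsv <- sub("\\.csv$", "_meta.tsv", csv)
    if (!file.exists(csv)) stop("file not found: ", csv)
    if (!file.exists(tsv)) stop("metadata file not found: ", tsv)
    df <- utils::read.csv(csv, check.names = FALSE)
    if (ncol(df) < 2L) stop("wide CSV needs a wavenumber column plus spectra")
    for (j in seq_along(df)) {
      if (!is.numeric(df[[j]])) {
        bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1L]
        stop("non-numeric cell in column '", names(df)[j], "', data row ",
             bad, " of ", csv)
      }
    }
    meta <- utils::read.table(tsv, sep = "\t", header = TRUE,
                              colClasses = "character")
    ids <- names(df)[-1L]
    missing <- setdiff(ids, meta$spectrum_id)
    if (length(missing)) {
      stop("spectra with no metadata row: ", paste(missing, collapse = ", "))
    }
    meta <- meta[match(ids, meta$spectrum_id), , drop = FALSE]
    meta$replicate <- as.integer(meta$replicate)
    spectral_dataset(df[[1L]], t(as.matrix(df[, -1L, drop = FALSE])), meta)
  } else {
    read_jcamp(path)
  }
}
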