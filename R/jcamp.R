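# JCAMP-DX reader/writer. Supported dialects: XYDATA=(X++(Y..Y)) with AFFN
# or ASDF SQZ/DIF/DUP (DIFDUP) ordinates, and XYPOINTS=(XY..XY) with AFFN
# pairs. Other compression schemes are rejected with a clear error.

SQZ_CHARS <- c(`@` = 0, A = 1, B = 2, C = 3, D = 4, E = 5, F = 6, G = 7,
               H = 8, I = 9, a = -1, b = -2, c = -3, d = -4, e = -5,
               f = -6, g = -7, h = -8, i = -9)
DIF_CHARS <- c(`%` = 0, J = 1, K = 2, L = 3, M = 4, N = 5, O = 6, P = 7,
               Q = 8, R = 9, j = -1, k = -2, l = -3, m = -4, n = -5,
               o = -6, p = -7, q = -8, r = -9)
DUP_CHARS <- c(S = 1, T = 2, U = 3, V = 4, W = 5, X = 6, Y = 7, Z = 8, s = 9)

# Split one ASDF/AFFN data line into tokens of (prefix char, trailing digits)
tokenize_asdf <- function(line) {
  chars <- strsplit(line, "")[[1]]
  tokens <- character(0)
  cur <- ""
  is_cont <- function(ch) grepl("[0-9.]", ch)
  for (ch in chars) {
    if (ch %in% c(" ", "\t", ",", ";")) {
      if (nzchar(cur)) { tokens <- c(tokens, cur); cur <- "" }
    } else if (is_cont(ch)) {
      cur <- paste0(cur, ch)
    } else if (ch %in% c("+", "-") ||
               ch %in% names(SQZ_CHARS) || ch %in% names(DIF_CHARS) ||
               ch %in% names(DUP_CHARS)) {
      if (nzchar(cur)) tokens <- c(tokens, cur)
      cur <- ch
    } else if (ch == "?") {
      if (nzchar(cur)) { tokens <- c(tokens, cur); cur <- "" }
    } else {
      stop("unsupported character '", ch, "' in JCAMP data line: ", line)
    }
  }
  if (nzchar(cur)) tokens <- c(tokens, cur)
  tokens
}

# Decode the ordinate tokens of one (X++(Y..Y)) line. `last_y` is the final
# ordinate of the previous line; `in_dif` says that line ended in DIF mode,
# in which case this line's first ordinate is a checkpoint to drop.
decode_asdf_line <- function(tokens, last_y, in_dif) {
  ys <- numeric(0)
  mode_dif_last <- FALSE
  prev_item <- NULL   # list(kind = "abs"/"dif", value)
  first_real <- TRUE
  for (tok in tokens) {
    head <- substr(tok, 1, 1)
    rest <- substr(tok, 2, nchar(tok))
    if (head %in% names(DUP_CHARS)) {
      count <- as.numeric(paste0(DUP_CHARS[[head]], rest))
      if (is.null(prev_item)) stop("JCAMP DUP token with no preceding value")
      for (d in seq_len(count - 1)) {
        if (prev_item$kind == "dif") {
          ys <- c(ys, ys[length(ys)] + prev_item$value)
          mode_dif_last <- TRUE
        } else {
          ys <- c(ys, prev_item$value)
          mode_dif_last <- FALSE
        }
      }
      next
    }
    if (head %in% names(DIF_CHARS)) {
      dif <- as.numeric(paste0(DIF_CHARS[[head]], rest))  # "-1"+"23" -> -123
      base <- if (length(ys)) ys[length(ys)] else last_y
      if (is.na(base)) stop("JCAMP DIF token with no preceding ordinate")
      ys <- c(ys, base + dif)
      prev_item <- list(kind = "dif", value = dif)
      mode_dif_last <- TRUE
      first_real <- FALSE
      next
    }
    # absolute: AFFN or SQZ
    if (head %in% names(SQZ_CHARS)) {
      v <- as.numeric(paste0(SQZ_CHARS[[head]], rest))    # "-2"+"34" -> -234
    } else {
      v <- as.numeric(tok)
      if (is.na(v)) stop("cannot parse JCAMP token '", tok, "'")
    }
    if (first_real && in_dif) {
      # checkpoint value: must equal the previous line's last ordinate
      if (!isTRUE(all.equal(v, last_y, tolerance = 1e-6))) {
        stop("JCAMP DIF checkpoint mismatch: expected ", last_y, ", got ", v)
      }
      first_real <- FALSE
      prev_item <- list(kind = "abs", value = v)
      mode_dif_last <- FALSE
      next
    }
    ys <- c(ys, v)
    prev_item <- list(kind = "abs", value = v)
    mode_dif_last <- FALSE
    first_real <- FALSE
  }
  list(ys = ys, in_dif = mode_dif_last)
}

parse_jcamp_block <- function(lines, what) {
  labels <- list()
  data_mode <- NULL
  ys <- numeric(0)
  xy_x <- numeric(0)
  xy_y <- numeric(0)
  last_y <- NA_real_
  in_dif <- FALSE
  for (ln in lines) {
    ln <- sub("\\$\\$.*$", "", ln)      # strip comments
    ln <- trimws(ln, which = "right")
    if (!nzchar(trimws(ln))) next
    if (grepl("^##", ln)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq < 0) next
      key <- toupper(gsub("[ _-]", "", substr(ln, 3, eq - 1)))
      val <- trimws(substr(ln, eq + 1, nchar(ln)))
      labels[[key]] <- val
      if (key == "XYDATA") {
        if (gsub(" ", "", val) != "(X++(Y..Y))") {
          stop("unsupported XYDATA form '", val, "' in ", what,
               "; only (X++(Y..Y)) is supported")
        }
        data_mode <- "xydata"
      } else if (key == "XYPOINTS") {
        data_mode <- "xypoints"
      } else if (key == "END") {
        break
      }
      next
    }
    if (is.null(data_mode)) next
    if (data_mode == "xydata") {
      tokens <- tokenize_asdf(ln)
      if (length(tokens) < 2L) next
      # first token is the line's abscissa (AFFN); ignore beyond bookkeeping
      dec <- decode_asdf_line(tokens[-1L], last_y, in_dif)
      ys <- c(ys, dec$ys)
      last_y <- if (length(ys)) ys[length(ys)] else NA_real_
      in_dif <- dec$in_dif
    } else {
      vals <- as.numeric(tokenize_asdf(ln))
      if (anyNA(vals)) stop("non-AFFN token in XYPOINTS block of ", what)
      if (length(vals) %% 2L != 0L) stop("odd token count in XYPOINTS line: ", ln)
      xy_x <- c(xy_x, vals[seq(1, length(vals), 2)])
      xy_y <- c(xy_y, vals[seq(2, length(vals), 2)])
    }
  }
  xf <- as.numeric(labels$XFACTOR %||% 1)
  yf <- as.numeric(labels$YFACTOR %||% 1)
  if (identical(data_mode, "xydata")) {
    np <- as.integer(labels$NPOINTS %||% length(ys))
    if (length(ys) != np) {
      stop("JCAMP block '", what, "': NPOINTS=", np, " but ", length(ys),
           " ordinates decoded")
    }
    firstx <- as.numeric(labels$FIRSTX)
    lastx <- as.numeric(labels$LASTX)
    if (is.na(firstx) || is.na(lastx)) {
      stop("JCAMP block '", what, "' lacks FIRSTX/LASTX")
    }
    x <- seq(firstx, lastx, length.out = np) * xf
    y <- ys * yf
  } else if (identical(data_mode, "xypoints")) {
    x <- xy_x * xf
    y <- xy_y * yf
  } else {
    stop("JCAMP block '", what, "' has no XYDATA or XYPOINTS table")
  }
  list(x = x, y = y, labels = labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
read_jcamp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^##TITLE=", lines, ignore.case = TRUE)
  if (!length(starts)) stop("no ##TITLE= record in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  specs <- vector("list", length(starts))
  metas <- vector("list", length(starts))
  grid <- NULL
  for (i in seq_along(starts)) {
    block <- lines[starts[i]:ends[i]]
    title <- trimws(sub("^##TITLE=", "", block[1L], ignore.case = TRUE))
    p <- parse_jcamp_block(block, title)
    ord <- order(p$x)
    x <- p$x[ord]; y <- p$y[ord]
    if (is.null(grid)) {
      grid <- x
    } else if (length(x) != length(grid) || max(abs(x - grid)) > 1e-6) {
      stop("grid mismatch across JCAMP spectra; first offender: '", title, "'")
    }
    specs[[i]] <- y
    metas[[i]] <- data.frame(
      spectrum_id = title,
      subject_id = p$labels[["$SUBJECTID"]] %||% title,
      group = p$labels[["$GROUP"]] %||% "unknown",
      batch = p$labels[["$BATCH"]] %||% "batch1",
      replicate = as.integer(p$labels[["$REPLICATE"]] %||% 1L))
  }
  spectral_dataset(grid, do.call(rbind, specs), do.call(rbind, metas))
}

#' @keywords internal
#' @noRd
write_jcamp <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- dataset$wavenumbers
  for (i in seq_len(n_spectra(dataset))) {
    m <- dataset$meta[i, ]
    y <- dataset$intensities[i, ]
    writeLines(c(
      paste0("##TITLE=", m$spectrum_id),
      "##JCAMP-DX=4.24",
      "##DATA TYPE=INFRARED SPECTRUM",
      "##XUNITS=1/CM",
      "##YUNITS=ABSORBANCE",
      paste0("##$SUBJECTID=", m$subject_id),
      paste0("##$GROUP=", m$group),
      paste0("##$BATCH=", m$batch),
      paste0("##$REPLICATE=", m$replicate),
      paste0("##FIRSTX=", format(w[1L], digits = 12, scientific = FALSE)),
      paste0("##LASTX=", format(w[length(w)], digits = 12, scientific = FALSE)),
      paste0("##NPOINTS=", length(w)),
      "##XFACTOR=1",
      "##YFACTOR=1",
      paste0("##FIRSTY=", format(y[1L], digits = 12, scientific = FALSE)),
      "##XYDATA=(X++(Y..Y))"), con)
    per_line <- 6L
    idx <- 1L
    while (idx <= length(y)) {
      j <- min(idx + per_line - 1L, length(y))
      writeLines(paste(c(format(w[idx], digits = 12, scientific = FALSE),
                         format(y[idx:j], digits = 10, scientific = FALSE)), collapse = " "), con)
      idx <- j + 1L
    }
    writeLines("##END=", con)
  }
  invisible(path)
}
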