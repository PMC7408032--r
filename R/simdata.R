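#' Define a Gaussian absorbance band
#'
#' @param center Band center (cm^-1).
#' @param width Gaussian sigma (cm^-1), > 0.
#' @param amplitude Peak absorbance (AU), >= 0.
#' @param class_effects Named numeric vector of per-class multiplicative
#'   amplitude factors (all > 0). Classes absent from the vector get factor 1.
#' @return A `band_spec` list.
#' @export
band_spec <- function(center, width, amplitude, class_effects = numeric(0)) {
  stopifnot(width > 0, amplitude >= 0)
  if (length(class_effects) && (is.null(names(class_effects)) ||
                                any(class_effects <= 0))) {
    stop("class_effects must be a named vector of positive factors")
  }
  structure(list(center = center, width = width, amplitude = amplitude,
                 class_effects = class_effects), class = "band_spec")
}

#' Default serum band table
#'
#' Eleven Gaussian bands covering the ester-carbonyl, amide, CH2,
#' collagen/amide III, phosphate-diester and carbohydrate regions of the
#' 1800-900 cm^-1 fingerprint window. The allergic class perturbs the ester
#' (1740) band by +10% and the amide I/II (1655/1545) bands by -8%; the
#' tolerized/SIT class perturbs the four carbohydrate bands (1165, 1120,
#' 1080, 1030) by +8%. `separation` scales these effects on the log scale:
#' "low" halves them, "high" doubles them.
#'
#' @param classes Character vector of class labels, in order
#'   (reference class first).
#' @param separation One of "low", "moderate", "high".
#' @return List of [band_spec()] objects.
#' @export
default_serum_bands <- function(classes = c("nonallergic", "allergic", "tolerized"),
                                separation = c("moderate", "low", "high")) {
  separation <- match.arg(separation)
  s <- switch(separation, low = 0.5, moderate = 1, high = 2)
  allergic <- classes[2L]
  tolerized <- classes[3L]
  eff <- function(...) {
    e <- c(...)
    e ^ s
  }
  list(
    band_spec(1740, 12, 0.10, eff(structure(1.10, names = allergic))),  # ester C=O
    band_spec(1655, 18, 0.45, eff(structure(0.92, names = allergic))),  # amide I
    band_spec(1545, 16, 0.30, eff(structure(0.92, names = allergic))),  # amide II
    band_spec(1455, 12, 0.12),                                          # CH2 bend
    band_spec(1310, 14, 0.08),                                          # collagen/amide III
    band_spec(1240, 12, 0.10),                                          # amide III
    band_spec(1235, 10, 0.08),                                          # phosphate diester
    band_spec(1165, 10, 0.10, eff(structure(1.08, names = tolerized))), # carbohydrate
    band_spec(1120, 10, 0.08, eff(structure(1.08, names = tolerized))), # carbohydrate
    band_spec(1080, 12, 0.14, eff(structure(1.08, names = tolerized))), # carbohydrate
    band_spec(1030, 10, 0.12, eff(structure(1.08, names = tolerized)))  # carbohydrate
  )
}

# 12 fixed narrow residual water-vapor lines (sigma 2 cm^-1). Rotational
# lines span ~1900-1400 cm^-1; two fall inside the 1847-1837 QC window.
WATER_VAPOR_LINES <- c(1889.6, 1869.3, 1844.3, 1838.9, 1820.1, 1791.8,
                       1772.6, 1751.2, 1718.4, 1683.9, 1652.7, 1616.3)

#' Simulation configuration for synthetic serum FTIR datasets
#'
#' Defaults emulate a transmission acquisition over 4000-500 cm^-1 at
#' 1.5 cm^-1 digital spacing (grid anchored so 900 and 1800 cm^-1 are exact
#' grid points), three classes, 20 replicate spectra per subject,
#' subject-level log-normal band-amplitude variability, multiplicative
#' scatter, polynomial baseline drift, additive white noise, a residual
#' water-vapor line comb, optional between-batch grid shift and gain, and a
#' small fraction of gross outliers.
#'
#' @param grid_start,grid_end,grid_step Wavenumber grid (cm^-1).
#' @param classes Ordered class labels (reference class first).
#' @param n_subjects_per_class,n_replicates_per_subject Cohort sizes.
#' @param bands List of [band_spec()]; defaults to [default_serum_bands()].
#' @param subject_sd Log-sd of per-subject, per-band amplitude factors.
#' @param scatter_slope_sd Log-sd of the multiplicative scatter gain b.
#' @param scatter_offset_sd Sd (AU) of the additive scatter offset a.
#' @param baseline_degree,baseline_sd Polynomial baseline drift: degree and
#'   per-coefficient sd (AU, on a grid scaled to [-1, 1]).
#' @param noise_sd Additive white-noise sd (AU).
#' @param water_vapor_amplitude Scale (AU) of the residual water-vapor comb;
#'   the per-spectrum multiplier is N(0, 1) (over/under compensation).
#' @param n_batches Number of acquisition batches; subjects are assigned to
#'   batches in a balanced round-robin within class.
#' @param batch_shift Grid shift (cm^-1) applied per batch beyond the first.
#' @param batch_gain Multiplicative response per batch beyond the first.
#' @param outlier_fraction Fraction of spectra replaced by gross outliers.
#' @param seed Integer seed; equal (config, seed) gives byte-identical data.
#' @return A `sim_config` list.
#' @export
sim_config <- function(grid_start = 499.5, grid_end = 4000.5, grid_step = 1.5,
                       classes = c("nonallergic", "allergic", "tolerized"),
                       n_subjects_per_class = 20L,
                       n_replicates_per_subject = 20L,
                       bands = default_serum_bands(classes),
                       subject_sd = 0.03,
                       scatter_slope_sd = 0.05,
                       scatter_offset_sd = 0.01,
                       baseline_degree = 2L,
                       baseline_sd = 0.005,
                       noise_sd = 0.002,
                       water_vapor_amplitude = 5e-4,
                       n_batches = 1L,
                       batch_shift = 1.5,
                       batch_gain = 1.05,
                       outlier_fraction = 0,
                       seed = 1L) {
  stopifnot(grid_start < grid_end, grid_step > 0,
            n_replicates_per_subject >= 1L, n_subjects_per_class >= 1L,
            outlier_fraction >= 0, outlier_fraction < 1,
            subject_sd >= 0, scatter_slope_sd >= 0, scatter_offset_sd >= 0,
            baseline_sd >= 0, noise_sd >= 0, water_vapor_amplitude >= 0,
            n_batches >= 1L, length(classes) >= 2L)
  structure(list(
    grid_start = grid_start, grid_end = grid_end, grid_step = grid_step,
    classes = classes,
    n_subjects_per_class = as.integer(n_subjects_per_class),
    n_replicates_per_subject = as.integer(n_replicates_per_subject),
    bands = bands, subject_sd = subject_sd,
    scatter_slope_sd = scatter_slope_sd, scatter_offset_sd = scatter_offset_sd,
    baseline_degree = as.integer(baseline_degree), baseline_sd = baseline_sd,
    noise_sd = noise_sd, water_vapor_amplitude = water_vapor_amplitude,
    n_batches = as.integer(n_batches), batch_shift = batch_shift,
    batch_gain = batch_gain, outlier_fraction = outlier_fraction,
    seed = as.integer(seed)), class = "sim_config")
}

#' Shipped cohort presets
#'
#' `"human"` mirrors a 3 x 20-subject single-batch cohort with the larger
#' between-subject variability of an outbred population; `"mouse"` a
#' 3 x 10-subject cohort measured in two acquisition batches (motivating
#' piecewise direct standardization) with the smaller variability of inbred
#' animals.
#'
#' @param preset `"human"` or `"mouse"`.
#' @param separation Class-effect scaling passed to [default_serum_bands()].
#' @param seed Integer seed.
#' @param ... Overrides forwarded to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_preset <- function(preset = c("human", "mouse"),
                       separation = "moderate", seed = 1L, ...) {
  preset <- match.arg(preset)
  classes <- c("nonallergic", "allergic", "tolerized")
  base <- switch(preset,
    human = list(n_subjects_per_class = 20L, n_batches = 1L,
                 subject_sd = 0.03, outlier_fraction = 0.02),
    mouse = list(n_subjects_per_class = 10L, n_batches = 2L,
                 subject_sd = 0.015, outlier_fraction = 0.02))
  args <- utils::modifyList(
    c(base, list(classes = classes,
                 bands = default_serum_bands(classes, separation),
                 seed = seed)),
    list(...))
  do.call(sim_config, args)
}

#' Wavenumber grid of a configuration
#' @param config A `sim_config`.
#' @return Ascending numeric grid (cm^-1).
#' @export
sim_grid <- function(config) {
  seq(config$grid_start, config$grid_end, by = config$grid_step)
}

#' Noiseless class/subject base spectrum
#'
#' Sum over bands of `amplitude x class_effect(class) x subject_factor x
#' Gaussian(center, width)` evaluated on the configuration grid.
#'
#' @param config A `sim_config`.
#' @param class_label One of `config$classes`.
#' @param subject_factors Positive per-band factors (default all 1).
#' @return Numeric vector on the grid, non-negative everywhere.
#' @export
make_base_spectrum <- function(config, class_label,
                               subject_factors = rep(1, length(config$bands))) {
  if (!class_label %in% config$classes) {
    stop("unknown class label '", class_label, "'; expected one of: ",
         paste(config$classes, collapse = ", "))
  }
  if (length(subject_factors) != length(config$bands) ||
      any(subject_factors <= 0)) {
    stop("subject_factors must supply one positive factor per band")
  }
  w <- sim_grid(config)
  y <- numeric(length(w))
  for (i in seq_along(config$bands)) {
    b <- config$bands[[i]]
    ce <- 1
    if (class_label %in% names(b$class_effects)) {
      ce <- unname(b$class_effects[[class_label]])
    }
    y <- y + b$amplitude * ce * subject_factors[i] *
      gaussian_band((w - b$center) / b$width)
  }
  y
}

# compactly supported Gaussian profile: identical to exp(-t^2/2) up to a
# ~3e-4 vertical rescale, but exactly zero beyond |t| = 4 so class effects
# are strictly local to their bands; peak value is exactly 1
gaussian_band <- function(t) {
  tail <- exp(-8)
  pmax(0, (exp(-pmin(t^2, 16) / 2) - tail) / (1 - tail))
}

water_vapor_comb <- function(w) {
  comb <- numeric(length(w))
  for (pos in WATER_VAPOR_LINES) {
    comb <- comb + exp(-(w - pos)^2 / (2 * 2^2))
  }
  comb
}

#' Add measurement artifacts to a clean spectrum
#'
#' Applies, in order: multiplicative scatter (`b*x + a` with log-normal `b`
#' and normal `a`), polynomial baseline drift, a residual water-vapor line
#' comb, per-batch grid shift (linear interpolation) and gain, and additive
#' white noise. Draws use the current R RNG stream; seed outside. With all
#' sd/amplitude parameters zero and `batch_index = 1` the output equals the
#' input.
#'
#' @param x Clean spectrum on the configuration grid.
#' @param config A `sim_config`.
#' @param batch_index 1-based batch; batch 1 is the reference (no shift/gain).
#' @return Numeric vector, same length as `x`.
#' @export
inject_artifacts <- function(x, config, batch_index = 1L) {
  w <- sim_grid(config)
  if (length(x) != length(w)) stop("spectrum is not on the configuration grid")
  b <- exp(stats::rnorm(1, 0, config$scatter_slope_sd))
  a <- stats::rnorm(1, 0, config$scatter_offset_sd)
  z <- b * x + a
  if (config$baseline_degree >= 0 && config$baseline_sd > 0) {
    t <- 2 * (w - min(w)) / (max(w) - min(w)) - 1
    coef <- stats::rnorm(config$baseline_degree + 1L, 0, config$baseline_sd)
    z <- z + drop(outer(t, 0:config$baseline_degree, `^`) %*% coef)
  } else if (config$baseline_degree >= 0) {
    # keep the RNG stream aligned whether or not drift is enabled
    invisible(stats::rnorm(config$baseline_degree + 1L, 0, 1))
  }
  wv <- stats::rnorm(1, 0, 1)
  if (config$water_vapor_amplitude > 0) {
    z <- z + wv * config$water_vapor_amplitude * water_vapor_comb(w)
  }
  if (batch_index > 1L) {
    shift <- (batch_index - 1L) * config$batch_shift
    if (shift != 0) {
      z <- stats::approx(w, z, xout = w - shift, rule = 2)$y
    }
    z <- z * config$batch_gain^(batch_index - 1L)
  }
  if (config$noise_sd > 0) {
    z <- z + stats::rnorm(length(z), 0, config$noise_sd)
  } else {
    invisible(stats::rnorm(1, 0, 1))
  }
  z
}

# Subject-level RNG stream: keyed by global subject index so growing the
# replicate count never changes existing subjects' draws.
subject_stream_seed <- function(seed, subject_index) {
  as.integer((as.numeric(seed) + 77003 * subject_index) %% 2147483629)
}

#' Generate a synthetic serum FTIR dataset with ground truth
#'
#' Emits `n_classes x n_subjects_per_class x n_replicates_per_subject`
#' spectra plus a truth table (subject, class, batch, replicate, outlier
#' flag/type). Subject band factors are log-normal with sd
#' `config$subject_sd`, drawn from per-subject streams; artifacts are drawn
#' per replicate; `outlier_fraction` of spectra are then corrupted by
#' [inject_outliers()].
#'
#' @param config A `sim_config`.
#' @return List with elements `dataset` (a [spectral_dataset()]) and
#'   `truth` (data frame).
#' @export
generate_dataset <- function(config) {
  grid <- sim_grid(config)
  nb <- length(config$bands)
  n_total <- length(config$classes) * config$n_subjects_per_class *
    config$n_replicates_per_subject
  X <- matrix(0, n_total, length(grid))
  meta <- vector("list", n_total)
  row <- 0L
  subject_index <- 0L
  for (ci in seq_along(config$classes)) {
    cls <- config$classes[ci]
    for (sj in seq_len(config$n_subjects_per_class)) {
      subject_index <- subject_index + 1L
      batch <- ((sj - 1L) %% config$n_batches) + 1L
      sid <- sprintf("%s_s%02d", cls, sj)
      set.seed(subject_stream_seed(config$seed, subject_index))
      sf <- exp(stats::rnorm(nb, 0, config$subject_sd))
      base <- make_base_spectrum(config, cls, sf)
      for (r in seq_len(config$n_replicates_per_subject)) {
        row <- row + 1L
        X[row, ] <- inject_artifacts(base, config, batch_index = batch)
        meta[[row]] <- data.frame(
          spectrum_id = sprintf("%s_r%02d", sid, r),
          subject_id = sid, group = cls,
          batch = sprintf("batch%d", batch), replicate = r)
      }
    }
  }
  meta <- do.call(rbind, meta)
  ds <- spectral_dataset(grid, X, meta)
  out <- inject_outliers(ds, config$outlier_fraction,
                         seed = subject_stream_seed(config$seed, subject_index + 1L))
  truth <- cbind(ds$meta,
                 is_outlier = out$mask,
                 outlier_type = out$type,
                 stringsAsFactors = FALSE)
  list(dataset = out$dataset, truth = truth)
}

#' Corrupt a fraction of spectra with gross outliers
#'
#' Replaces `floor(fraction * n)` spectra (at least one when
#' `fraction > 0`) by one of three gross corruptions: 10x amplitude
#' scaling, a saturated flat-top segment (4 AU across 1700-1600 cm^-1), or
#' a strong sloped baseline (+3 AU across the grid).
#'
#' @param dataset A [spectral_dataset()].
#' @param fraction Fraction in `[0, 1)`.
#' @param seed Optional integer seed for the selection/type draws.
#' @return List: `dataset` (corrupted copy), `mask` (logical per row),
#'   `type` (character per row, `"none"` for clean rows).
#' @export
inject_outliers <- function(dataset, fraction, seed = NULL) {
  stopifnot(fraction >= 0, fraction < 1)
  n <- n_spectra(dataset)
  mask <- rep(FALSE, n)
  type <- rep("none", n)
  k <- floor(fraction * n)
  if (fraction > 0 && k < 1L) k <- 1L
  if (k == 0L) return(list(dataset = dataset, mask = mask, type = type))
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n, k)
  kinds <- sample(c("scale10x", "flat_top", "slope"), k, replace = TRUE)
  w <- dataset$wavenumbers
  X <- dataset$intensities
  for (i in seq_len(k)) {
    r <- idx[i]
    X[r, ] <- switch(kinds[i],
      scale10x = 10 * X[r, ],
      flat_top = { y <- X[r, ]; y[w >= 1600 & w <= 1700] <- 4; y },
      slope    = X[r, ] + 3 * (w - min(w)) / (max(w) - min(w)))
  }
  mask[idx] <- TRUE
  type[idx] <- kinds
  list(dataset = spectral_dataset(w, X, dataset$meta), mask = mask, type = type)
}

#' Paired transfer standards for calibration transfer
#'
#' Renders the same clean subject spectra under batch-1 (master) and
#' batch-k (slave) acquisition conditions, giving the paired measurements a
#' piecewise-direct-standardization fit requires. Standards are drawn
#' round-robin across classes with fresh subject factors, independent of
#' the cohort subjects.
#'
#' @param config A `sim_config` (needs `n_batches >= 2` in spirit; the
#'   slave batch index is given explicitly).
#' @param n_pairs Number of transfer samples (>= 3); the default matches
#'   three standards measured as 20 replicate films in each batch.
#' @param slave_batch Batch index rendered as the slave (default 2).
#' @param seed Integer seed.
#' @return List of two [spectral_dataset()]s, `master` and `slave`, with
#'   identical row order.
#' @export
generate_transfer_pairs <- function(config, n_pairs = 60L, slave_batch = 2L,
                                    seed = config$seed + 104729L) {
  stopifnot(n_pairs >= 3L, slave_batch >= 2L)
  grid <- sim_grid(config)
  nb <- length(config$bands)
  set.seed(as.integer(seed %% 2147483629))
  Xm <- matrix(0, n_pairs, length(grid))
  Xs <- matrix(0, n_pairs, length(grid))
  cls <- rep_len(config$classes, n_pairs)
  for (i in seq_len(n_pairs)) {
    sf <- exp(stats::rnorm(nb, 0, config$subject_sd))
    base <- make_base_spectrum(config, cls[i], sf)
    Xm[i, ] <- inject_artifacts(base, config, batch_index = 1L)
    Xs[i, ] <- inject_artifacts(base, config, batch_index = slave_batch)
  }
  meta <- data.frame(spectrum_id = sprintf("std_%02d", seq_len(n_pairs)),
                     subject_id = sprintf("std_%02d", seq_len(n_pairs)),
                     group = cls, replicate = 1L)
  master <- spectral_dataset(grid, Xm, transform(meta, batch = "batch1"))
  slave <- spectral_dataset(grid, Xs,
                            transform(meta, batch = sprintf("batch%d", slave_batch)))
  list(master = master, slave = slave)
}
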