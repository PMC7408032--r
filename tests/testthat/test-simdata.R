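test_that("base spectra are the stated sums of Gaussians", {
  cfg <- noiseless_config(bands = one_band(1656, 18, 0.5))  # grid-aligned center
  y <- make_base_spectrum(cfg, "nonallergic")
  w <- sim_grid(cfg)
  expect_equal(y[which.min(abs(w - 1656))], 0.5, tolerance = 1e-12)
  expect_true(all(y >= 0))

  cfg0 <- noiseless_config(bands = list(band_spec(1655, 18, 0),
                                        band_spec(1080, 12, 0)))
  expect_equal(make_base_spectrum(cfg0, "allergic"), rep(0, length(w)))

  expect_error(make_base_spectrum(cfg, "martian"), "unknown class")
  expect_error(make_base_spectrum(cfg, "allergic", subject_factors = c(1, 1)),
               "one positive factor per band")
})

test_that("class effects act multiplicatively and locally at the band", {
  # two classes differing only by a 1.10 factor on the 1740 band
  bands <- list(band_spec(1740, 12, 0.2,
                          class_effects = c(allergic = 1.10)),
                band_spec(1080, 12, 0.3))
  cfg <- noiseless_config(bands = bands)
  w <- sim_grid(cfg)
  y_ref <- make_base_spectrum(cfg, "nonallergic")
  y_all <- make_base_spectrum(cfg, "allergic")
  ic <- which.min(abs(w - 1740))
  expect_equal(y_all[ic] / y_ref[ic], 1.10, tolerance = 1e-12)
  outside <- abs(w - 1740) > 4 * 12
  expect_equal(y_all[outside], y_ref[outside], tolerance = 1e-12)
})

test_that("between-class differences vanish outside perturbed-band neighborhoods", {
  cfg <- noiseless_config()
  w <- sim_grid(cfg)
  perturbed <- vapply(cfg$bands, function(b) length(b$class_effects) > 0, TRUE)
  hot <- rep(FALSE, length(w))
  for (b in cfg$bands[perturbed]) hot <- hot | abs(w - b$center) <= 4 * b$width
  for (cls in c("allergic", "tolerized")) {
    d <- make_base_spectrum(cfg, cls) - make_base_spectrum(cfg, "nonallergic")
    expect_true(max(abs(d[!hot])) < 1e-6 * max(abs(d)))
  }
})

test_that("artifact injection reduces to the identity when all channels are off", {
  cfg <- noiseless_config(bands = one_band())
  x <- make_base_spectrum(cfg, "nonallergic")
  set.seed(1)
  expect_equal(inject_artifacts(x, cfg, batch_index = 1L), x, tolerance = 1e-14)
})

test_that("additive noise has the configured standard deviation", {
  cfg <- noiseless_config(bands = one_band(), noise_sd = 0.01)
  x <- make_base_spectrum(cfg, "nonallergic")
  set.seed(42)
  out <- replicate(5, inject_artifacts(x, cfg))
  d <- as.vector(out) - rep(x, 5)         # > 1e4 points
  expect_gt(length(d), 1e4)
  expect_equal(sd(d), 0.01, tolerance = 0.03)
})

test_that("batch shift by one grid step moves intensities by one index", {
  cfg <- noiseless_config(bands = one_band(), n_batches = 2L,
                          batch_shift = 1.5, batch_gain = 1)
  x <- make_base_spectrum(cfg, "nonallergic")
  set.seed(3)
  y <- inject_artifacts(x, cfg, batch_index = 2L)
  n <- length(x)
  expect_equal(y[2:n], x[1:(n - 1)], tolerance = 1e-12)
})

test_that("dataset generation has the contracted size, truth table and determinism", {
  cfg <- sim_preset("human", seed = 42, n_replicates_per_subject = 2L,
                    outlier_fraction = 0)
  g1 <- generate_dataset(cfg)
  expect_equal(n_spectra(g1$dataset), 3 * 20 * 2)
  expect_equal(nrow(g1$truth), 3 * 20 * 2)
  expect_identical(g1$truth$spectrum_id, g1$dataset$meta$spectrum_id)
  # all replicates of a subject share one class and one batch
  by_subj <- split(g1$truth[, c("group", "batch")], g1$truth$subject_id)
  expect_true(all(vapply(by_subj, function(d) nrow(unique(d)) == 1L, TRUE)))

  g2 <- generate_dataset(cfg)
  expect_identical(g1$dataset$intensities, g2$dataset$intensities)
  expect_identical(g1$truth, g2$truth)
})

test_that("growing the replicate count preserves existing subject draws", {
  cfg2 <- tiny_config(n_replicates_per_subject = 2L)
  cfg4 <- tiny_config(n_replicates_per_subject = 4L)
  g2 <- generate_dataset(cfg2)
  g4 <- generate_dataset(cfg4)
  expect_equal(n_spectra(g4$dataset), 2L * n_spectra(g2$dataset))
  common <- g2$dataset$meta$spectrum_id
  idx4 <- match(common, g4$dataset$meta$spectrum_id)
  expect_equal(g4$dataset$intensities[idx4, ], g2$dataset$intensities,
               ignore_attr = TRUE)
})

test_that("outlier injection follows the floor-with-minimum count rule", {
  ds <- random_dataset(10)
  out0 <- inject_outliers(ds, 0)
  expect_false(any(out0$mask))
  expect_identical(out0$dataset$intensities, ds$intensities)

  out5 <- inject_outliers(ds, 0.5, seed = 1)
  expect_equal(sum(out5$mask), 5L)
  expect_setequal(unique(out5$type[out5$mask]),
                  intersect(c("scale10x", "flat_top", "slope"),
                            out5$type))

  # floor(0.02 * 1200) = 24; and fraction > 0 forces at least one
  cfg <- sim_preset("human", seed = 42)
  tr <- generate_dataset(cfg)$truth
  expect_equal(sum(tr$is_outlier), 24L)
  expect_equal(sum(inject_outliers(ds, 0.01, seed = 2)$mask), 1L)
})

test_that("corrupted spectra are gross relative to the clean set", {
  cfg <- sim_preset("human", seed = 7, n_subjects_per_class = 5L,
                    n_replicates_per_subject = 4L, outlier_fraction = 0.1)
  g <- generate_dataset(cfg)
  mx <- apply(g$dataset$intensities, 1, max)
  clean99 <- quantile(mx[!g$truth$is_outlier], 0.99)
  expect_true(all(mx[g$truth$is_outlier] > 5 * clean99 |
                    g$truth$outlier_type[g$truth$is_outlier] != "scale10x"))
  expect_true(all(mx[g$truth$is_outlier] > 2 * clean99))
})

test_that("the human preset has larger between-subject variability than mouse", {
  amp_var <- function(preset) {
    cfg <- sim_preset(preset, seed = 99, n_subjects_per_class = 20L,
                      n_replicates_per_subject = 1L, outlier_fraction = 0,
                      scatter_slope_sd = 0, scatter_offset_sd = 0,
                      baseline_sd = 0, noise_sd = 0, water_vapor_amplitude = 0,
                      n_batches = 1L)
    g <- generate_dataset(cfg)
    w <- g$dataset$wavenumbers
    i <- which.min(abs(w - 1655))
    stats::var(g$dataset$intensities[g$truth$group == "nonallergic", i])
  }
  expect_gt(amp_var("human"), amp_var("mouse"))
})
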