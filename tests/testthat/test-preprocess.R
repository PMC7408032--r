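test_that("truncation keeps exactly the closed-window grid points", {
  g <- generate_dataset(noiseless_config())
  ds <- g$dataset
  tr <- truncate_window(ds, 900, 1800)
  # brute-force count on the default grid
  expect_equal(n_points(tr), sum(ds$wavenumbers >= 900 & ds$wavenumbers <= 1800))
  expect_equal(n_points(tr), 601L)
  expect_identical(tr$meta, ds$meta)

  full <- truncate_window(ds, min(ds$wavenumbers), max(ds$wavenumbers))
  expect_equal(full$intensities, ds$intensities)

  expect_error(truncate_window(ds, 1800, 900), "low bound")
  expect_error(truncate_window(ds, 10000, 20000), "does not intersect")
})

test_that("SG second derivative annihilates lines and is exact on quadratics", {
  w <- seq(1000, 1300, by = 1.5)
  lin <- spectral_dataset(w, rbind(2.5 * w + 3, -0.1 * w + 40))
  dl <- sg_second_derivative(lin, 15L, 3L)
  expect_lt(max(abs(dl$intensities)), 1e-10)

  quad <- spectral_dataset(w, matrix(w^2, 1))
  dq <- sg_second_derivative(quad, 15L, 3L)
  expect_equal(as.vector(dq$intensities), rep(2, n_points(dq)), tolerance = 1e-8)
  # edge policy: (15-1)/2 points dropped at each end
  expect_equal(n_points(dq), length(w) - 14L)
  expect_equal(dq$wavenumbers, w[8:(length(w) - 7)])
})

test_that("SG second derivative matches the analytic Gaussian derivative within 2%", {
  # smoothing bias scales as (window / band width)^2; a broad band keeps the
  # 15-point window's bias under 2%, a narrow amide-like band under 8%
  gauss_err <- function(s) {
    w <- seq(1300, 2000, by = 1.5); c0 <- 1650
    y <- exp(-(w - c0)^2 / (2 * s^2))
    d <- sg_second_derivative(spectral_dataset(w, matrix(y, 1)), 15L, 3L)
    analytic <- ((d$wavenumbers - c0)^2 / s^4 - 1 / s^2) *
      exp(-(d$wavenumbers - c0)^2 / (2 * s^2))
    within <- abs(d$wavenumbers - c0) <= 2 * s
    max(abs(d$intensities[1, within] - analytic[within])) / max(abs(analytic))
  }
  expect_lt(gauss_err(45), 0.02)
  expect_lt(gauss_err(18), 0.08)
})

test_that("SG second derivative is linear and commutes with interior truncation", {
  set.seed(2)
  w <- seq(900, 1200, by = 1.5)
  x <- rnorm(length(w)); y <- rnorm(length(w))
  D <- function(v) sg_second_derivative(spectral_dataset(w, matrix(v, 1)))$intensities
  expect_equal(D(x + y), D(x) + D(y), tolerance = 1e-10)
  expect_equal(D(3.7 * x), 3.7 * D(x), tolerance = 1e-10)

  ds <- spectral_dataset(w, rbind(x, y))
  d_then_t <- truncate_window(sg_second_derivative(ds), 950, 1150)
  t_then_d <- sg_second_derivative(truncate_window(ds, 950, 1150))
  common <- intersect(round(d_then_t$wavenumbers, 6), round(t_then_d$wavenumbers, 6))
  i1 <- match(common, round(d_then_t$wavenumbers, 6))
  i2 <- match(common, round(t_then_d$wavenumbers, 6))
  expect_equal(d_then_t$intensities[, i1], t_then_d$intensities[, i2],
               tolerance = 1e-10)

  expect_error(sg_second_derivative(spectral_dataset(c(w[-2], 2000), rbind(x))),
               "not uniform")
})

test_that("MSC recovers affine scatter distortions in closed form", {
  g <- generate_dataset(noiseless_config())
  ds <- truncate_window(g$dataset, 900, 1800)
  ref <- colMeans(ds$intensities)

  m1 <- msc(spectral_dataset(ds$wavenumbers, rbind(ref, 2 * ref + 5)), ref)
  expect_equal(m1$coefficients$offset, c(0, 5), tolerance = 1e-10)
  expect_equal(m1$coefficients$slope, c(1, 2), tolerance = 1e-10)
  expect_equal(m1$dataset$intensities[2, ], ref, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("MSC coefficients equal the normal-equations oracle", {
  ds <- random_dataset(6, 30, seed = 21)
  ref <- colMeans(ds$intensities)
  m <- msc(ds, ref)
  for (i in 1:6) {
    beta <- solve(crossprod(cbind(1, ref)), crossprod(cbind(1, ref),
                                                      ds$intensities[i, ]))
    expect_equal(m$coefficients$offset[i], beta[1], tolerance = 1e-8)
    expect_equal(m$coefficients$slope[i], beta[2], tolerance = 1e-8)
  }
  flat <- spectral_dataset(ds$wavenumbers,
                           rbind(ds$intensities[1, ], rep(1, 30)))
  expect_error(msc(flat, ref), "degenerate scatter fit")
})

test_that("unit-vector normalization has norm-1 postcondition and scale invariance", {
  w <- seq_len(10) + 1000
  x <- c(3, 4, rep(0, 8))
  vn <- vector_normalize(spectral_dataset(w, matrix(x, 1)))
  expect_equal(as.vector(vn$intensities), c(0.6, 0.8, rep(0, 8)))
  expect_equal(vector_normalize(vn)$intensities, vn$intensities)

  ds <- random_dataset(5, 12, seed = 3)
  a <- vector_normalize(ds)
  b <- vector_normalize(spectral_dataset(ds$wavenumbers, 17 * ds$intensities,
                                         ds$meta))
  expect_equal(a$intensities, b$intensities, tolerance = 1e-12)
  expect_lt(max(abs(sqrt(rowSums(a$intensities^2)) - 1)), 1e-12)

  zero <- spectral_dataset(w, matrix(0, 1, 10),
                           data.frame(spectrum_id = "nil"))
  expect_error(vector_normalize(zero), "nil")
})

test_that("scalers fit on training data and reuse those statistics unchanged", {
  ds <- random_dataset(20, 15, seed = 9)
  mc <- apply_scaler(fit_scaler(ds, "mean-center"), ds)
  expect_lt(max(abs(colMeans(mc$intensities))), 1e-10)
  st <- apply_scaler(fit_scaler(ds, "standardize"), ds)
  expect_lt(max(abs(apply(st$intensities, 2, sd) - 1)), 1e-10)

  state <- fit_scaler(ds, "mean-center")
  shift <- 0.35
  test <- spectral_dataset(ds$wavenumbers, ds$intensities + shift, ds$meta)
  out <- apply_scaler(state, test)
  expect_equal(unname(colMeans(out$intensities)),
               rep(shift, 15) + unname(colMeans(ds$intensities)) -
                 unname(state$mean),
               tolerance = 1e-10)

  flat <- spectral_dataset(ds$wavenumbers,
                           cbind(ds$intensities[, -1], rep(1, 20)))
  expect_error(fit_scaler(flat, "standardize"), "zero-variance")
})

test_that("the full chain is deterministic and removes affine distortion", {
  cfg <- noiseless_config()
  ds <- generate_dataset(cfg)$dataset
  p1 <- preprocess_pipeline(ds)
  p2 <- preprocess_pipeline(ds)
  expect_identical(p1$intensities, p2$intensities)
  # artifacts off: replicates of one subject give identical processed rows
  reps <- which(p1$meta$subject_id == p1$meta$subject_id[1])
  expect_equal(p1$intensities[reps[1], ], p1$intensities[reps[2], ],
               tolerance = 1e-12)
  expect_equal(attr(p1, "steps")[1:4],
               c("truncate[900,1800]", "sg_second_derivative[n=15,p=3]",
                 "msc[dataset-mean]", "vector_normalize"))

  # per-spectrum affine distortion b*x + a is removed to ~1% RMS
  distorted <- ds
  set.seed(4)
  b <- exp(rnorm(n_spectra(ds), 0, 0.3))
  a <- rnorm(n_spectra(ds), 0, 0.1)
  distorted <- spectral_dataset(ds$wavenumbers, ds$intensities * b + a, ds$meta)
  pd <- preprocess_pipeline(distorted)
  rms <- sqrt(mean((pd$intensities - p1$intensities)^2)) /
    sqrt(mean(p1$intensities^2))
  expect_lt(rms, 0.01)
})
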