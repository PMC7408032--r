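# a small, high-separation, spectrum-mode benchmark the CNN solves quickly
bench_features <- function(seed = 15, grouping = "spectrum",
                           n_subjects = 5L, n_reps = 8L) {
  cfg <- sim_preset("human", separation = "high", seed = seed,
                    n_subjects_per_class = n_subjects,
                    n_replicates_per_subject = n_reps, outlier_fraction = 0)
  ds <- generate_dataset(cfg)$dataset
  derived <- sg_second_derivative(truncate_window(ds, 900, 1800), 15L, 3L)
  split <- make_splits(derived, grouping = grouping, n_repeats = 1L,
                       seed = seed)[[1L]]
  c(prepare_split_features(derived, split$assignment),
    list(classes = cfg$classes, input_length = n_points(derived)))
}

small_net <- function(input_length, ...) {
  build_cnn(cnn_architecture(section_depth = 1L, filter_size = 5L,
                             n_filters = 4L, ...), input_length)
}

test_that("stratified splits have largest-remainder sizes and honor grouping", {
  cfg <- sim_preset("human", seed = 1, outlier_fraction = 0)
  ds <- generate_dataset(cfg)$dataset

  sp <- make_splits(ds, grouping = "spectrum", n_repeats = 2L, seed = 4L)
  expect_equal(unname(table(sp[[1]]$assignment)),
               c(780L, 240L, 180L), ignore_attr = TRUE)
  # stratification: exact ratios within every class
  for (cl in unique(ds$meta$group)) {
    tab <- table(sp[[1]]$assignment[ds$meta$group == cl])
    expect_equal(unname(tab), c(260L, 80L, 60L), ignore_attr = TRUE)
  }

  su <- make_splits(ds, grouping = "subject", n_repeats = 2L, seed = 4L)
  cross <- table(ds$meta$subject_id, su[[1]]$assignment)
  expect_true(all(rowSums(cross > 0) == 1L))   # no subject in two subsets

  again <- make_splits(ds, grouping = "subject", n_repeats = 2L, seed = 4L)
  expect_identical(su[[1]]$assignment, again[[1]]$assignment)
  expect_false(identical(su[[1]]$assignment, su[[2]]$assignment))

  small <- ds[which(ds$meta$subject_id %in%
                      c("nonallergic_s01", "allergic_s01", "allergic_s02",
                        "tolerized_s01", "tolerized_s02", "tolerized_s03"))]
  expect_error(make_splits(small, grouping = "subject"), "too small")
})

test_that("network descriptions track depth, and degenerate pooling is an error", {
  n1 <- build_cnn(cnn_architecture(section_depth = 1L), 587L)
  n3 <- build_cnn(cnn_architecture(section_depth = 3L), 587L)
  conv_params <- function(n) sum(n$layers$parameters[grepl("conv", n$layers$layer)])
  # deeper sections add conv parameters (the dense layer after the flatten
  # shrinks with extra pooling, so the total need not grow)
  expect_gt(conv_params(n3), conv_params(n1))
  expect_gt(nrow(n3$layers), nrow(n1$layers))
  expect_equal(nrow(n1$layers), 1L + 2L + 2L)   # blocks + 2 dense layers
  expect_error(build_cnn(cnn_architecture(section_depth = 3L), 40L),
               "conv block")
})

test_that("an untrained network on all-zero input is exactly uniform; rows sum to 1", {
  f <- bench_features()
  net <- small_net(f$input_length)
  fit <- train_cnn(net, f$x_train, f$y_train, f$x_val, f$y_val,
                   training_params(learning_rate = 0, max_epochs = 1L,
                                   seed = 2L),
                   classes = f$classes)
  p0 <- predict(fit, matrix(0, 2, f$input_length))
  expect_equal(unname(p0), matrix(1 / 3, 2, 3), tolerance = 1e-12)

  pr <- predict(fit, f$x_test)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-6,
               ignore_attr = TRUE)
  # duplicating an input row duplicates its output row exactly
  two <- predict(fit, f$x_test[c(1, 1), ])
  expect_identical(two[1, ], two[2, ])
})

test_that("zero learning rate leaves the network unchanged across epochs", {
  f <- bench_features()
  net <- small_net(f$input_length)
  fit1 <- train_cnn(net, f$x_train, f$y_train, f$x_val, f$y_val,
                    training_params(learning_rate = 0, max_epochs = 1L, seed = 9L),
                    classes = f$classes)
  fit5 <- train_cnn(net, f$x_train, f$y_train, f$x_val, f$y_val,
                    training_params(learning_rate = 0, max_epochs = 5L,
                                    patience = 99L, seed = 9L),
                    classes = f$classes)
  expect_equal(fit1$weights, fit5$weights, tolerance = 1e-15)
  expect_lt(diff(range(fit5$history$val_loss)), 1e-12)
})

test_that("early stopping restores the best-validation weights", {
  f <- bench_features()
  net <- small_net(f$input_length)
  full <- train_cnn(net, f$x_train, f$y_train, f$x_val, f$y_val,
                    training_params(max_epochs = 30L, patience = 3L, seed = 5L),
                    classes = f$classes)
  # retraining with the same seed up to the best epoch reproduces the
  # restored weights (per-epoch RNG use is sequential and deterministic)
  rerun <- train_cnn(net, f$x_train, f$y_train, f$x_val, f$y_val,
                     training_params(max_epochs = full$best_epoch,
                                     patience = 99L, seed = 5L),
                     classes = f$classes)
  expect_equal(full$weights, rerun$weights, tolerance = 1e-12)
  expect_lte(full$stopped_epoch, 30L)
  expect_lte(full$best_epoch + 3L + 1L,
             max(full$best_epoch + 4L, full$stopped_epoch + 1L))
})

test_that("the CNN solves the high-separation benchmark and divergence is reported", {
  f <- bench_features()
  net <- small_net(f$input_length)
  fit <- train_cnn(net, f$x_train, f$y_train, f$x_val, f$y_val,
                   training_params(seed = 7L), classes = f$classes)
  expect_gte(1 - fit$best_val_error, 0.95)
  acc <- mean(predict(fit, f$x_test, type = "class") == f$y_test)
  expect_gte(acc, 0.95)
  expect_error(
    train_cnn(net, f$x_train, f$y_train, f$x_val, f$y_val,
              training_params(learning_rate = 50, seed = 7L),
              classes = f$classes),
    "diverged")
  expect_error(predict(fit, f$x_test[, -1]), "length")
})

test_that("training on permuted labels collapses to chance accuracy", {
  f <- bench_features(seed = 31)
  set.seed(13)
  y_perm <- sample(f$y_train)
  net <- small_net(f$input_length)
  fit <- train_cnn(net, f$x_train, y_perm, f$x_val, sample(f$y_val),
                   training_params(seed = 3L), classes = f$classes)
  acc <- mean(predict(fit, f$x_test, type = "class") == f$y_test)
  n <- length(f$y_test)
  expect_lt(abs(acc - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / n))
})

test_that("Bayesian optimization finds a 1-D quadratic minimum and keeps its books", {
  space <- list(param_dim("x", "num", -2, 8))
  obj <- function(p) (p$x - 3.2)^2
  res <- bayes_optimize(obj, space, budget = 20L, seed = 44L)
  expect_lt(abs(res$best$x - 3.2), 0.1 * 10)
  expect_equal(nrow(res$trace), 20L)
  expect_equal(sum(!res$trace$failed), 20L)

  # never worse than the median of seeded 20-point random searches
  rs_best <- vapply(1:11, function(s) {
    bayes_optimize(obj, space, budget = 20L, seed = s, method = "random")$best_value
  }, 1)
  expect_lte(res$best_value, median(rs_best))

  one <- bayes_optimize(obj, space, budget = 1L, seed = 2L)
  expect_equal(nrow(one$trace), 1L)
  expect_equal(one$best_value, (one$best$x - 3.2)^2)

  # failures are recorded and skipped; all-fail is an error
  flaky <- function(p) if (p$x < 4) NaN else (p$x - 5)^2
  res2 <- bayes_optimize(flaky, space, budget = 12L, seed = 3L)
  expect_true(any(res2$trace$failed))
  expect_gte(res2$best$x, 4)
  expect_error(bayes_optimize(function(p) NaN, space, budget = 3L, seed = 1L),
               "failed")
})

test_that("mixed-space decoding respects bounds, types and determinism", {
  space <- default_cnn_space()
  obj <- function(p) {
    expect_true(p$section_depth %in% 1:3)
    expect_true(p$filter_size %in% c(3L, 5L, 7L))
    expect_true(p$n_filters >= 4 && p$n_filters <= 16)
    expect_true(p$learning_rate >= 1e-3 && p$learning_rate <= 1e-1)
    expect_true(p$momentum >= 0.5 && p$momentum <= 0.95)
    p$learning_rate
  }
  r1 <- bayes_optimize(obj, space, budget = 8L, seed = 10L)
  r2 <- bayes_optimize(obj, space, budget = 8L, seed = 10L)
  expect_identical(r1$trace, r2$trace)
})
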