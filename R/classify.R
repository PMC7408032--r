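#' Stratified train/validation/test splits
#'
#' Produces `n_repeats` independent stratified random splits at the given
#' ratios. Stratification is by class; in `"subject"` grouping mode every
#' replicate spectrum of a subject receives one assignment (no replicate
#' leakage), in `"spectrum"` mode individual spectra are assigned. Subset
#' sizes per class follow largest-remainder rounding of the ratios.
#' Deterministic under `(seed, repeat index)`.
#'
#' @param dataset A [spectral_dataset()].
#' @param ratios Length-3 numeric summing to 1 (train, validation, test).
#' @param grouping `"subject"` or `"spectrum"`.
#' @param n_repeats Number of independent splits.
#' @param seed Integer seed.
#' @return List of `split_spec` objects, each with `assignment` (factor
#'   `train`/`validation`/`test` aligned to dataset rows), `repeat_index`,
#'   `grouping`, `ratios`, `seed`.
#' @export
make_splits <- function(dataset, ratios = c(0.65, 0.20, 0.15),
                        grouping = c("subject", "spectrum"),
                        n_repeats = 10L, seed = 1L) {
  grouping <- match.arg(grouping)
  stopifnot(length(ratios) == 3L, all(ratios > 0),
            abs(sum(ratios) - 1) < 1e-9, n_repeats >= 1L)
  meta <- dataset$meta
  classes <- unique(meta$group)
  units_by_class <- lapply(classes, function(cl) {
    if (grouping == "subject") unique(meta$subject_id[meta$group == cl])
    else meta$spectrum_id[meta$group == cl]
  })
  names(units_by_class) <- classes
  too_small <- classes[vapply(units_by_class, length, 1L) < 3L]
  if (length(too_small)) {
    stop("class(es) too small to appear in all three subsets: ",
         paste(too_small, collapse = ", "))
  }
  subsets <- c("train", "validation", "test")
  lapply(seq_len(n_repeats), function(r) {
    set.seed(as.integer((as.numeric(seed) * 1009 + r * 9176) %% 2147483629))
    unit_assign <- character(0)
    unit_names <- character(0)
    for (cl in classes) {
      u <- sample(units_by_class[[cl]])
      counts <- largest_remainder(length(u), ratios)
      if (any(counts == 0L)) {
        stop("class '", cl, "' has too few ", grouping,
             "s to appear in all three subsets at these ratios")
      }
      unit_assign <- c(unit_assign, rep(subsets, counts))
      unit_names <- c(unit_names, u)
    }
    names(unit_assign) <- unit_names
    key <- if (grouping == "subject") meta$subject_id else meta$spectrum_id
    assignment <- factor(unname(unit_assign[key]), levels = subsets)
    structure(list(assignment = assignment, repeat_index = r,
                   grouping = grouping, ratios = ratios, seed = seed),
              class = "split_spec")
  })
}

largest_remainder <- function(n, ratios) {
  quota <- ratios * n
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, seq_along(ratios), decreasing = c(TRUE, FALSE),
                   method = "radix")[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' CNN architecture specification
#'
#' A main section of `section_depth` conv blocks (conv + ReLU + max-pool,
#' filter count doubling per block from `n_filters`, capped at 64), two
#' further conv + max-pool blocks, a dropout-regularized dense hidden layer,
#' and a softmax output of size `n_classes`.
#'
#' @param section_depth Conv blocks in the main section (>= 1).
#' @param filter_size Odd kernel length >= 3.
#' @param n_filters Filters in the first block.
#' @param pool_size Max-pool window (and stride).
#' @param dense_units Hidden dense width.
#' @param dropout_rate Dropout fraction in `[0, 1)` on the dense layer.
#' @param n_classes Output classes.
#' @return A `cnn_architecture` list (with the derived per-block `filters`).
#' @export
cnn_architecture <- function(section_depth = 2L, filter_size = 5L,
                             n_filters = 8L, pool_size = 2L,
                             dense_units = 64L, dropout_rate = 0.3,
                             n_classes = 3L) {
  section_depth <- as.integer(section_depth)
  filter_size <- as.integer(filter_size)
  stopifnot(section_depth >= 1L, filter_size >= 3L, filter_size %% 2L == 1L,
            n_filters >= 1L, pool_size >= 2L, dense_units >= 1L,
            dropout_rate >= 0, dropout_rate < 1, n_classes >= 2L)
  n_blocks <- section_depth + 2L   # two extra conv + max-pool blocks
  filters <- pmin(as.integer(n_filters) * 2L^(seq_len(n_blocks) - 1L), 64L)
  structure(list(section_depth = section_depth, filter_size = filter_size,
                 n_filters = as.integer(n_filters), pool_size = as.integer(pool_size),
                 dense_units = as.integer(dense_units),
                 dropout_rate = dropout_rate, n_classes = as.integer(n_classes),
                 filters = filters),
            class = "cnn_architecture")
}

#' Instantiate a network description for a given input length
#'
#' Computes the layer-by-layer output shapes and parameter counts, raising
#' an architecture error naming the offending block if any pooled length
#' reaches 0.
#'
#' @param arch A [cnn_architecture()].
#' @param input_length Number of spectral points fed to the network.
#' @return A `cnn_network`: the architecture, `input_length`, a `layers`
#'   data frame (layer, type, output length, channels, parameters) and
#'   `n_parameters`.
#' @export
build_cnn <- function(arch, input_length) {
  stopifnot(inherits(arch, "cnn_architecture"))
  input_length <- as.integer(input_length)
  len <- input_length
  cin <- 1L
  rows <- list()
  total <- 0L
  for (l in seq_along(arch$filters)) {
    f <- arch$filters[l]
    conv_len <- len - arch$filter_size + 1L
    if (conv_len < 1L) {
      stop("conv block ", l, ": input length ", len,
           " is below the kernel size ", arch$filter_size)
    }
    pool_len <- conv_len %/% arch$pool_size
    if (pool_len < 1L) stop("conv block ", l, ": pooled length reaches 0")
    np <- f * (arch$filter_size * cin + 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("conv%d+relu+pool", l), out_length = pool_len,
      channels = f, parameters = np)
    total <- total + np
    len <- pool_len
    cin <- f
  }
  flat <- len * cin
  np1 <- arch$dense_units * (flat + 1L)
  np2 <- arch$n_classes * (arch$dense_units + 1L)
  rows[[length(rows) + 1L]] <- data.frame(layer = "dense+relu+dropout",
                                          out_length = 1L,
                                          channels = arch$dense_units,
                                          parameters = np1)
  rows[[length(rows) + 1L]] <- data.frame(layer = "dense+softmax",
                                          out_length = 1L,
                                          channels = arch$n_classes,
                                          parameters = np2)
  structure(list(arch = arch, input_length = input_length,
                 layers = do.call(rbind, rows),
                 n_parameters = total + np1 + np2),
            class = "cnn_network")
}

#' Training parameters for the CNN
#'
#' @param learning_rate Initial SGD learning rate (> 0; 0 is allowed and
#'   leaves the weights unchanged).
#' @param momentum SGD momentum in `[0, 1)`.
#' @param l2 L2 regularization strength (>= 0, applied to weights only).
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch budget.
#' @param patience Early-stopping patience in epochs without validation
#'   improvement; best-validation weights are restored.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return A `training_params` list.
#' @export
training_params <- function(learning_rate = 0.02, momentum = 0.9, l2 = 1e-4,
                            batch_size = 32L, max_epochs = 150L,
                            patience = 15L, seed = 1L) {
  stopifnot(learning_rate >= 0, momentum >= 0, momentum < 1, l2 >= 0,
            batch_size >= 1L, max_epochs >= 1L, patience >= 0L)
  structure(list(learning_rate = learning_rate, momentum = momentum, l2 = l2,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "training_params")
}

arch_cpp_list <- function(network) {
  a <- network$arch
  list(filter_size = a$filter_size, filters = as.integer(a$filters),
       pool_size = a$pool_size, dense_units = a$dense_units,
       n_classes = a$n_classes, dropout_rate = a$dropout_rate,
       input_length = network$input_length)
}

#' Train a CNN classifier
#'
#' Stochastic gradient descent with momentum and L2 penalty minimizing
#' multinomial cross-entropy; training stops at `max_epochs` or when the
#' validation classification error has not improved for `patience` epochs,
#' restoring the best-validation weights.
#'
#' @param network A [build_cnn()] result.
#' @param x_train,x_val Numeric matrices (spectra in rows), already
#'   preprocessed and scaled with a train-fitted scaler.
#' @param y_train,y_val Class labels (character or factor); training labels
#'   must cover all classes.
#' @param params A [training_params()].
#' @param classes Fixed class order; defaults to the sorted training labels.
#' @return A `cnn_model`: `network`, `classes`, `weights`, `history` (per
#'   epoch train/validation loss and accuracy), `best_epoch`,
#'   `best_val_error`.
#' @export
train_cnn <- function(network, x_train, y_train, x_val, y_val,
                      params = training_params(),
                      classes = sort(unique(as.character(y_train)))) {
  stopifnot(inherits(network, "cnn_network"))
  y_tr <- match(as.character(y_train), classes) - 1L
  y_va <- match(as.character(y_val), classes) - 1L
  if (anyNA(y_tr) || anyNA(y_va)) stop("labels outside the class list")
  if (length(unique(y_tr)) < length(classes)) {
    stop("training labels do not cover all ", length(classes), " classes")
  }
  if (ncol(x_train) != network$input_length) {
    stop("x_train has ", ncol(x_train), " columns; network expects ",
         network$input_length)
  }
  fit <- .cnn_train_cpp(as.matrix(x_train), as.integer(y_tr),
                        as.matrix(x_val), as.integer(y_va),
                        arch_cpp_list(network), unclass(params))
  structure(list(network = network, classes = classes,
                 weights = fit$weights, history = fit$history,
                 best_epoch = fit$best_epoch,
                 best_val_error = fit$best_val_error,
                 stopped_epoch = fit$stopped_epoch,
                 params = params),
            class = "cnn_model")
}

#' Predict class probabilities / labels from a trained CNN
#'
#' Deterministic (dropout disabled). Ties at the probability argmax resolve
#' to the lowest class index.
#'
#' @param object A `cnn_model`.
#' @param newdata Matrix of spectra (rows), preprocessed and scaled exactly
#'   as the training data.
#' @param type `"prob"` for the probability matrix, `"class"` for labels.
#' @param ... Unused.
#' @return Probability matrix (rows summing to 1) or character labels.
#' @export
predict.cnn_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  probs <- .cnn_predict_cpp(object$weights, arch_cpp_list(object$network),
                            newdata)
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  object$classes[apply(probs, 1, which.max)]
}
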