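#' Pool per-repeat test predictions into one confusion matrix
#'
#' @param predictions List (one element per repeat) of data frames with
#'   columns `truth` and `predicted`, covering each repeat's test rows only.
#' @param classes Fixed class order for rows (truth) and columns (predicted).
#' @return A `confusion_matrix`: integer matrix with `classes` as dimnames.
#' @export
pool_predictions <- function(predictions, classes) {
  if (is.data.frame(predictions)) predictions <- list(predictions)
  if (!length(predictions)) stop("no predictions to pool")
  cm <- matrix(0L, length(classes), length(classes),
               dimnames = list(truth = classes, predicted = classes))
  total <- 0L
  for (p in predictions) {
    bad <- setdiff(unique(c(as.character(p$truth), as.character(p$predicted))),
                   classes)
    if (length(bad)) stop("label outside the class list: ",
                          paste(bad, collapse = ", "))
    t <- table(factor(p$truth, classes), factor(p$predicted, classes))
    cm <- cm + unclass(t)
    total <- total + nrow(p)
  }
  if (total == 0L) stop("no pooled predictions (all inputs empty)")
  storage.mode(cm) <- "integer"
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Per-class one-vs-rest diagnostic metrics
#'
#' For each class, TP/TN/FP/FN from the pooled confusion matrix, with
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP) and
#' PPV = TP/(TP+FP); zero denominators yield `NA` (reported as undefined,
#' never silently 0). Overall accuracy = trace/total.
#'
#' @param cm A confusion matrix (truth rows x predicted columns).
#' @return List: `per_class` data frame (class, TP, TN, FP, FN,
#'   sensitivity, specificity, ppv) and `accuracy`.
#' @export
class_metrics <- function(cm) {
  cm <- unclass(cm)
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  classes <- rownames(cm)
  rows <- lapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    safe <- function(num, den) if (den == 0) NA_real_ else num / den
    data.frame(class = classes[i], TP = tp, TN = tn, FP = fp, FN = fn,
               sensitivity = safe(tp, tp + fn),
               specificity = safe(tn, tn + fp),
               ppv = safe(tp, tp + fp))
  })
  list(per_class = do.call(rbind, rows),
       accuracy = sum(diag(cm)) / total)
}

#' Export a confusion matrix as a chord-diagram edge list
#'
#' One `(source = true class, target = predicted class, weight = count)`
#' edge per nonzero cell, self-edges included.
#'
#' @param cm A confusion matrix.
#' @param path Optional TSV output path.
#' @return Data frame with columns `source`, `target`, `weight`.
#' @export
chord_export <- function(cm, path = NULL) {
  cm <- unclass(cm)
  idx <- which(cm != 0, arr.ind = TRUE)
  edges <- data.frame(source = rownames(cm)[idx[, 1L]],
                      target = colnames(cm)[idx[, 2L]],
                      weight = cm[idx])
  edges <- edges[order(match(edges$source, rownames(cm)),
                       match(edges$target, colnames(cm))), ]
  rownames(edges) <- NULL
  if (!is.null(path)) {
    utils::write.table(edges, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  edges
}
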