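#!/usr/bin/env Rscript
# Per-class diagnostic metrics and chord-diagram edge lists from the pooled
# test predictions written by 05_classify.R.

library(serofir)
classes <- c("nonallergic", "allergic", "tolerized")

for (grouping in c("spectrum", "subject")) {
  f <- sprintf("results/05_predictions_%s.tsv", grouping)
  if (!file.exists(f)) stop("run analysis/05_classify.R first (missing ", f, ")")
  pooled <- read.table(f, sep = "\t", header = TRUE)
  cm <- pool_predictions(split(pooled[, c("truth", "predicted")],
                               pooled$repeat_index), classes)
  m <- class_metrics(cm)
  out <- m$per_class
  out$sensitivity <- round(100 * out$sensitivity, 1)
  out$specificity <- round(100 * out$specificity, 1)
  out$ppv <- round(100 * out$ppv, 1)
  write.table(out, sprintf("results/06_metrics_%s.tsv", grouping),
              sep = "\t", row.names = FALSE, quote = FALSE)
  chord_export(cm, sprintf("results/06_chord_%s.tsv", grouping))
  cat("=== grouping:", grouping, "===\n")
  print(cm)
  print(out, row.names = FALSE)
  cat(sprintf("overall accuracy: %.1f%% (n = %d pooled test spectra)\n\n",
              100 * m$accuracy, sum(cm)))
}
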