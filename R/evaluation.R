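#' Confusion matrix
#'
#' Tallies predictions against truth with rows = predicted class and
#' columns = true class (the orientation used for the published heatmaps).
#'
#' @param true_labels,predicted_labels Equal-length character vectors.
#' @param label_order Class order for rows/columns; every label must appear
#'   in it.
#' @return A `ConfusionMatrix`: list(label_order, counts).
#' @export
confusion <- function(true_labels, predicted_labels, label_order) {
  if (length(true_labels) != length(predicted_labels))
    stopf("label vectors differ in length")
  unknown <- setdiff(unique(c(true_labels, predicted_labels)), label_order)
  if (length(unknown))
    stopf("labels outside label_order: %s", paste(unknown, collapse = ", "))
  counts <- table(factor(predicted_labels, levels = label_order),
                  factor(true_labels, levels = label_order))
  counts <- matrix(as.integer(counts), nrow = length(label_order),
                   dimnames = list(predicted = label_order, true = label_order))
  structure(list(label_order = label_order, counts = counts),
            class = "ConfusionMatrix")
}

#' Per-class and weighted classification metrics
#'
#' One-vs-rest precision, recall and F1 per class, overall accuracy
#' (trace / total), and support-weighted averages, following the standard
#' definitions precision = TP / (TP + FP), recall = TP / (TP + FN),
#' F1 = 2 * precision * recall / (precision + recall). A division by zero
#' yields 0 for that metric with the class flagged; classes with zero true
#' and zero predicted instances are excluded from the weighted means (their
#' support is zero anyway).
#'
#' @param cm A `ConfusionMatrix`.
#' @return A `MetricsReport`: list(per_class data frame with precision,
#'   recall, f1, support and zero-division flags; overall_accuracy;
#'   weighted = c(precision, recall, f1); n).
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "ConfusionMatrix"))
  m <- cm$counts
  total <- sum(m)
  if (total < 1L) stopf("empty confusion matrix")
  tp <- diag(m)
  pred_tot <- rowSums(m)               # predicted counts per class
  true_tot <- colSums(m)               # supports
  precision <- ifelse(pred_tot > 0, tp / pred_tot, 0)
  recall <- ifelse(true_tot > 0, tp / true_tot, 0)
  pr_sum <- precision + recall
  f1 <- ifelse(pr_sum > 0, 2 * precision * recall / pr_sum, 0)
  flagged <- pred_tot == 0 | true_tot == 0 | pr_sum == 0
  per_class <- data.frame(class = cm$label_order,
                          precision = as.numeric(precision),
                          recall = as.numeric(recall),
                          f1 = as.numeric(f1),
                          support = as.integer(true_tot),
                          zero_division = flagged,
                          row.names = NULL, stringsAsFactors = FALSE)
  w <- true_tot / total
  structure(list(per_class = per_class,
                 overall_accuracy = sum(tp) / total,
                 weighted = c(precision = sum(w * precision),
                              recall = sum(w * recall),
                              f1 = sum(w * f1)),
                 n = total),
            class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, digits = 4, ...) {
  cat(sprintf("MetricsReport: n = %d, overall accuracy = %.*f\n",
              x$n, digits, x$overall_accuracy))
  cat(sprintf("  weighted precision %.*f | recall %.*f | F1 %.*f\n",
              digits, x$weighted["precision"], digits, x$weighted["recall"],
              digits, x$weighted["f1"]))
  print(x$per_class, digits = digits)
  invisible(x)
}

#' Serialise evaluation outputs
#'
#' Writes the metrics as JSON and the confusion matrix as TSV (rows =
#' predicted, columns = true).
#'
#' @param report A `MetricsReport`.
#' @param cm A `ConfusionMatrix`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_metrics <- function(report, cm, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  mj <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(list(overall_accuracy = report$overall_accuracy,
                            weighted = as.list(report$weighted),
                            per_class = report$per_class, n = report$n),
                       mj, auto_unbox = TRUE, digits = NA)
  ct <- file.path(out_dir, "confusion_matrix.tsv")
  dt <- data.table::as.data.table(cm$counts, keep.rownames = "predicted")
  data.table::fwrite(dt, ct, sep = "\t", quote = FALSE)
  invisible(c(mj, ct))
}
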