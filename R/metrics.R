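## Confusion matrix and the derived metric suite: accuracy, error = 1 -
## accuracy, per-class one-vs-rest precision/recall, macro averages (means of
## the per-class values), micro averages (pooled one-vs-rest counts), and F1
## as the harmonic mean of macro precision and macro recall. For single-label
## classification the pooled false positives and false negatives coincide, so
## micro precision = micro recall = accuracy — an identity asserted on every
## computed report.

#' Confusion matrix
#'
#' `counts[i, j]` is the number of items with true class `i` predicted as
#' class `j`.
#'
#' @param truth,predicted Equal-length label vectors.
#' @param class_names Ordered class labels (default: sorted union).
#' @return An `edl_confusion` (integer matrix with class dimnames).
#' @export
confusion_matrix <- function(truth, predicted, class_names = NULL) {
  if (length(truth) == 0L || length(truth) != length(predicted))
    stop("truth and predicted must be non-empty and of equal length",
         call. = FALSE)
  if (is.null(class_names)) class_names <- sort(unique(c(truth, predicted)))
  if (!all(truth %in% class_names))
    stop("unknown label in truth", call. = FALSE)
  if (!all(predicted %in% class_names))
    stop("unknown label in predicted", call. = FALSE)
  k <- length(class_names)
  counts <- matrix(0L, k, k, dimnames = list(truth = class_names,
                                             predicted = class_names))
  for (i in seq_along(truth))
    counts[truth[i], predicted[i]] <- counts[truth[i], predicted[i]] + 1L
  structure(counts, class = c("edl_confusion", "matrix"))
}

#' Metric suite from a confusion matrix
#'
#' Per-class one-vs-rest counts are `TP_i = counts[i, i]`,
#' `FP_i = colsum_i - TP_i`, `FN_i = rowsum_i - TP_i`. A per-class precision
#' or recall with a zero denominator is defined as 0 (and the event logged),
#' and still enters the macro means.
#'
#' @param cm An `edl_confusion` with at least one count.
#' @return An `edl_metrics` list: `accuracy`, `error`, `per_class_precision`,
#'   `per_class_recall`, `macro_precision`, `macro_recall`,
#'   `micro_precision`, `micro_recall`, `f1`, and the per-class `tp`, `fp`,
#'   `fn`, `tn` counts.
#' @export
compute_metrics <- function(cm) {
  counts <- unclass(cm)
  total <- sum(counts)
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(counts)
  fp <- colSums(counts) - tp
  fn <- rowSums(counts) - tp
  tn <- total - tp - fp - fn
  safe_div <- function(num, den, what) {
    z <- den == 0
    if (any(z))
      edl_log("zero denominator for ", what, " of class(es) ",
              paste(names(num)[z], collapse = ", "), "; defined as 0",
              level = "WARN")
    out <- numeric(length(num))
    out[!z] <- num[!z] / den[!z]
    names(out) <- names(num)
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  accuracy <- sum(tp) / total
  macro_p <- mean(precision)
  macro_r <- mean(recall)
  micro_p <- sum(tp) / (sum(tp) + sum(fp))
  micro_r <- sum(tp) / (sum(tp) + sum(fn))
  f1 <- if (macro_p + macro_r > 0) 2 * macro_p * macro_r / (macro_p + macro_r)
        else 0
  structure(list(accuracy = accuracy, error = 1 - accuracy,
                 per_class_precision = precision, per_class_recall = recall,
                 macro_precision = macro_p, macro_recall = macro_r,
                 micro_precision = micro_p, micro_recall = micro_r, f1 = f1,
                 tp = tp, fp = fp, fn = fn, tn = tn, n = total),
            class = "edl_metrics")
}

#' @export
print.edl_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f (error %.4f) on %d predictions\n",
              x$accuracy, x$error, x$n))
  cat(sprintf("macro P/R %.4f/%.4f   micro P/R %.4f/%.4f   F1 %.4f\n",
              x$macro_precision, x$macro_recall, x$micro_precision,
              x$micro_recall, x$f1))
  tab <- rbind(precision = x$per_class_precision,
               recall = x$per_class_recall)
  print(round(tab, 4))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param metrics An `edl_metrics`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  payload <- lapply(unclass(metrics), function(v)
    if (length(v) > 1L) as.list(v) else v)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
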