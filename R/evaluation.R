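# Confusion counts, the six-metric suite, unseen-data evaluation of frozen
# pipelines, and hybrid-vs-standalone comparison tables. Class 1 (disease)
# is the positive class throughout.

#' Tally a confusion matrix
#'
#' @param y_true,y_pred Equal-length binary (0/1) label vectors; 1 is the
#'   positive class.
#' @return An object of class `confusion_counts` with fields TP, TN, FP,
#'   FN (summing to the number of records).
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) tf_schema_error("label vectors differ in length")
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) {
    tf_schema_error("labels must be binary 0/1")
  }
  structure(list(
    TP = sum(y_true == 1L & y_pred == 1L),
    TN = sum(y_true == 0L & y_pred == 0L),
    FP = sum(y_true == 0L & y_pred == 1L),
    FN = sum(y_true == 1L & y_pred == 0L)
  ), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion> TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              x$TP, x$TN, x$FP, x$FN, x$TP + x$TN + x$FP + x$FN))
  invisible(x)
}

safe_ratio <- function(num, den, name) {
  if (den == 0) {
    structure(NA_real_, reason = sprintf("%s undefined: zero denominator", name))
  } else {
    num / den
  }
}

#' Compute the six evaluation metrics from confusion counts
#'
#' accuracy = (TP+TN)/n, precision = TP/(TP+FP), recall = sensitivity =
#' TP/(TP+FN), F1 = harmonic mean of precision and recall, specificity =
#' TN/(FP+TN). Ratios with a zero denominator are explicit `NA` markers
#' carrying a reason (never silent zeros).
#'
#' @param counts A [confusion()] result.
#' @return An object of class `metrics_report`: list of the six proportions
#'   plus the counts and an `undefined` reason vector.
#' @export
metrics <- function(counts) {
  with(counts, {
    n <- TP + TN + FP + FN
    if (n == 0) tf_schema_error("no evaluated records")
    precision <- safe_ratio(TP, TP + FP, "precision")
    recall <- safe_ratio(TP, TP + FN, "recall")
    f1 <- if (is.na(precision) || is.na(recall) || (precision + recall) == 0) {
      structure(NA_real_, reason = "f1 undefined: precision + recall is 0 or undefined")
    } else {
      2 * precision * recall / (precision + recall)
    }
    specificity <- safe_ratio(TN, FP + TN, "specificity")
    vals <- list(accuracy = (TP + TN) / n, precision = as.numeric(precision),
                 recall = as.numeric(recall), f1 = as.numeric(f1),
                 sensitivity = as.numeric(recall),
                 specificity = as.numeric(specificity))
    reasons <- c(attr(precision, "reason"), attr(recall, "reason"),
                 attr(f1, "reason"), attr(specificity, "reason"))
    structure(c(vals, list(counts = counts, undefined = reasons)),
              class = "metrics_report")
  })
}

#' @export
print.metrics_report <- function(x, ...) {
  for (m in c("accuracy", "precision", "recall", "f1", "sensitivity", "specificity")) {
    cat(sprintf("  %-12s %s\n", m,
                if (is.na(x[[m]])) "undefined" else sprintf("%.4f", x[[m]])))
  }
  invisible(x)
}

#' Evaluate a frozen pipeline on an unseen dataset
#'
#' Applies the saved pipeline without refitting anything and reports the
#' confusion counts and metric suite.
#'
#' @param pipeline A `trained_pipeline`.
#' @param unseen A labeled [tabular_dataset()] on the pipeline's schema.
#' @return List with `metrics` ([metrics()] report), `counts` and `n`.
#' @export
evaluate_unseen <- function(pipeline, unseen) {
  if (is.null(unseen$labels)) tf_schema_error("evaluation requires labeled data")
  pred <- stats::predict(pipeline, unseen)
  counts <- confusion(unseen$labels, pred$label)
  list(metrics = metrics(counts), counts = counts, n = nrow(unseen$values))
}

metric_names <- c("accuracy", "precision", "recall", "f1", "sensitivity", "specificity")

#' Long-format comparison of hybrid vs standalone results
#'
#' @param results List of entries, each a list with `mode` (e.g. "hybrid" /
#'   "standalone"), `family`, and `metrics` (a [metrics()] report).
#' @return An object of class `comparison_report`: list with `table`
#'   (family x mode x metric long data frame) and `deltas` (per-family
#'   hybrid-minus-standalone differences, when both modes are present).
#' @export
comparison_report <- function(results) {
  if (!length(results)) tf_schema_error("at least one result is required")
  rows <- lapply(results, function(r) {
    data.frame(family = r$family, mode = r$mode, metric = metric_names,
               value = vapply(metric_names, function(m) as.numeric(r$metrics[[m]]),
                              numeric(1)))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  deltas <- NULL
  fams <- unique(tab$family)
  for (f in fams) {
    h <- tab[tab$family == f & tab$mode == "hybrid", ]
    s <- tab[tab$family == f & tab$mode == "standalone", ]
    if (nrow(h) && nrow(s)) {
      d <- data.frame(family = f, metric = metric_names,
                      delta = h$value[match(metric_names, h$metric)] -
                        s$value[match(metric_names, s$metric)])
      deltas <- rbind(deltas, d)
    }
  }
  structure(list(table = tab, deltas = deltas), class = "comparison_report")
}

#' Write a comparison report as TSV
#'
#' @param report A [comparison_report()].
#' @param path Output TSV path (deltas, if any, go to `*_deltas.tsv`).
#' @return `path`, invisibly.
#' @export
write_comparison <- function(report, path) {
  utils::write.table(report$table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(report$deltas)) {
    dpath <- sub("\\.tsv$", "_deltas.tsv", path)
    if (identical(dpath, path)) dpath <- paste0(path, ".deltas")
    utils::write.table(report$deltas, dpath, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write a metrics report to JSON and TSV
#'
#' @param report A [metrics()] result.
#' @param json_path,tsv_path Output paths (either may be NULL to skip).
#' @return Invisibly, the list of written paths.
#' @export
write_metrics <- function(report, json_path = NULL, tsv_path = NULL) {
  vals <- stats::setNames(lapply(metric_names, function(m) report[[m]]), metric_names)
  if (!is.null(json_path)) {
    jsonlite::write_json(c(vals, list(counts = unclass(report$counts))),
                         json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(tsv_path)) {
    df <- data.frame(metric = c(metric_names, "TP", "TN", "FP", "FN"),
                     value = c(unlist(vals, use.names = FALSE),
                               report$counts$TP, report$counts$TN,
                               report$counts$FP, report$counts$FN))
    utils::write.table(df, tsv_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(list(json = json_path, tsv = tsv_path))
}
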