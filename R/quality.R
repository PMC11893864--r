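# Synthetic-data quality evaluation: pairwise-correlation MAE against the
# reference, a within-reference 50:50 baseline, and per-feature
# Kolmogorov-Smirnov / chi-squared distribution tests with a 0.05 cutoff.

# Pearson correlation matrix over predictor columns; constant columns get
# zero correlations (with a warning) instead of NAs.
safe_cor <- function(x) {
  const <- apply(x, 2L, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)))
  R <- suppressWarnings(stats::cor(x))
  if (any(const)) {
    warning(sprintf("constant feature(s) treated as uncorrelated: %s",
                    paste(colnames(x)[const], collapse = ", ")))
    R[const, ] <- 0
    R[, const] <- 0
  }
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  R
}

#' Correlation mean absolute error between two datasets
#'
#' For each feature i, `MAE_i` is the mean over the other features j of
#' `|cor_real(i, j) - cor_synth(i, j)|`, using Pearson correlation on the
#' coded values (nominal codes enter as-is). The average is the arithmetic
#' mean of the per-feature MAEs. Symmetric in its two arguments.
#'
#' @param real,synth [tabular_dataset()]s sharing a schema.
#' @return List with `per_feature` (named numeric) and `average`.
#' @export
correlation_mae <- function(real, synth) {
  if (!identical(schema_names(real$schema), schema_names(synth$schema))) {
    tf_schema_error("datasets must share a schema")
  }
  R1 <- safe_cor(real$values)
  R2 <- safe_cor(synth$values)
  D <- abs(R1 - R2)
  d <- ncol(D)
  per <- (rowSums(D) - diag(D)) / (d - 1)
  list(per_feature = per, average = mean(per))
}

#' Baseline split correlation MAE
#'
#' Randomly splits a dataset 50:50 and returns the average correlation MAE
#' between the two halves: the sampling-noise reference level against which
#' the synthetic-vs-real MAE is judged.
#'
#' @param ds A [tabular_dataset()] with at least 4 rows.
#' @param seed Integer RNG seed.
#' @return Average MAE (scalar).
#' @export
baseline_split_mae <- function(ds, seed) {
  n <- nrow(ds$values)
  if (n < 4L) tf_schema_error("baseline split needs at least 4 rows")
  idx <- with_seed(seed, sample.int(n, floor(n / 2)))
  a <- subset_dataset(ds, idx)
  b <- subset_dataset(ds, setdiff(seq_len(n), idx))
  correlation_mae(a, b)$average
}

# Merge nominal categories whose expected count under the pooled 2 x k
# table falls below 5 into a single pooled category.
merge_small_categories <- function(c1, c2, min_expected = 5) {
  total <- sum(c1) + sum(c2)
  repeat {
    E <- outer(c(sum(c1), sum(c2)), (c1 + c2)) / total
    small <- which(apply(E, 2L, min) < min_expected)
    if (length(small) < 2L || length(c1) <= 2L) break
    pooled1 <- sum(c1[small])
    pooled2 <- sum(c2[small])
    keep <- setdiff(seq_along(c1), small)
    c1 <- c(c1[keep], pooled = pooled1)
    c2 <- c(c2[keep], pooled = pooled2)
  }
  list(c1 = c1, c2 = c2)
}

#' Per-feature distribution tests between real and synthetic data
#'
#' Numeric features get the two-sample Kolmogorov-Smirnov test (asymptotic
#' p-value); nominal features get a chi-squared test on the two frequency
#' tables, after pooling categories with expected count below 5 (no
#' continuity correction, so identical frequency tables give statistic 0
#' and p = 1). A nominal feature observed in a single category in both
#' tables is skipped with a note.
#'
#' @param real,synth [tabular_dataset()]s sharing a schema.
#' @return Data frame with columns `feature`, `test` ("ks" or "chisq"),
#'   `statistic`, `p_value`, `note`.
#' @export
distribution_tests <- function(real, synth) {
  if (!identical(schema_names(real$schema), schema_names(synth$schema))) {
    tf_schema_error("datasets must share a schema")
  }
  schema <- real$schema
  nm <- schema_names(schema)
  kinds <- schema_kinds(schema)
  rows <- lapply(seq_along(nm), function(j) {
    x <- real$values[, j]
    y <- synth$values[, j]
    if (kinds[j] == "numeric") {
      if (length(unique(c(x, y))) == 1L) {
        # both constant and equal: D = 0, p = 1 without invoking ks.test on ties
        return(data.frame(feature = nm[j], test = "ks", statistic = 0,
                          p_value = 1, note = "degenerate"))
      }
      kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
      data.frame(feature = nm[j], test = "ks",
                 statistic = unname(kt$statistic),
                 p_value = min(1, unname(kt$p.value)), note = "")
    } else {
      spec <- schema$predictors[[j]]
      c1 <- as.numeric(table(factor(x, levels = spec$domain)))
      c2 <- as.numeric(table(factor(y, levels = spec$domain)))
      names(c1) <- names(c2) <- as.character(spec$domain)
      observed <- c1 + c2 > 0
      c1 <- c1[observed]
      c2 <- c2[observed]
      if (length(c1) < 2L) {
        return(data.frame(feature = nm[j], test = "chisq", statistic = NA_real_,
                          p_value = NA_real_, note = "skipped: single observed category"))
      }
      m <- merge_small_categories(c1, c2)
      note <- if (length(m$c1) < length(c1)) "pooled small categories" else ""
      ct <- suppressWarnings(stats::chisq.test(rbind(m$c1, m$c2), correct = FALSE))
      data.frame(feature = nm[j], test = "chisq",
                 statistic = unname(ct$statistic),
                 p_value = unname(ct$p.value), note = note)
    }
  })
  do.call(rbind, rows)
}

#' Full synthetic-data quality report
#'
#' Aggregates the correlation MAE analysis, the within-reference baseline
#' split, and the per-feature distribution tests. A feature passes iff its
#' test p-value is at or above the 0.05 significance cutoff.
#'
#' @param real Reference [tabular_dataset()].
#' @param synth Synthetic [tabular_dataset()] with the same schema.
#' @param seed Integer RNG seed (drives the baseline split).
#' @param cutoff Significance cutoff for the pass flags (default 0.05).
#' @return An object of class `quality_report`: list with `correlation`
#'   (per-feature MAE + average), `baseline_average`, `tests` (data frame
#'   with `pass` flags), `cutoff` and `seed`.
#' @export
quality_report <- function(real, synth, seed, cutoff = 0.05) {
  cm <- correlation_mae(real, synth)
  base <- baseline_split_mae(real, seed)
  tests <- distribution_tests(real, synth)
  tests$pass <- ifelse(is.na(tests$p_value), NA, tests$p_value >= cutoff)
  structure(list(correlation = cm, baseline_average = base, tests = tests,
                 cutoff = cutoff, seed = seed),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> avg correlation MAE %.4f (baseline split %.4f)\n",
              x$correlation$average, x$baseline_average))
  passed <- sum(x$tests$pass, na.rm = TRUE)
  total <- sum(!is.na(x$tests$pass))
  cat(sprintf("  distribution tests at cutoff %.2f: %d/%d features pass\n",
              x$cutoff, passed, total))
  invisible(x)
}

#' Write a quality report to JSON and TSV
#'
#' @param report A [quality_report()].
#' @param json_path,tsv_path Output paths (either may be NULL to skip).
#' @return Invisibly, the list of written paths.
#' @export
write_quality_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      correlation_mae = as.list(report$correlation$per_feature),
      correlation_mae_average = report$correlation$average,
      baseline_split_average = report$baseline_average,
      tests = report$tests,
      cutoff = report$cutoff,
      seed = report$seed
    ), json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(tsv_path)) {
    long <- rbind(
      data.frame(feature = names(report$correlation$per_feature),
                 metric = "correlation_mae",
                 value = unname(report$correlation$per_feature), pass = NA),
      data.frame(feature = "(all)", metric = "correlation_mae_average",
                 value = report$correlation$average, pass = NA),
      data.frame(feature = "(all)", metric = "baseline_split_average",
                 value = report$baseline_average, pass = NA),
      data.frame(feature = report$tests$feature,
                 metric = paste0(report$tests$test, "_p"),
                 value = report$tests$p_value, pass = report$tests$pass)
    )
    utils::write.table(long, tsv_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(list(json = json_path, tsv = tsv_path))
}

#' Rebuild a quality report from its JSON form
#'
#' @param json_path Path written by [write_quality_report()].
#' @return A `quality_report` object.
#' @export
read_quality_report <- function(json_path) {
  doc <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  per <- unlist(doc$correlation_mae)
  tests <- as.data.frame(doc$tests)
  structure(list(
    correlation = list(per_feature = per, average = doc$correlation_mae_average),
    baseline_average = doc$baseline_split_average,
    tests = tests, cutoff = doc$cutoff, seed = doc$seed
  ), class = "quality_report")
}
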