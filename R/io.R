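#' Read a CSV table against a schema
#'
#' Columns are matched to the schema by header name, not position, so files
#' with reordered columns load identically. Cells equal to `""`, `"NA"` or
#' `"?"` are read as missing; any other unparseable cell raises a parse
#' error naming its row and column. A validation report (see
#' [validate_dataset()]) is attached as the `"validation"` attribute.
#'
#' @param path CSV file with a header row, comma delimiter, `.` decimal.
#' @param schema A [feature_schema()]; defaults to the bundled heart schema.
#' @param require_labels Require the target column (default TRUE). Set FALSE
#'   for prediction-only input.
#' @param strict Error on columns not declared in the schema (default FALSE:
#'   unknown columns are ignored).
#' @return A [tabular_dataset()].
#' @export
load_dataset <- function(path, schema = heart_schema(), require_labels = TRUE,
                         strict = FALSE) {
  if (!file.exists(path)) tf_io_error("file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  nm <- schema_names(schema)
  missing_cols <- setdiff(nm, names(raw))
  if (length(missing_cols)) {
    tf_schema_error("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  }
  want <- c(nm, schema$target$name)
  unknown <- setdiff(names(raw), want)
  if (strict && length(unknown)) {
    tf_schema_error("unknown column(s) not in schema: %s", paste(unknown, collapse = ", "))
  }
  has_target <- schema$target$name %in% names(raw)
  if (require_labels && !has_target) {
    tf_schema_error("missing required column(s): %s", schema$target$name)
  }
  parse_col <- function(txt, col) {
    txt[txt %in% c("", "NA", "?")] <- NA_character_
    val <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(val) & !is.na(txt))
    if (length(bad)) {
      tf_parse_error("unparseable value '%s' at row %d, column '%s'",
                     txt[bad[1]], bad[1], col)
    }
    val
  }
  values <- vapply(nm, function(col) parse_col(raw[[col]], col),
                   numeric(nrow(raw)))
  if (nrow(raw) == 1L) values <- matrix(values, nrow = 1L, dimnames = list(NULL, nm))
  labels <- if (has_target) {
    lab <- parse_col(raw[[schema$target$name]], schema$target$name)
    as.integer(lab)
  } else NULL
  tabular_dataset(values, labels, schema, validate = TRUE)
}

#' Write a dataset to CSV
#'
#' Numeric values are printed with 17 significant digits so that
#' `load_dataset(write_dataset(ds))` round-trips every value exactly;
#' nominal codes and labels are written as integers.
#'
#' @param ds A [tabular_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  schema <- ds$schema
  kinds <- schema_kinds(schema)
  cols <- lapply(seq_along(kinds), function(j) {
    x <- ds$values[, j]
    out <- character(length(x))
    out[is.na(x)] <- ""
    ok <- !is.na(x)
    out[ok] <- if (kinds[j] == "numeric") sprintf("%.17g", x[ok]) else
      sprintf("%d", as.integer(round(x[ok])))
    out
  })
  names(cols) <- schema_names(schema)
  df <- as.data.frame(cols, check.names = FALSE, optional = TRUE)
  if (!is.null(ds$labels)) df[[schema$target$name]] <- ds$labels
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) tf_io_error("cannot write '%s': %s", path, conditionMessage(ok))
  invisible(path)
}

#' Stratified train/test split
#'
#' Splits rows so that each class contributes `round(class_count *
#' test_fraction)` rows (within 1) to the test part. Deterministic for a
#' fixed seed.
#'
#' @param ds A labeled [tabular_dataset()] with both classes present.
#' @param test_fraction Proportion in (0, 1) assigned to the test part.
#' @param seed Integer RNG seed.
#' @return List with elements `train` and `test` ([tabular_dataset()]s);
#'   the selected row indices are attached as attributes `train_idx` and
#'   `test_idx`.
#' @export
stratified_split <- function(ds, test_fraction, seed) {
  if (is.null(ds$labels)) tf_schema_error("stratified_split needs a labeled dataset")
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    tf_schema_error("test_fraction must lie strictly between 0 and 1")
  }
  classes <- sort(unique(ds$labels))
  if (length(classes) < 2L) tf_schema_error("both classes must be present to stratify")
  test_idx <- with_seed(seed, {
    unlist(lapply(classes, function(cl) {
      rows <- which(ds$labels == cl)
      k <- round(length(rows) * test_fraction)
      k <- max(0L, min(length(rows), k))
      if (k == 0L) integer() else sort(sample(rows, k))
    }))
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(nrow(ds$values)), test_idx)
  out <- list(train = subset_dataset(ds, train_idx),
              test = subset_dataset(ds, test_idx))
  attr(out, "train_idx") <- train_idx
  attr(out, "test_idx") <- test_idx
  out
}
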