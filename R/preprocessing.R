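# Min-max scaling, median/mode imputation and Tukey-fence outlier flags.
# Parameters are fitted on training data and applied frozen elsewhere.

#' Fit min-max normalization parameters
#'
#' Records each predictor's observed minimum and maximum on the fitting
#' data. Constant columns (min = max) are flagged degenerate and later map
#' to 0.
#'
#' @param train A [tabular_dataset()] or numeric matrix.
#' @param clip Clip out-of-range values when applying (default TRUE).
#' @return An object of class `minmax_params`.
#' @export
fit_minmax <- function(train, clip = TRUE) {
  x <- if (inherits(train, "tabular_dataset")) train$values else as.matrix(train)
  if (nrow(x) < 1L) tf_schema_error("cannot fit normalization on an empty dataset")
  mins <- apply(x, 2L, min, na.rm = TRUE)
  maxs <- apply(x, 2L, max, na.rm = TRUE)
  if (any(!is.finite(mins)) || any(!is.finite(maxs))) {
    tf_schema_error("normalization fit found a column with no observed values")
  }
  structure(list(feature = colnames(x), min = mins, max = maxs,
                 degenerate = mins == maxs, clip = clip),
            class = "minmax_params")
}

#' Apply min-max normalization
#'
#' Maps each value x to (x - min) / (max - min) using the fitted extremes,
#' so the fitted minimum lands on 0 and the fitted maximum on 1. Unseen
#' out-of-range values are clipped into \[0, 1\] (when the params say so);
#' degenerate features map to 0.
#'
#' @param data A [tabular_dataset()] or numeric matrix with the fitted columns.
#' @param params A [fit_minmax()] result.
#' @return Numeric matrix of scaled values in \[0, 1\].
#' @export
apply_minmax <- function(data, params) {
  x <- if (inherits(data, "tabular_dataset")) data$values else as.matrix(data)
  if (!is.null(params$feature) && !is.null(colnames(x))) {
    if (!setequal(colnames(x), params$feature)) {
      tf_schema_error("columns do not match the fitted normalization parameters")
    }
    x <- x[, params$feature, drop = FALSE]
  } else if (ncol(x) != length(params$min)) {
    tf_schema_error("column count does not match the fitted normalization parameters")
  }
  rng <- params$max - params$min
  out <- sweep(x, 2L, params$min, "-")
  safe <- ifelse(params$degenerate, 1, rng)
  out <- sweep(out, 2L, safe, "/")
  out[, params$degenerate] <- 0
  if (isTRUE(params$clip)) out <- pmin(pmax(out, 0), 1)
  out
}

#' Invert min-max normalization
#'
#' Recovers original values from scaled ones for non-degenerate features
#' (degenerate columns return the fitted constant).
#'
#' @param scaled Matrix produced by [apply_minmax()].
#' @param params The same [fit_minmax()] parameters.
#' @return Numeric matrix on the original scale.
#' @export
invert_minmax <- function(scaled, params) {
  rng <- ifelse(params$degenerate, 0, params$max - params$min)
  out <- sweep(as.matrix(scaled), 2L, rng, "*")
  sweep(out, 2L, params$min, "+")
}

#' Fit imputation parameters
#'
#' Numeric features impute with the training median, nominal features with
#' the training mode (ties broken toward the smaller code).
#'
#' @param train A [tabular_dataset()].
#' @return An object of class `impute_params`.
#' @export
fit_impute <- function(train) {
  schema <- train$schema
  kinds <- schema_kinds(schema)
  vals <- lapply(seq_along(kinds), function(j) {
    x <- train$values[, j]
    x <- x[!is.na(x)]
    if (!length(x)) tf_schema_error("feature '%s' is entirely missing; cannot impute",
                                    schema_names(schema)[j])
    if (kinds[j] == "numeric") {
      stats::median(x)
    } else {
      tab <- table(x)
      as.numeric(names(tab)[which.max(tab)])  # which.max takes the first (smallest code) on ties
    }
  })
  names(vals) <- schema_names(schema)
  structure(list(values = vals), class = "impute_params")
}

#' Impute missing cells
#'
#' Replaces every `NA` with the fitted (or self-fitted) median/mode. The
#' number of imputed cells per feature is attached as attribute
#' `"imputed_counts"`. Idempotent: a dataset without missing cells is
#' returned unchanged.
#'
#' @param ds A [tabular_dataset()].
#' @param params Optional [fit_impute()] result; when NULL, parameters are
#'   fitted on `ds` itself.
#' @return The imputed [tabular_dataset()].
#' @export
impute_missing <- function(ds, params = NULL) {
  params <- params %||% fit_impute(ds)
  x <- ds$values
  counts <- integer(ncol(x))
  names(counts) <- colnames(x)
  for (j in seq_len(ncol(x))) {
    na <- is.na(x[, j])
    counts[j] <- sum(na)
    if (counts[j]) x[na, j] <- params$values[[colnames(x)[j]]]
  }
  out <- tabular_dataset(x, ds$labels, ds$schema, validate = FALSE)
  attr(out, "imputed_counts") <- counts
  out
}

#' Flag outliers with the Tukey 1.5 IQR fence
#'
#' A numeric cell is flagged iff it falls outside
#' \[Q1 - 1.5 IQR, Q3 + 1.5 IQR\], with quartiles computed by linear
#' interpolation between order statistics (`stats::quantile` type 7).
#' Nominal cells are never flagged. Rows are only reported, never dropped.
#'
#' @param ds A [tabular_dataset()].
#' @return Logical matrix of the same shape as `ds$values`.
#' @export
flag_outliers <- function(ds) {
  kinds <- schema_kinds(ds$schema)
  mask <- matrix(FALSE, nrow(ds$values), ncol(ds$values),
                 dimnames = dimnames(ds$values))
  for (j in which(kinds == "numeric")) {
    x <- ds$values[, j]
    q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE, type = 7)
    iqr <- q[2] - q[1]
    mask[, j] <- !is.na(x) & (x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr)
  }
  mask
}
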