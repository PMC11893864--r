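#' Declare a single feature
#'
#' A feature is either `numeric` with a closed interval domain or `nominal`
#' with a finite set of integer codes. The bundled heart-disease schema uses
#' integer codes exactly as the clinical coding convention defines them
#' (e.g. chest-pain type `cp` in 0..3).
#'
#' @param name Feature name (non-empty string, unique within a schema).
#' @param kind `"numeric"` or `"nominal"`.
#' @param domain For numeric features a length-2 vector `c(lower, upper)`
#'   with `lower < upper`; for nominal features a non-empty integer code set.
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(name, kind = c("numeric", "nominal"), domain) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    tf_schema_error("feature name must be a non-empty string")
  }
  if (kind == "numeric") {
    domain <- as.numeric(domain)
    if (length(domain) != 2L || !is.finite(domain[1]) || !is.finite(domain[2]) ||
        domain[1] >= domain[2]) {
      tf_schema_error("numeric domain of '%s' must be c(lower, upper) with lower < upper", name)
    }
  } else {
    domain <- as.integer(domain)
    if (length(domain) == 0L || anyNA(domain) || anyDuplicated(domain)) {
      tf_schema_error("nominal domain of '%s' must be a non-empty set of unique integer codes", name)
    }
    domain <- sort(domain)
  }
  structure(list(name = name, kind = kind, domain = domain), class = "feature_spec")
}

#' Assemble a dataset schema
#'
#' @param predictors List of [feature_spec()] objects (the model inputs, in
#'   canonical column order).
#' @param target A nominal [feature_spec()] with exactly two codes; code `1`
#'   is the positive (disease) class throughout the package.
#' @return An object of class `feature_schema`.
#' @export
feature_schema <- function(predictors, target) {
  if (!length(predictors)) tf_schema_error("schema needs at least one predictor")
  if (!all(vapply(predictors, inherits, logical(1), "feature_spec"))) {
    tf_schema_error("predictors must all be feature_spec objects")
  }
  nm <- vapply(predictors, `[[`, character(1), "name")
  if (anyDuplicated(nm)) tf_schema_error("duplicate predictor names: %s",
                                         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  if (!inherits(target, "feature_spec") || target$kind != "nominal" ||
      length(target$domain) != 2L) {
    tf_schema_error("target must be a nominal feature_spec with exactly two codes")
  }
  structure(list(predictors = predictors, target = target), class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat(sprintf("<feature_schema> %d predictors (%d numeric, %d nominal), target '%s' codes {%s}\n",
              length(x$predictors), sum(schema_kinds(x) == "numeric"),
              sum(schema_kinds(x) == "nominal"), x$target$name,
              paste(x$target$domain, collapse = ",")))
  invisible(x)
}

schema_names <- function(schema) vapply(schema$predictors, `[[`, character(1), "name")
schema_kinds <- function(schema) vapply(schema$predictors, `[[`, character(1), "kind")

#' Names of numeric / nominal predictors
#' @param schema A [feature_schema()].
#' @return Character vector of feature names.
#' @export
numeric_features <- function(schema) schema_names(schema)[schema_kinds(schema) == "numeric"]

#' @rdname numeric_features
#' @export
nominal_features <- function(schema) schema_names(schema)[schema_kinds(schema) == "nominal"]

#' The bundled 13-predictor heart-disease schema
#'
#' Loads the versioned schema document shipped with the package. It mirrors
#' the standard UCI/Kaggle heart-disease coding: 5 numeric predictors (age,
#' trestbps, chol, thalach, oldpeak) and 8 nominal ones (sex, cp, fbs,
#' restecg, exang, slope, ca, thal), with binary `target` (1 = heart disease).
#' The thalassemia code `thal = 0` is schema-valid but treated by the
#' validator as a missingness indicator.
#'
#' @param path Optional path to an alternative schema YAML document.
#' @return A [feature_schema()].
#' @export
heart_schema <- function(path = NULL) {
  path <- path %||% system.file("extdata", "heart_schema.yaml", package = "tabfuse")
  if (!nzchar(path) || !file.exists(path)) tf_io_error("schema file not found: %s", path)
  doc <- yaml::read_yaml(path)
  preds <- lapply(doc$predictors, function(p) {
    feature_spec(p$name, p$kind, if (p$kind == "numeric") unlist(p$range) else unlist(p$codes))
  })
  target <- feature_spec(doc$target$name, "nominal", unlist(doc$target$codes))
  schema <- feature_schema(preds, target)
  attr(schema, "version") <- doc$version
  attr(schema, "missing_codes") <- doc$missing_codes
  schema
}

#' Construct a tabular dataset bound to a schema
#'
#' @param values Numeric matrix or data frame, one column per schema
#'   predictor (matched by name when column names are present, otherwise by
#'   position).
#' @param labels Optional vector of target codes (length `nrow(values)`).
#' @param schema A [feature_schema()].
#' @param validate Run domain validation and attach the report (default TRUE).
#' @return An object of class `tabular_dataset` with fields `values`
#'   (numeric matrix), `labels` and `schema`.
#' @export
tabular_dataset <- function(values, labels = NULL, schema, validate = TRUE) {
  nm <- schema_names(schema)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L) tf_schema_error("dataset must contain at least one row")
  if (!is.null(colnames(values))) {
    miss <- setdiff(nm, colnames(values))
    if (length(miss)) tf_schema_error("missing predictor column(s): %s", paste(miss, collapse = ", "))
    values <- values[, nm, drop = FALSE]
  } else {
    if (ncol(values) != length(nm)) {
      tf_schema_error("expected %d predictor columns, got %d", length(nm), ncol(values))
    }
    colnames(values) <- nm
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(values)) tf_schema_error("labels length must match row count")
    bad <- !is.na(labels) & !(labels %in% schema$target$domain)
    if (any(bad)) tf_schema_error("label(s) outside target domain at row(s): %s",
                                  paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  ds <- structure(list(values = values, labels = labels, schema = schema),
                  class = "tabular_dataset")
  if (validate) attr(ds, "validation") <- validate_dataset(ds)
  ds
}

#' @export
print.tabular_dataset <- function(x, ...) {
  cat(sprintf("<tabular_dataset> %d rows x %d predictors%s\n", nrow(x$values),
              ncol(x$values), if (is.null(x$labels)) " (unlabeled)" else
                sprintf(", labels: %s", paste(sprintf("%d=%d", as.integer(names(table(x$labels))),
                                                      as.integer(table(x$labels))), collapse = " "))))
  invisible(x)
}

#' @export
dim.tabular_dataset <- function(x) dim(x$values)

#' Validate every cell against its feature domain
#'
#' Flags exactly the cells outside their feature's declared domain. `NA`
#' cells are reported separately as missing (they are the imputation
#' module's concern, not domain violations), as are schema-declared
#' missingness indicator codes such as `thal = 0`.
#'
#' @param ds A [tabular_dataset()].
#' @return A data frame with columns `row`, `column`, `value`, `reason`
#'   (`"out_of_domain"`, `"missing"` or `"missing_code"`).
#' @export
validate_dataset <- function(ds) {
  schema <- ds$schema
  out <- list()
  miss_codes <- attr(schema, "missing_codes")
  for (spec in schema$predictors) {
    x <- ds$values[, spec$name]
    na_rows <- which(is.na(x))
    if (length(na_rows)) {
      out[[length(out) + 1L]] <- data.frame(row = na_rows, column = spec$name,
                                            value = NA_real_, reason = "missing")
    }
    ok <- if (spec$kind == "numeric") {
      x >= spec$domain[1] & x <= spec$domain[2]
    } else {
      x %in% spec$domain & x == round(x)
    }
    bad <- which(!is.na(x) & !ok)
    if (length(bad)) {
      out[[length(out) + 1L]] <- data.frame(row = bad, column = spec$name,
                                            value = x[bad], reason = "out_of_domain")
    }
    mc <- miss_codes[[spec$name]]
    if (!is.null(mc)) {
      ind <- which(!is.na(x) & x %in% mc)
      if (length(ind)) {
        out[[length(out) + 1L]] <- data.frame(row = ind, column = spec$name,
                                              value = x[ind], reason = "missing_code")
      }
    }
  }
  if (!length(out)) {
    data.frame(row = integer(), column = character(), value = numeric(),
               reason = character())
  } else {
    res <- do.call(rbind, out)
    res[order(res$row, res$column), , drop = FALSE]
  }
}

# Row subset preserving class and schema.
subset_dataset <- function(ds, idx) {
  tabular_dataset(ds$values[idx, , drop = FALSE],
                  if (is.null(ds$labels)) NULL else ds$labels[idx],
                  ds$schema, validate = FALSE)
}
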