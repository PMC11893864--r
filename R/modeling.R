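# Feature fusion, tuned classifier families, stratified k-fold grid search,
# and the frozen end-to-end pipeline bundle.

#' Fuse tabular and deep feature blocks
#'
#' Column-wise concatenation with the tabular block first. Block membership
#' is retained (attribute `"blocks"`) for ablation and explanation.
#'
#' @param tab_scaled Numeric matrix `n x d_tab` of scaled tabular features.
#' @param deep Numeric matrix `n x d_cnn` of backbone features, or NULL for
#'   standalone (tabular-only) mode.
#' @return Numeric matrix `n x (d_tab + d_cnn)` with column names prefixed
#'   `tab_` / `deep_`.
#' @export
fuse <- function(tab_scaled, deep = NULL) {
  tab <- as.matrix(tab_scaled)
  colnames(tab) <- paste0("tab_", colnames(tab) %||% seq_len(ncol(tab)))
  if (is.null(deep) || NCOL(deep) == 0L) {
    attr(tab, "blocks") <- rep("tabular", ncol(tab))
    return(tab)
  }
  deep <- as.matrix(deep)
  if (nrow(deep) != nrow(tab)) tf_schema_error("tabular and deep blocks disagree on row count")
  colnames(deep) <- paste0("deep_", seq_len(ncol(deep)))
  out <- cbind(tab, deep)
  attr(out, "blocks") <- c(rep("tabular", ncol(tab)), rep("deep", ncol(deep)))
  out
}

#' Default hyperparameter grids for the six classifier families
#'
#' Compact search spaces for the hybrid classifiers; each family's commonly
#' reported optimum for this problem is reachable inside its grid. Grid
#' order is the declared tie-breaking order. `max_depth = NA` means
#' unlimited depth.
#'
#' @return Named list of grids (family -> named list of candidate vectors).
#' @export
default_grids <- function() {
  list(
    random_forest = list(max_depth = c(NA, 5, 10), n_estimators = c(50, 100, 200)),
    logistic_regression = list(C = c(0.1, 1, 10), solver = "liblinear"),
    decision_tree = list(max_depth = c(NA, 5, 10), min_samples_split = c(2, 5)),
    knn = list(n_neighbors = c(3, 5, 7), weights = c("uniform", "distance")),
    gradient_boosting = list(learning_rate = c(0.05, 0.1, 0.2), n_estimators = c(50, 100)),
    svm = list(C = c(0.1, 1, 10), kernel = c("linear", "rbf"))
  )
}

#' Declare a classifier family and its search grid
#'
#' @param family One of `"random_forest"`, `"logistic_regression"`,
#'   `"decision_tree"`, `"knn"`, `"gradient_boosting"`, `"svm"`.
#' @param grid Named list of candidate values; defaults to the family's
#'   entry in [default_grids()].
#' @param folds Cross-validation fold count (default 5).
#' @param scoring Scoring metric; only `"accuracy"` is provided.
#' @return An object of class `hybrid_model_spec`.
#' @export
hybrid_model_spec <- function(family, grid = NULL, folds = 5L, scoring = "accuracy") {
  families <- names(default_grids())
  if (!family %in% families) {
    tf_schema_error("unknown family '%s'; choose one of: %s", family,
                    paste(families, collapse = ", "))
  }
  if (folds < 2L) tf_schema_error("fold count must be at least 2")
  if (scoring != "accuracy") tf_schema_error("only accuracy scoring is provided")
  grid <- grid %||% default_grids()[[family]]
  if (!length(grid)) tf_schema_error("grid must be non-empty")
  structure(list(family = family, grid = grid, folds = as.integer(folds),
                 scoring = scoring),
            class = "hybrid_model_spec")
}

# Cross product of the grid in declared order: the first parameter varies
# slowest, so candidate 1 is the first-declared value of every parameter.
cross_grid <- function(grid) {
  cands <- list(list())
  for (p in names(grid)) {
    cands <- unlist(lapply(cands, function(cand) {
      lapply(grid[[p]], function(v) c(cand, stats::setNames(list(v), p)))
    }), recursive = FALSE)
  }
  # reorder: first parameter slowest
  if (length(grid) > 1L) {
    keys <- vapply(cands, function(cand) {
      paste(vapply(names(grid), function(p) {
        as.character(match(cand[[p]], grid[[p]]))
      }, character(1)), collapse = ".")
    }, character(1))
    cands <- cands[order(keys)]
  }
  cands
}

# Stratified fold assignment: within each class, shuffled rows are dealt
# round-robin across folds.
make_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      rows <- which(labels == cl)
      rows <- rows[sample.int(length(rows))]
      fold[rows] <- rep_len(seq_len(k), length(rows))
    }
  })
  fold
}

# ---- classifier family registry ------------------------------------------

fit_classifier <- function(family, x, y, params, seed) {
  yf <- factor(y, levels = c(0L, 1L))
  model <- switch(family,
    random_forest = ranger::ranger(
      x = x, y = yf, num.trees = params$n_estimators,
      max.depth = if (is.na(params$max_depth)) 0 else params$max_depth,
      probability = TRUE, seed = seed, num.threads = 1L),
    logistic_regression = glmnet::glmnet(
      x, yf, family = "binomial", alpha = 0, standardize = FALSE,
      lambda = 1 / (params$C * nrow(x))),
    decision_tree = {
      df <- data.frame(.y = yf, x, check.names = TRUE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(
                     maxdepth = if (is.na(params$max_depth)) 30L else params$max_depth,
                     minsplit = params$min_samples_split, cp = 0, xval = 0))
    },
    knn = list(x = x, y = as.integer(as.character(yf)),
               k = params$n_neighbors, weights = params$weights),
    gradient_boosting = with_seed(seed, xgboost::xgboost(
      x, yf, objective = "binary:logistic",
      nrounds = params$n_estimators, learning_rate = params$learning_rate,
      max_depth = 3L, nthreads = 1L, verbosity = 0)),
    svm = e1071::svm(x = x, y = yf, kernel = if (params$kernel == "rbf") "radial" else params$kernel,
                     cost = params$C, scale = FALSE),
    tf_schema_error("unknown family '%s'", family)
  )
  structure(list(family = family, params = params, fit = model, seed = seed),
            class = "tabfuse_classifier")
}

# Distance-weighted kNN scores: fraction (uniform) or inverse-distance
# weighted fraction of class-1 neighbors; exact matches dominate.
knn_scores <- function(model, x) {
  xt <- model$x
  d2 <- outer(rowSums(x^2), rowSums(xt^2), "+") - 2 * tcrossprod(x, xt)
  d2[d2 < 0] <- 0
  vapply(seq_len(nrow(x)), function(i) {
    ord <- order(d2[i, ], seq_len(ncol(d2)))[seq_len(model$k)]
    if (model$weights == "uniform") {
      mean(model$y[ord] == 1L)
    } else {
      dd <- sqrt(d2[i, ord])
      if (any(dd == 0)) return(mean(model$y[ord[dd == 0]] == 1L))
      w <- 1 / dd
      sum(w * (model$y[ord] == 1L)) / sum(w)
    }
  }, numeric(1))
}

predict_classifier <- function(model, x) {
  x <- as.matrix(x)
  score <- switch(model$family,
    random_forest = {
      p <- stats::predict(model$fit, data = x, num.threads = 1L)$predictions
      p[, "1"]
    },
    logistic_regression = as.numeric(stats::predict(model$fit, newx = x, type = "response")),
    decision_tree = {
      df <- data.frame(x, check.names = TRUE)
      p <- stats::predict(model$fit, newdata = df, type = "prob")
      if ("1" %in% colnames(p)) p[, "1"] else numeric(nrow(x))
    },
    knn = knn_scores(model$fit, x),
    gradient_boosting = as.numeric(stats::predict(model$fit, x)),
    svm = {
      pred <- stats::predict(model$fit, x, decision.values = TRUE)
      dv <- attr(pred, "decision.values")
      oriented <- if (identical(colnames(dv), "1/0")) dv[, 1] else -dv[, 1]
      stats::plogis(oriented)
    },
    tf_schema_error("unknown family '%s'", model$family)
  )
  score <- as.numeric(score)
  list(label = as.integer(score > 0.5), score = score)
}

# ---- grid-search cross-validation ----------------------------------------

format_params <- function(params) {
  paste(vapply(names(params), function(p) {
    v <- params[[p]]
    sprintf("%s=%s", p, if (is.na(v)) "None" else as.character(v))
  }, character(1)), collapse = ", ")
}

#' Tune and train a classifier by stratified k-fold grid search
#'
#' Exhaustively scores every grid candidate with stratified k-fold
#' cross-validation (one seeded fold assignment shared by all candidates,
#' so scores are paired), selects the candidate with the best mean accuracy
#' (ties: first in declared grid order), and refits it on all rows.
#'
#' @param fused Feature matrix from [fuse()].
#' @param labels Binary label vector (0/1), both classes present.
#' @param spec A [hybrid_model_spec()].
#' @param seed Integer seed for fold assignment and stochastic learners.
#' @return An object of class `tuned_model`: list with `family`,
#'   `best_params`, `cv_score`, `cv_table` (candidate x fold scores),
#'   `model` (refit classifier) and `seed`.
#' @export
tune_and_train <- function(fused, labels, spec, seed = 1L) {
  x <- as.matrix(fused)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) tf_schema_error("both classes must be present")
  k <- spec$folds
  if (min(table(labels)) < k) {
    tf_schema_error("a class has fewer rows than the %d folds; reduce the fold count", k)
  }
  fold <- make_folds(labels, k, seed)
  if (any(vapply(seq_len(k), function(f) length(unique(labels[fold == f])) < 2L, logical(1)))) {
    tf_schema_error("a fold lost a class; reduce the fold count")
  }
  candidates <- cross_grid(spec$grid)
  cv_rows <- list()
  means <- numeric(length(candidates))
  for (ci in seq_along(candidates)) {
    params <- candidates[[ci]]
    scores <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      m <- fit_classifier(spec$family, x[tr, , drop = FALSE], labels[tr], params, seed)
      pred <- predict_classifier(m, x[!tr, , drop = FALSE])
      mean(pred$label == labels[!tr])
    }, numeric(1))
    means[ci] <- mean(scores)
    cv_rows[[ci]] <- data.frame(candidate = ci, params = format_params(params),
                                fold = seq_len(k), score = scores)
  }
  best <- which.max(means)  # first maximum: declared-order tie-break
  final <- fit_classifier(spec$family, x, labels, candidates[[best]], seed)
  structure(list(family = spec$family, spec = spec,
                 best_params = candidates[[best]],
                 cv_score = means[best],
                 cv_table = do.call(rbind, cv_rows),
                 model = final, seed = as.integer(seed)),
            class = "tuned_model")
}

# ---- end-to-end pipeline --------------------------------------------------

#' Train the full hybrid (or standalone) pipeline
#'
#' Runs the complete training path on a labeled dataset: imputation and
#' min-max normalization fitted on the training rows, correlation-clustered
#' feature ordering, grid embedding and upscaling, frozen-backbone feature
#' extraction, fusion with the tabular block, and grid-search
#' cross-validated classifier tuning. The result is a frozen bundle that
#' can be applied to unseen data without refitting anything.
#'
#' `stats_data` optionally supplies a different dataset for fitting the
#' normalization and feature ordering ("paper mode": fitting them on the
#' full dataset rather than the training rows only).
#'
#' @param ds Labeled training [tabular_dataset()].
#' @param spec A [hybrid_model_spec()].
#' @param backbone A `backbone_spec`, or NULL for standalone mode (no deep
#'   block).
#' @param seed Integer seed driving fold assignment and stochastic learners.
#' @param target_side Image side in pixels; defaults to the backbone's
#'   expected side.
#' @param stats_data Optional [tabular_dataset()] on which normalization
#'   and feature order are fitted (default: `ds` itself).
#' @return An object of class `trained_pipeline`.
#' @export
train_pipeline <- function(ds, spec, backbone = NULL, seed = 1L,
                           target_side = NULL, stats_data = NULL) {
  if (is.null(ds$labels)) tf_schema_error("training requires a labeled dataset")
  stats_ds <- stats_data %||% ds
  impute_params <- fit_impute(stats_ds)
  ds_imp <- impute_missing(ds, impute_params)
  stats_imp <- impute_missing(stats_ds, impute_params)
  norm <- fit_minmax(stats_imp)
  scaled_stats <- apply_minmax(stats_imp, norm)
  order <- compute_feature_order(scaled_stats, schema = ds$schema)
  scaled <- apply_minmax(ds_imp, norm)
  deep <- NULL
  if (!is.null(backbone)) {
    side <- as.integer(target_side %||% backbone$input_side)
    images <- convert_dataset(scaled, order, side)
    deep <- extract_features(images, backbone)
  }
  fused <- fuse(scaled, deep)
  tuned <- tune_and_train(fused, ds$labels, spec, seed)
  structure(list(version = 1L, schema = ds$schema,
                 schema_fingerprint = paste(schema_names(ds$schema), collapse = "|"),
                 impute_params = impute_params, norm_params = norm,
                 feature_order = order, backbone = backbone,
                 target_side = if (is.null(backbone)) NA_integer_ else
                   as.integer(target_side %||% backbone$input_side),
                 model = tuned, family = tuned$family,
                 best_params = tuned$best_params, cv_score = tuned$cv_score,
                 cv_table = tuned$cv_table,
                 paper_mode = !is.null(stats_data), seed = as.integer(seed)),
            class = "trained_pipeline")
}

#' Train a standalone (tabular-only) pipeline
#'
#' The hybrid path with the deep block removed (`d_cnn = 0`): identical
#' preprocessing, fold machinery and grids, so hybrid and standalone scores
#' are directly comparable.
#'
#' @inheritParams train_pipeline
#' @return A `trained_pipeline` with no backbone.
#' @export
train_standalone <- function(ds, spec, seed = 1L, stats_data = NULL) {
  train_pipeline(ds, spec, backbone = NULL, seed = seed, stats_data = stats_data)
}

#' @export
print.trained_pipeline <- function(x, ...) {
  cat(sprintf("<trained_pipeline> %s%s | best: %s | CV accuracy %.4f\n",
              x$family, if (is.null(x$backbone)) " (standalone)" else
                sprintf(" + %s backbone (%d features)", x$backbone$backend,
                        x$backbone$output_dim),
              format_params(x$best_params), x$cv_score))
  invisible(x)
}

# Shared raw-record -> fused-features path for prediction and explanation.
pipeline_features <- function(pipeline, ds) {
  ds_imp <- impute_missing(ds, pipeline$impute_params)
  scaled <- apply_minmax(ds_imp, pipeline$norm_params)
  deep <- NULL
  if (!is.null(pipeline$backbone)) {
    images <- convert_dataset(scaled, pipeline$feature_order, pipeline$target_side)
    deep <- extract_features(images, pipeline$backbone)
  }
  fuse(scaled, deep)
}

#' Predict with a frozen pipeline
#'
#' Applies, in order: stored imputation, frozen min-max normalization
#' (clipping unseen out-of-range values), the fitted feature order, grid
#' embedding, upscaling, the frozen backbone, fusion, and the tuned
#' classifier. Deterministic given the bundle.
#'
#' @param object A `trained_pipeline`.
#' @param newdata A [tabular_dataset()] (labels not required) or a numeric
#'   matrix/data frame with the schema's predictor columns.
#' @param ... Ignored.
#' @return A data frame with columns `label` (0/1) and `score` (class-1
#'   score in \[0, 1\]).
#' @export
predict.trained_pipeline <- function(object, newdata, ...) {
  ds <- if (inherits(newdata, "tabular_dataset")) newdata else
    tabular_dataset(newdata, NULL, object$schema, validate = FALSE)
  if (!identical(paste(schema_names(ds$schema), collapse = "|"),
                 object$schema_fingerprint)) {
    tf_schema_error("dataset schema does not match the pipeline's schema fingerprint")
  }
  fused <- pipeline_features(object, ds)
  pred <- predict_classifier(object$model$model, fused)
  data.frame(label = pred$label, score = pred$score)
}

#' Save / load a trained pipeline bundle
#'
#' The bundle is a single self-contained file: feature order, normalization
#' and imputation parameters, backbone spec (with toy weights), the tuned
#' classifier and its CV table.
#'
#' @param pipeline A `trained_pipeline`.
#' @param path Bundle file path.
#' @return `save_pipeline`: `path`, invisibly. `load_pipeline`: the
#'   `trained_pipeline`.
#' @export
save_pipeline <- function(pipeline, path) {
  saveRDS(pipeline, path)
  invisible(path)
}

#' @rdname save_pipeline
#' @export
load_pipeline <- function(path) {
  if (!file.exists(path)) tf_io_error("pipeline bundle not found: %s", path)
  obj <- readRDS(path)
  if (!inherits(obj, "trained_pipeline")) tf_io_error("'%s' is not a pipeline bundle", path)
  obj
}

#' Export a CV table as TSV
#'
#' @param pipeline A `trained_pipeline` (or `tuned_model`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cv_table <- function(pipeline, path) {
  tab <- pipeline$cv_table
  tab <- cbind(family = pipeline$family, tab)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
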