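# Shapley-value attributions for black-box models: an exact enumerator over
# all feature coalitions and a seeded permutation-sampling estimator.
#
# The value of a coalition S is the interventional expectation over a
# finite background set: features in S take the explained record's values,
# the rest are replaced by each background row's values, and the model
# outputs are averaged. Both estimators share that value function, so the
# sampled estimator converges to the exact one.

# Evaluate v(S) for a list of coalitions (logical matrix n_coal x M).
coalition_values <- function(model_fn, x, background, coalitions, chunk_rows = 65536L) {
  B <- nrow(background)
  M <- ncol(background)
  n_coal <- nrow(coalitions)
  v <- numeric(n_coal)
  per <- max(1L, chunk_rows %/% B)
  for (start in seq(1L, n_coal, by = per)) {
    idx <- start:min(n_coal, start + per - 1L)
    m <- length(idx)
    X <- background[rep(seq_len(B), times = m), , drop = FALSE]
    sel <- coalitions[rep(idx, each = B), , drop = FALSE]
    xm <- matrix(x, nrow(X), M, byrow = TRUE)
    X[sel] <- xm[sel]
    f <- model_fn(X)
    v[idx] <- colMeans(matrix(f, B, m))
  }
  v
}

new_shap_explanation <- function(phi, base_value, fx, method, features = NULL,
                                 se = NULL, n_permutations = NULL, seed = NULL) {
  if (!is.null(features)) names(phi) <- features
  structure(list(phi = phi, base_value = base_value, fx = fx, method = method,
                 se = se, n_permutations = n_permutations, seed = seed),
            class = "shap_explanation")
}

#' @export
print.shap_explanation <- function(x, ...) {
  cat(sprintf("<shap_explanation> %s: base %.4f, f(x) %.4f, sum(phi) %.4f\n",
              x$method, x$base_value, x$fx, sum(x$phi)))
  invisible(x)
}

#' Exact Shapley values by coalition enumeration
#'
#' Enumerates all 2^M coalitions and computes each feature's weighted
#' average marginal contribution with the combinatorial weights
#' `|S|! (M - |S| - 1)! / M!`. Satisfies the efficiency, dummy, symmetry
#' and linearity axioms exactly (up to numeric round-off).
#'
#' @param model_fn Function taking a numeric matrix (rows = records,
#'   columns = the M features) and returning one numeric score per row.
#' @param x Length-M numeric vector: the record to explain.
#' @param background Numeric matrix of background records (rows) used for
#'   the interventional expectation; must be non-empty.
#' @param cap Refuse enumeration above this feature count (default 15; the
#'   13-feature schema needs 8192 coalitions).
#' @return A `shap_explanation` with fields `phi`, `base_value`
#'   (= mean model output on the background), `fx` (= model output at `x`)
#'   and `method = "exact"`.
#' @export
exact_shapley <- function(model_fn, x, background, cap = 15L) {
  background <- as.matrix(background)
  if (nrow(background) < 1L) tf_schema_error("background set must be non-empty")
  M <- length(x)
  if (ncol(background) != M) tf_schema_error("background column count must equal length(x)")
  if (M > cap) {
    tf_schema_error("exact enumeration over %d features exceeds the cap (%d); use sampled_shapley", M, cap)
  }
  masks <- 0:(2^M - 1)
  bits <- 2^(0:(M - 1))
  coalitions <- matrix(FALSE, length(masks), M)
  for (j in seq_len(M)) coalitions[, j] <- bitwAnd(masks, bits[j]) > 0
  v <- coalition_values(model_fn, x, background, coalitions)
  sizes <- rowSums(coalitions)
  # weight by coalition size s: s! (M-s-1)! / M!
  wt <- exp(lfactorial(0:(M - 1)) + lfactorial(M - 1 - (0:(M - 1))) - lfactorial(M))
  phi <- numeric(M)
  for (j in seq_len(M)) {
    without <- which(!coalitions[, j])
    with_j <- without + bits[j]  # index shift = adding bit j to the mask
    phi[j] <- sum(wt[sizes[without] + 1L] * (v[with_j] - v[without]))
  }
  new_shap_explanation(phi, base_value = v[1L], fx = v[length(v)],
                       method = "exact", features = colnames(background))
}

#' Shapley values by permutation sampling
#'
#' Monte-Carlo estimator: for each sampled feature permutation, features
#' are switched from background to the explained record one at a time and
#' the marginal output changes are recorded. Deterministic per seed;
#' reports a per-feature Monte-Carlo standard error; converges to
#' [exact_shapley()] as the permutation count grows. Even a single
#' permutation satisfies efficiency exactly (the contributions telescope).
#'
#' @inheritParams exact_shapley
#' @param n_permutations Number of sampled permutations (>= 1).
#' @param seed Integer RNG seed.
#' @return A `shap_explanation` with `method = "sampled"` and a `se` field.
#' @export
sampled_shapley <- function(model_fn, x, background, n_permutations = 200L, seed = 1L) {
  background <- as.matrix(background)
  if (nrow(background) < 1L) tf_schema_error("background set must be non-empty")
  M <- length(x)
  if (ncol(background) != M) tf_schema_error("background column count must equal length(x)")
  if (n_permutations < 1L) tf_schema_error("n_permutations must be at least 1")
  perms <- with_seed(seed, replicate(n_permutations, sample.int(M), simplify = FALSE))
  contrib <- matrix(0, n_permutations, M)
  # batch permutations so each coalition_values call stays bounded
  per_batch <- max(1L, 16384L %/% ((M + 1L) * nrow(background)))
  for (start in seq(1L, n_permutations, by = per_batch)) {
    idx <- start:min(n_permutations, start + per_batch - 1L)
    coalitions <- do.call(rbind, lapply(perms[idx], function(p) {
      steps <- matrix(FALSE, M + 1L, M)
      for (k in seq_len(M)) steps[k + 1L, p[seq_len(k)]] <- TRUE
      steps
    }))
    v <- coalition_values(model_fn, x, background, coalitions)
    for (bi in seq_along(idx)) {
      vv <- v[((bi - 1L) * (M + 1L) + 1L):(bi * (M + 1L))]
      p <- perms[[idx[bi]]]
      contrib[idx[bi], p] <- diff(vv)
    }
  }
  phi <- colMeans(contrib)
  se <- if (n_permutations > 1L) {
    apply(contrib, 2L, stats::sd) / sqrt(n_permutations)
  } else {
    rep(NA_real_, M)
  }
  empty <- coalition_values(model_fn, x, background, matrix(FALSE, 1L, M))
  full <- coalition_values(model_fn, x, background, matrix(TRUE, 1L, M))
  new_shap_explanation(phi, base_value = empty, fx = full, method = "sampled",
                       features = colnames(background), se = se,
                       n_permutations = as.integer(n_permutations),
                       seed = as.integer(seed))
}

#' Explain pipeline predictions over the tabular features
#'
#' Treats the full frozen pipeline (imputation through classifier score for
#' class 1) as a black box over the raw tabular predictors: masked features
#' are replaced from background rows before grid conversion and feature
#' extraction, so the deep block reacts to coalitions. Uses exact
#' enumeration when the feature count is within `cap`, otherwise the
#' seeded permutation sampler.
#'
#' @param pipeline A `trained_pipeline`.
#' @param records [tabular_dataset()] of records to explain.
#' @param background [tabular_dataset()] of background records (a small
#'   seeded sample of training rows; ~20 is typical).
#' @param method `"auto"` (default), `"exact"` or `"sampled"`.
#' @param cap Exact-mode feature-count cap (default 13).
#' @param n_permutations Permutation count for sampled mode.
#' @param seed Integer RNG seed for sampled mode.
#' @return List with `explanations` (one `shap_explanation` per record),
#'   `summary` (an `impact_summary`), and `table` (plot-ready long data
#'   frame: record, feature, value, phi).
#' @export
explain_pipeline <- function(pipeline, records, background,
                             method = c("auto", "exact", "sampled"),
                             cap = 13L, n_permutations = 200L, seed = 1L) {
  method <- match.arg(method)
  bg <- background$values
  M <- ncol(bg)
  if (method == "auto") method <- if (M <= cap) "exact" else "sampled"
  model_fn <- function(mat) {
    colnames(mat) <- schema_names(pipeline$schema)
    ds <- tabular_dataset(mat, NULL, pipeline$schema, validate = FALSE)
    stats::predict(pipeline, ds)$score
  }
  explanations <- lapply(seq_len(nrow(records$values)), function(i) {
    x <- records$values[i, ]
    if (method == "exact") {
      exact_shapley(model_fn, x, bg, cap = max(cap, M))
    } else {
      sampled_shapley(model_fn, x, bg, n_permutations = n_permutations,
                      seed = seed + i - 1L)
    }
  })
  summary <- impact_summary(explanations, records$values)
  tab <- do.call(rbind, lapply(seq_along(explanations), function(i) {
    data.frame(record = i, feature = names(explanations[[i]]$phi) %||%
                 colnames(records$values),
               value = records$values[i, ], phi = unname(explanations[[i]]$phi))
  }))
  rownames(tab) <- NULL
  list(explanations = explanations, summary = summary, table = tab)
}

#' Summarize feature impacts across explained records
#'
#' Mean absolute Shapley value per feature, the sign profile (correlation
#' between a feature's Shapley values and its raw values across records;
#' NA when either is constant), and the impact ranking (most impactful
#' first).
#'
#' @param explanations List of `shap_explanation`s.
#' @param values Matrix of the explained records' feature values (rows
#'   aligned with `explanations`).
#' @return An object of class `impact_summary`: data frame with columns
#'   `feature`, `mean_abs_phi`, `sign_profile`, sorted by `mean_abs_phi`
#'   descending.
#' @export
impact_summary <- function(explanations, values) {
  phi <- do.call(rbind, lapply(explanations, function(e) e$phi))
  features <- colnames(phi) %||% colnames(values) %||% paste0("f", seq_len(ncol(phi)))
  mean_abs <- colMeans(abs(phi))
  sign_profile <- vapply(seq_len(ncol(phi)), function(j) {
    if (nrow(phi) < 2L || stats::sd(phi[, j]) == 0 || stats::sd(values[, j]) == 0) {
      NA_real_
    } else {
      stats::cor(phi[, j], values[, j])
    }
  }, numeric(1))
  out <- data.frame(feature = features, mean_abs_phi = unname(mean_abs),
                    sign_profile = sign_profile)
  out <- out[order(-out$mean_abs_phi), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("impact_summary", "data.frame")
  out
}

#' Write explanations to TSV and JSON
#'
#' @param result An [explain_pipeline()] result.
#' @param tsv_path,json_path,summary_path Output paths (NULL to skip).
#' @return Invisibly, the list of written paths.
#' @export
write_explanations <- function(result, tsv_path = NULL, json_path = NULL,
                               summary_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(result$table, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(lapply(result$explanations, function(e) {
      list(phi = as.list(e$phi), base_value = e$base_value, fx = e$fx,
           method = e$method)
    }), json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(summary_path)) {
    utils::write.table(as.data.frame(result$summary), summary_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(list(tsv = tsv_path, json = json_path, summary = summary_path))
}
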