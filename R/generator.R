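# Gaussian copula generator for schema-conforming synthetic records.
#
# Marginals are empirical (numeric: inverse empirical CDF over stored sample
# points; nominal: category frequencies turned into latent-normal
# thresholds), fitted per target class. Dependence is a latent normal
# correlation matrix estimated from Spearman rank correlations via the
# classical r = 2 sin(pi * rho / 6) map and repaired to positive
# semi-definiteness by eigenvalue clipping.

# Project a symmetric matrix onto the PSD cone by clipping eigenvalues,
# then rescale to unit diagonal.
nearest_psd_correlation <- function(R, eps = 1e-8) {
  dn <- dimnames(R)
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eps) {
    diag(R) <- 1
    return(R)
  }
  vals <- pmax(e$values, eps)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  dimnames(out) <- dn
  out
}

check_component <- function(comp, schema, class_label) {
  nm <- schema_names(schema)
  kinds <- schema_kinds(schema)
  for (j in seq_along(nm)) {
    m <- comp$marginals[[nm[j]]]
    if (is.null(m)) tf_schema_error("class %s: no marginal for feature '%s'", class_label, nm[j])
    if (kinds[j] == "nominal") {
      if (abs(sum(m) - 1) > 1e-8) {
        tf_schema_error("class %s: frequencies of '%s' must sum to 1", class_label, nm[j])
      }
    }
  }
  d <- length(nm)
  if (!is.matrix(comp$latent) || any(dim(comp$latent) != d)) {
    tf_schema_error("class %s: latent correlation must be %d x %d", class_label, d, d)
  }
  comp$latent <- nearest_psd_correlation(comp$latent)
  comp
}

#' Construct a copula generator directly
#'
#' Builds a `copula_generator` from explicitly stated marginals and a latent
#' correlation structure, without fitting to data. Used for reference
#' populations with known ground truth (see [heart_reference_generator()]).
#'
#' @param schema A [feature_schema()].
#' @param components Named list, one entry per target class (names are the
#'   class codes). Each entry is a list with `marginals` (named list: for a
#'   numeric feature a sorted vector of sample points defining the inverse
#'   empirical CDF; for a nominal feature a vector of category frequencies
#'   named by code, summing to 1) and `latent` (d x d latent correlation
#'   matrix over the predictors; repaired to PSD by eigenvalue clipping).
#' @param class_probs Named numeric vector of class prevalences, summing to 1.
#' @param seed Optional integer recorded as the model's fit seed.
#' @return An object of class `copula_generator`.
#' @export
new_copula_generator <- function(schema, components, class_probs, seed = NULL) {
  if (abs(sum(class_probs) - 1) > 1e-8) tf_schema_error("class_probs must sum to 1")
  if (!setequal(names(components), names(class_probs))) {
    tf_schema_error("components and class_probs must cover the same classes")
  }
  components <- components[names(class_probs)]
  components <- Map(check_component, components, list(schema), names(components))
  structure(list(schema = schema, class_probs = class_probs,
                 components = components, seed = seed, backend = "copula"),
            class = "copula_generator")
}

#' Fit the copula generator to a reference dataset
#'
#' Per target class, stores each numeric feature's sorted observed values
#' (the empirical quantile function), each nominal feature's category
#' frequencies, and the latent correlation matrix over all predictors
#' estimated from within-class Spearman rank correlations. Fitting is
#' deterministic; `seed` is recorded for provenance.
#'
#' @param reference A labeled [tabular_dataset()] without missing cells.
#' @param seed Integer recorded as the fit seed.
#' @param backend Generator backend; only `"copula"` is provided.
#' @return An object of class `copula_generator`.
#' @export
fit_generator <- function(reference, seed = NULL, backend = "copula") {
  if (backend != "copula") {
    tf_capability_error("generator backend '%s' is not available; use backend = 'copula'", backend)
  }
  if (is.null(reference$labels)) tf_schema_error("fit_generator needs a labeled reference dataset")
  if (anyNA(reference$values)) tf_schema_error("impute missing cells before fitting the generator")
  n <- nrow(reference$values)
  if (n < 30L) warning(sprintf("fitting a generator to only %d rows; marginals will be coarse", n))
  schema <- reference$schema
  nm <- schema_names(schema)
  kinds <- schema_kinds(schema)
  classes <- sort(unique(reference$labels))
  class_probs <- as.numeric(table(factor(reference$labels, levels = classes))) / n
  names(class_probs) <- as.character(classes)

  components <- lapply(classes, function(cl) {
    x <- reference$values[reference$labels == cl, , drop = FALSE]
    marginals <- lapply(seq_along(nm), function(j) {
      if (kinds[j] == "numeric") {
        sort(x[, j])
      } else {
        spec <- schema$predictors[[j]]
        f <- as.numeric(table(factor(x[, j], levels = spec$domain))) / nrow(x)
        names(f) <- as.character(spec$domain)
        f
      }
    })
    names(marginals) <- nm
    const <- apply(x, 2L, function(v) length(unique(v)) == 1L)
    if (any(const)) {
      warning(sprintf("class %s: degenerate (constant) feature(s): %s",
                      cl, paste(nm[const], collapse = ", ")))
    }
    rho <- suppressWarnings(stats::cor(x, method = "spearman"))
    rho[!is.finite(rho)] <- 0
    diag(rho) <- 1
    latent <- 2 * sin(pi * rho / 6)
    list(marginals = marginals, latent = nearest_psd_correlation(latent))
  })
  names(components) <- as.character(classes)
  new_copula_generator(schema, components, class_probs, seed = seed)
}

#' @export
print.copula_generator <- function(x, ...) {
  cat(sprintf("<copula_generator> %d predictors, classes {%s}, prevalences {%s}\n",
              length(schema_names(x$schema)), paste(names(x$class_probs), collapse = ","),
              paste(sprintf("%.3f", x$class_probs), collapse = ",")))
  invisible(x)
}

# Inverse empirical CDF at u for a sorted sample-point vector.
inv_ecdf <- function(sorted_vals, u) {
  n <- length(sorted_vals)
  sorted_vals[pmin.int(n, pmax.int(1L, ceiling(u * n)))]
}

#' Sample synthetic records from a fitted generator
#'
#' Class labels are drawn from the fitted prevalences, then for each class a
#' latent normal vector with the class's correlation structure is pushed
#' through the per-feature marginals: numeric features through the inverse
#' empirical CDF (so only reference sample points are ever emitted), nominal
#' features through frequency thresholds. Identical seeds give identical
#' tables.
#'
#' @param model A `copula_generator`.
#' @param n Number of records (default 1100, the augmentation batch size).
#' @param seed Integer RNG seed.
#' @return A schema-valid labeled [tabular_dataset()].
#' @export
sample_synthetic <- function(model, n = 1100, seed = NULL) {
  if (!inherits(model, "copula_generator")) tf_schema_error("model must be a copula_generator")
  if (!is.numeric(n) || n <= 0) tf_schema_error("n must be a positive count")
  n <- as.integer(n)
  schema <- model$schema
  nm <- schema_names(schema)
  kinds <- schema_kinds(schema)
  d <- length(nm)
  with_seed(seed, {
    counts <- as.integer(stats::rmultinom(1L, n, model$class_probs))
    rows <- vector("list", length(counts))
    labs <- vector("list", length(counts))
    for (k in seq_along(counts)) {
      nc <- counts[k]
      if (nc == 0L) next
      comp <- model$components[[k]]
      L <- chol(nearest_psd_correlation(comp$latent, eps = 1e-6))
      z <- matrix(stats::rnorm(nc * d), nc, d) %*% L
      u <- stats::pnorm(z)
      vals <- matrix(0, nc, d, dimnames = list(NULL, nm))
      for (j in seq_len(d)) {
        m <- comp$marginals[[nm[j]]]
        if (kinds[j] == "numeric") {
          vals[, j] <- inv_ecdf(m, u[, j])
        } else {
          codes <- as.numeric(names(m))
          cum <- cumsum(m)
          idx <- findInterval(u[, j], cum, left.open = TRUE) + 1L
          vals[, j] <- codes[pmin.int(idx, length(codes))]
        }
      }
      rows[[k]] <- vals
      labs[[k]] <- rep(as.integer(names(model$class_probs)[k]), nc)
    }
    values <- do.call(rbind, rows)
    labels <- unlist(labs)
    perm <- sample.int(n)
    tabular_dataset(values[perm, , drop = FALSE], labels[perm], schema,
                    validate = FALSE)
  })
}

# Build a latent correlation matrix for the heart schema from a list of
# named pairwise entries; everything unstated is 0.
heart_latent_correlation <- function() {
  nm <- c("age", "sex", "cp", "trestbps", "chol", "fbs", "restecg",
          "thalach", "exang", "oldpeak", "slope", "ca", "thal")
  R <- diag(13)
  dimnames(R) <- list(nm, nm)
  set_pair <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_pair("age", "thalach", -0.40)
  set_pair("age", "trestbps", 0.28)
  set_pair("age", "chol", 0.20)
  set_pair("age", "ca", 0.30)
  set_pair("cp", "exang", -0.40)
  set_pair("cp", "thalach", 0.30)
  set_pair("thalach", "exang", -0.35)
  set_pair("thalach", "slope", 0.35)
  set_pair("thalach", "oldpeak", -0.35)
  set_pair("oldpeak", "slope", -0.50)
  set_pair("oldpeak", "exang", 0.30)
  set_pair("sex", "thal", 0.25)
  set_pair("trestbps", "oldpeak", 0.20)
  set_pair("restecg", "thalach", 0.10)
  nearest_psd_correlation(R)
}

#' Reference generator emulating the heart-disease population
#'
#' A directly constructed [new_copula_generator()] for the bundled
#' 13-predictor schema, with stated marginals and a stated latent
#' correlation structure. Numeric marginals are smooth parametric quantile
#' grids (normal for age, blood pressure, cholesterol and maximum heart
#' rate; gamma for ST depression) clipped into the schema domains; nominal
#' frequencies and numeric locations shift between the healthy and disease
#' classes the way the public Kaggle heart data do under its target coding
#' (the disease class shows higher peak heart rate, lower ST depression,
#' more non-typical chest pain and fewer fluoroscopy-colored vessels). It
#' serves as a seeded ground-truth population for generator calibration
#' studies.
#'
#' @param grid_points Number of sample points per numeric quantile grid
#'   (default 1024).
#' @return A `copula_generator`.
#' @export
heart_reference_generator <- function(grid_points = 1024L) {
  schema <- heart_schema()
  p <- stats::ppoints(grid_points)
  qgrid <- function(q, lo, hi) sort(pmin(pmax(q, lo), hi))
  num_marg <- function(age_mu, bp_mu, chol_mu, hr_mu, op_shape, op_scale) {
    list(
      age = qgrid(stats::qnorm(p, age_mu, 9), 29, 77),
      trestbps = qgrid(stats::qnorm(p, bp_mu, 17), 94, 200),
      chol = qgrid(stats::qnorm(p, chol_mu, 50), 126, 564),
      thalach = qgrid(stats::qnorm(p, hr_mu, 21), 71, 202),
      oldpeak = qgrid(stats::qgamma(p, shape = op_shape, scale = op_scale), 0, 6.2)
    )
  }
  freq <- function(codes, probs) {
    f <- probs / sum(probs)
    names(f) <- as.character(codes)
    f
  }
  latent <- heart_latent_correlation()

  healthy <- list(
    marginals = c(
      num_marg(56.5, 134, 251, 139, 1.8, 0.88),
      list(
        sex = freq(0:1, c(0.17, 0.83)),
        cp = freq(0:3, c(0.73, 0.09, 0.13, 0.05)),
        fbs = freq(0:1, c(0.84, 0.16)),
        restecg = freq(0:2, c(0.56, 0.42, 0.02)),
        exang = freq(0:1, c(0.45, 0.55)),
        slope = freq(0:2, c(0.09, 0.56, 0.35)),
        ca = freq(0:3, c(0.45, 0.24, 0.19, 0.12)),
        thal = freq(0:3, c(0.01, 0.04, 0.35, 0.60))
      )
    )[schema_names(schema)],
    latent = latent
  )
  disease <- list(
    marginals = c(
      num_marg(52.5, 129, 242, 158, 0.9, 0.65),
      list(
        sex = freq(0:1, c(0.44, 0.56)),
        cp = freq(0:3, c(0.25, 0.25, 0.40, 0.10)),
        fbs = freq(0:1, c(0.86, 0.14)),
        restecg = freq(0:2, c(0.46, 0.52, 0.02)),
        exang = freq(0:1, c(0.86, 0.14)),
        slope = freq(0:2, c(0.02, 0.35, 0.63)),
        ca = freq(0:3, c(0.79, 0.12, 0.06, 0.03)),
        thal = freq(0:3, c(0.01, 0.06, 0.78, 0.15))
      )
    )[schema_names(schema)],
    latent = latent
  )
  new_copula_generator(schema,
                       components = list(`0` = healthy, `1` = disease),
                       class_probs = c(`0` = 0.49, `1` = 0.51))
}
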