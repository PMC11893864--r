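test_that("exact Shapley values satisfy the additive-model oracle", {
  # f = x1 + 2 x2, x = (1, 1), background (0, 0):
  # enumerating both coalitions per feature by hand gives phi = (1, 2)
  f <- function(m) m[, 1] + 2 * m[, 2]
  ex <- exact_shapley(f, c(1, 1), matrix(0, 1, 2))
  expect_equal(unname(ex$phi), c(1, 2))
  expect_equal(ex$base_value, 0)
  expect_equal(ex$fx, 3)
})

test_that("efficiency, dummy, symmetry and linearity hold on constructed models", {
  set.seed(50)
  bg <- matrix(stats::rnorm(5 * 4), 5, 4)
  x <- stats::rnorm(4)

  # efficiency on an arbitrary nonlinear model
  g <- function(m) sin(m[, 1]) + m[, 2] * m[, 3]^2 + exp(0.3 * m[, 4])
  ex <- exact_shapley(g, x, bg)
  expect_equal(sum(ex$phi), ex$fx - ex$base_value, tolerance = 1e-10)

  # dummy: a feature the model never reads gets exactly 0
  h <- function(m) m[, 1]^2 + m[, 3]
  exh <- exact_shapley(h, x, bg)
  expect_equal(unname(exh$phi[2]), 0)
  expect_equal(unname(exh$phi[4]), 0)

  # symmetry: interchangeable features with symmetric x and background
  sym <- function(m) m[, 1] + m[, 2]
  bg_sym <- cbind(rep(0, 3), rep(0, 3), stats::rnorm(3), stats::rnorm(3))
  x_sym <- c(2, 2, 0.5, -0.3)
  exs <- exact_shapley(sym, x_sym, bg_sym)
  expect_equal(unname(exs$phi[1]), unname(exs$phi[2]), tolerance = 1e-10)

  # linearity: phi(g + h) = phi(g) + phi(h)
  gh <- function(m) g(m) + h(m)
  exgh <- exact_shapley(gh, x, bg)
  expect_equal(unname(exgh$phi), unname(ex$phi + exh$phi), tolerance = 1e-10)
})

test_that("the sampled estimator agrees with the exact enumerator", {
  # all M <= 4 toys, 50 seeded trials: each phi within 3 Monte-Carlo SEs
  set.seed(51)
  models <- list(
    function(m) m[, 1],
    function(m) m[, 1] - 2 * m[, 2],
    function(m) m[, 1] * m[, 2] + m[, 3],
    function(m) sin(m[, 1]) + m[, 2] * m[, 3] - 0.5 * m[, 4]^2
  )
  for (trial in 1:50) {
    M <- sample(1:4, 1)
    f <- models[[M]]
    bg <- matrix(stats::rnorm(4 * M), 4, M)
    x <- stats::rnorm(M)
    ex <- exact_shapley(f, x, bg)
    sa <- sampled_shapley(f, x, bg, n_permutations = 300, seed = trial)
    tol <- 3 * pmax(sa$se, 1e-12) + 1e-10
    expect_true(all(abs(sa$phi - ex$phi) <= tol))
    expect_equal(sum(sa$phi), sa$fx - sa$base_value, tolerance = 1e-10)
  }
})

test_that("sampling is seeded and a single permutation still telescopes", {
  f <- function(m) m[, 1] * m[, 2] + m[, 3]
  bg <- matrix(stats::rnorm(12), 4, 3)
  x <- c(1, -1, 2)
  a <- sampled_shapley(f, x, bg, n_permutations = 40, seed = 9)
  b <- sampled_shapley(f, x, bg, n_permutations = 40, seed = 9)
  expect_identical(a$phi, b$phi)
  one <- sampled_shapley(f, x, bg, n_permutations = 1, seed = 3)
  expect_equal(sum(one$phi), one$fx - one$base_value, tolerance = 1e-10)
  expect_error(exact_shapley(f, rep(0, 20), matrix(0, 1, 20)),
               class = "tabfuse_schema_error")
  expect_error(exact_shapley(f, x, bg[0, , drop = FALSE]),
               class = "tabfuse_schema_error")
})

test_that("pipeline explanations obey the dummy axiom over raw features", {
  # dataset where only chest-pain type carries signal: every other feature
  # is constant, so replacing it from the background can never move the
  # pipeline score and its Shapley value must be exactly 0.
  schema <- heart_schema()
  n <- 60
  set.seed(52)
  cp <- sample(0:3, n, replace = TRUE)
  vals <- matrix(rep(c(55, 1, 0, 130, 240, 0, 1, 150, 0, 1, 1, 0, 2), each = n),
                 n, 13, dimnames = list(NULL, schema_names(schema)))
  vals[, "cp"] <- cp
  labels <- as.integer(cp >= 2)
  ds <- suppressWarnings(tabular_dataset(vals, labels, schema, validate = FALSE))
  spec <- hybrid_model_spec("decision_tree", grid = list(max_depth = 3, min_samples_split = 2),
                            folds = 3)
  bb <- make_toy_backbone(seed = 5, output_dim = 4, input_side = 4)
  pl <- suppressWarnings(train_pipeline(ds, spec, backbone = bb, seed = 6, target_side = 4))

  records <- subset_dataset(ds, 1:3)
  background <- subset_dataset(ds, 4:7)
  res <- suppressWarnings(explain_pipeline(pl, records, background, method = "exact"))
  s <- res$summary
  expect_setequal(s$feature, schema_names(schema))       # ranking covers all 13
  expect_gt(s$mean_abs_phi[s$feature == "cp"], 0)
  others <- s$mean_abs_phi[s$feature != "cp"]
  expect_true(all(others < 1e-10))
  # explanations of identical records are identical
  rec2 <- subset_dataset(ds, c(1L, 1L))
  res2 <- suppressWarnings(explain_pipeline(pl, rec2, background, method = "exact"))
  expect_equal(res2$explanations[[1]]$phi, res2$explanations[[2]]$phi)
  # efficiency through the full pipeline
  e1 <- res$explanations[[1]]
  expect_equal(sum(e1$phi), e1$fx - e1$base_value, tolerance = 1e-8)
})

test_that("explanations export to TSV/JSON and the summary ranks by impact", {
  f <- function(m) 2 * m[, 1] - m[, 2]
  bg <- matrix(stats::rnorm(8), 4, 2, dimnames = list(NULL, c("a", "b")))
  exps <- lapply(1:3, function(i) exact_shapley(f, c(i, -i), bg))
  vals <- rbind(c(1, -1), c(2, -2), c(3, -3))
  colnames(vals) <- c("a", "b")
  s <- impact_summary(exps, vals)
  expect_identical(s$feature, c("a", "b"))    # |2x| beats |-x|
  expect_true(all(diff(s$mean_abs_phi) <= 0))
  res <- list(explanations = exps, summary = s,
              table = data.frame(record = 1, feature = c("a", "b"),
                                 value = c(1, -1), phi = unname(exps[[1]]$phi)))
  paths <- write_explanations(res, tempfile(fileext = ".tsv"),
                              tempfile(fileext = ".json"),
                              tempfile(fileext = ".tsv"))
  expect_true(file.exists(paths$tsv))
  doc <- jsonlite::read_json(paths$json)
  expect_length(doc, 3L)
  expect_true(file.exists(paths$summary))
})
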