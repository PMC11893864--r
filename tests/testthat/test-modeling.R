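test_that("fusion concatenates blocks column-wise with row alignment", {
  set.seed(30)
  tab <- matrix(stats::runif(5 * 13), 5, 13, dimnames = list(NULL, paste0("f", 1:13)))
  deep <- matrix(stats::rnorm(5 * 32), 5, 32)
  fused <- fuse(tab, deep)
  expect_identical(ncol(fused), 45L)
  expect_identical(attr(fused, "blocks"), c(rep("tabular", 13), rep("deep", 32)))
  expect_equal(unname(fused[3, ]), unname(c(tab[3, ], deep[3, ])))
  # standalone mode: fused is the tabular block
  alone <- fuse(tab, NULL)
  expect_identical(ncol(alone), 13L)
  expect_equal(as.numeric(alone), as.numeric(tab))
  expect_error(fuse(tab, deep[1:4, ]), class = "tabfuse_schema_error")
})

test_that("grid search selects within the declared grid and reports paired folds", {
  ds <- separable_ds(120, seed = 2)
  fused <- fuse(ds$values)
  spec <- hybrid_model_spec("decision_tree",
                            grid = list(max_depth = c(NA, 5), min_samples_split = c(2, 5)),
                            folds = 4)
  tm <- tune_and_train(fused, ds$labels, spec, seed = 7)
  expect_true(tm$best_params$max_depth %in% c(NA, 5))
  expect_true(tm$best_params$min_samples_split %in% c(2, 5))
  # CV mean recomputed from the fold table equals the reported mean
  best_rows <- tm$cv_table[tm$cv_table$params == with(tm$best_params,
    sprintf("max_depth=%s, min_samples_split=%s",
            ifelse(is.na(max_depth), "None", max_depth), min_samples_split)), ]
  expect_equal(mean(best_rows$score), tm$cv_score)
  # every candidate is scored on every fold
  expect_identical(nrow(tm$cv_table), 4L * 4L)

  # a one-candidate grid selects that candidate
  spec1 <- hybrid_model_spec("knn", grid = list(n_neighbors = 3, weights = "uniform"),
                             folds = 3)
  tm1 <- tune_and_train(fused, ds$labels, spec1, seed = 7)
  expect_identical(tm1$best_params$n_neighbors, 3)

  # degenerate folds are rejected with guidance
  tiny <- separable_ds(8, seed = 1)
  expect_error(tune_and_train(fuse(tiny$values), tiny$labels,
                              hybrid_model_spec("knn", grid = list(n_neighbors = 3, weights = "uniform"),
                                                folds = 6), seed = 1),
               "fold")
})

test_that("seed determinism: identical seed gives identical tuning outcome", {
  ds <- separable_ds(80, seed = 4)
  fused <- fuse(ds$values)
  spec <- hybrid_model_spec("random_forest",
                            grid = list(max_depth = c(NA, 5), n_estimators = 50),
                            folds = 4)
  a <- tune_and_train(fused, ds$labels, spec, seed = 11)
  b <- tune_and_train(fused, ds$labels, spec, seed = 11)
  expect_identical(a$best_params, b$best_params)
  expect_identical(a$cv_table, b$cv_table)
})

test_that("separable data reaches CV accuracy 1.0 for hybrid and standalone LR", {
  ds <- separable_ds(200, seed = 5)
  spec <- hybrid_model_spec("logistic_regression", grid = list(C = 1, solver = "liblinear"),
                            folds = 5)
  bb <- make_toy_backbone(seed = 6, output_dim = 8, input_side = 8)
  hybrid <- train_pipeline(ds, spec, backbone = bb, seed = 9, target_side = 8)
  alone <- train_standalone(ds, spec, seed = 9)
  expect_equal(hybrid$cv_score, 1.0)
  expect_equal(alone$cv_score, 1.0)
  # fused width: standalone = d_tab only
  expect_null(alone$backbone)
  # prediction on the training rows of a perfectly fitted model returns the labels
  pred <- predict(hybrid, ds)
  expect_identical(pred$label, ds$labels)
  pred2 <- predict(hybrid, ds)
  expect_identical(pred, pred2)
})

test_that("every classifier family trains, predicts, and respects its grid", {
  ds <- separable_ds(60, seed = 8)
  fused <- fuse(ds$values)
  grids <- list(
    random_forest = list(max_depth = NA, n_estimators = 50),
    logistic_regression = list(C = 1, solver = "liblinear"),
    decision_tree = list(max_depth = NA, min_samples_split = 2),
    knn = list(n_neighbors = 5, weights = "distance"),
    gradient_boosting = list(learning_rate = 0.1, n_estimators = 50),
    svm = list(C = 0.1, kernel = "linear")
  )
  for (fam in names(grids)) {
    spec <- hybrid_model_spec(fam, grid = grids[[fam]], folds = 3)
    tm <- tune_and_train(fused, ds$labels, spec, seed = 3)
    expect_identical(tm$family, fam)
    expect_identical(tm$best_params[names(grids[[fam]])], grids[[fam]])
    pred <- predict_accuracy <- mean(
      tabfuse:::predict_classifier(tm$model, fused)$label == ds$labels)
    expect_gte(pred, 0.95)
  }
})

test_that("default grids contain each family's reported optimum", {
  g <- default_grids()
  expect_true(is.na(g$random_forest$max_depth[1]) && 50 %in% g$random_forest$n_estimators)
  expect_true(1 %in% g$logistic_regression$C && "liblinear" %in% g$logistic_regression$solver)
  expect_true(2 %in% g$decision_tree$min_samples_split)
  expect_true(5 %in% g$knn$n_neighbors && "uniform" %in% g$knn$weights)
  expect_true(0.1 %in% g$gradient_boosting$learning_rate && 50 %in% g$gradient_boosting$n_estimators)
  expect_true(0.1 %in% g$svm$C && "linear" %in% g$svm$kernel)
})

test_that("frozen preprocessing: test rows never influence fitted parameters", {
  ds <- heart_sample(150, seed = 12)
  sp <- stratified_split(ds, 0.3, seed = 3)
  spec <- hybrid_model_spec("decision_tree", grid = list(max_depth = 5, min_samples_split = 2),
                            folds = 3)
  p1 <- train_standalone(sp$train, spec, seed = 5)
  # corrupt the test rows wildly; refit on the same training rows
  corrupted <- sp$test
  corrupted$values[, "chol"] <- 700
  p2 <- train_standalone(sp$train, spec, seed = 5)
  expect_identical(p1$norm_params, p2$norm_params)
  expect_identical(p1$feature_order$order, p2$feature_order$order)
  expect_identical(p1$impute_params, p2$impute_params)
})

test_that("out-of-range unseen values are clipped and still scored", {
  ds <- separable_ds(60, seed = 13)
  spec <- hybrid_model_spec("logistic_regression", grid = list(C = 1, solver = "liblinear"),
                            folds = 3)
  pl <- train_standalone(ds, spec, seed = 2)
  extreme <- ds$values[1:2, , drop = FALSE]
  extreme[1, 1] <- 999   # far outside the fitted range
  pred <- predict(pl, tabular_dataset(extreme, NULL, ds$schema, validate = FALSE))
  expect_identical(nrow(pred), 2L)
  expect_true(all(pred$score >= 0 & pred$score <= 1))
})

test_that("pipeline bundles save and load as self-contained files", {
  ds <- separable_ds(60, seed = 14)
  spec <- hybrid_model_spec("knn", grid = list(n_neighbors = 3, weights = "uniform"),
                            folds = 3)
  bb <- make_toy_backbone(seed = 1, output_dim = 4, input_side = 8)
  pl <- train_pipeline(ds, spec, backbone = bb, seed = 4, target_side = 8)
  path <- tempfile(fileext = ".bundle")
  save_pipeline(pl, path)
  back <- load_pipeline(path)
  expect_identical(predict(back, ds), predict(pl, ds))
  expect_error(load_pipeline(tempfile()), class = "tabfuse_io_error")
})
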