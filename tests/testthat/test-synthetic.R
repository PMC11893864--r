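test_that("fitting recovers exact duplicates and independence", {
  schema <- toy_schema(4)
  set.seed(3)
  a <- stats::rnorm(400)
  b <- a                       # exact copy
  c_ <- stats::rnorm(400)
  d_ <- stats::rnorm(400)
  ds <- tabular_dataset(cbind(x1 = a, x2 = b, x3 = c_, x4 = d_),
                        rep(0:1, 200), schema, validate = FALSE)
  gen <- fit_generator(ds, seed = 1)
  for (cl in c("0", "1")) {
    expect_gt(gen$components[[cl]]$latent["x1", "x2"], 0.999)
  }

  # independent features: fitted latent correlations near zero
  set.seed(4)
  ds2 <- tabular_dataset(matrix(stats::rnorm(5000 * 4), 5000, 4,
                                dimnames = list(NULL, paste0("x", 1:4))),
                         rep(0:1, 2500), schema, validate = FALSE)
  gen2 <- fit_generator(ds2, seed = 1)
  off <- gen2$components[["0"]]$latent
  diag(off) <- 0
  expect_lt(max(abs(off)), 0.06)

  # refit with same seed is identical
  expect_identical(fit_generator(ds, seed = 1), fit_generator(ds, seed = 1))
})

test_that("sampling is seeded, schema-valid, and defaults to 1100 rows", {
  gen <- heart_reference_generator()
  s1 <- sample_synthetic(gen, seed = 5)
  expect_identical(nrow(s1$values), 1100L)
  s2 <- sample_synthetic(gen, seed = 5)
  expect_identical(s1$values, s2$values)
  expect_identical(s1$labels, s2$labels)
  s3 <- sample_synthetic(gen, seed = 6)
  expect_false(identical(s1$values, s3$values))
  expect_error(sample_synthetic(gen, n = 0, seed = 1), class = "tabfuse_schema_error")

  # every sampled value is inside its feature domain
  report <- validate_dataset(s1)
  expect_false(any(report$reason == "out_of_domain"))

  # a frequency table concentrated on one code samples only that code
  gen2 <- gen
  f <- gen2$components[["0"]]$marginals$cp
  f[] <- c(1, 0, 0, 0)
  gen2$components[["0"]]$marginals$cp <- f
  gen2$components[["1"]]$marginals$cp <- f
  s4 <- sample_synthetic(gen2, 500, seed = 2)
  expect_true(all(s4$values[, "cp"] == 0))
})

test_that("sampled nominal frequencies converge to the model frequencies", {
  gen <- heart_reference_generator()
  s <- sample_synthetic(gen, 10000, seed = 17)
  for (feat in c("cp", "slope", "thal")) {
    for (cl in c("0", "1")) {
      want <- gen$components[[cl]]$marginals[[feat]]
      rows <- s$labels == as.integer(cl)
      got <- as.numeric(table(factor(s$values[rows, feat],
                                     levels = as.numeric(names(want))))) / sum(rows)
      expect_lt(max(abs(got - want)), 0.03)
    }
  }
})

test_that("correlation MAE matches a longhand oracle and is symmetric", {
  schema <- toy_schema(3)
  set.seed(8)
  r1 <- matrix(stats::rnorm(60), 20, 3, dimnames = list(NULL, paste0("x", 1:3)))
  r2 <- matrix(stats::rnorm(60), 20, 3, dimnames = list(NULL, paste0("x", 1:3)))
  a <- tabular_dataset(r1, NULL, schema, validate = FALSE)
  b <- tabular_dataset(r2, NULL, schema, validate = FALSE)

  # longhand Pearson correlation
  pearson <- function(x, y) {
    xm <- x - mean(x); ym <- y - mean(y)
    sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  }
  want <- numeric(3)
  for (i in 1:3) {
    diffs <- c()
    for (j in setdiff(1:3, i)) {
      diffs <- c(diffs, abs(pearson(r1[, i], r1[, j]) - pearson(r2[, i], r2[, j])))
    }
    want[i] <- mean(diffs)
  }
  got <- correlation_mae(a, b)
  expect_equal(unname(got$per_feature), want, tolerance = 1e-12)
  expect_equal(got$average, mean(want), tolerance = 1e-12)

  # identical tables give zero; symmetry holds
  expect_equal(correlation_mae(a, a)$average, 0)
  expect_equal(correlation_mae(a, b)$average, correlation_mae(b, a)$average)
})

test_that("baseline split MAE is a small seeded sampling-noise level", {
  schema <- toy_schema(4)
  set.seed(10)
  ds <- tabular_dataset(matrix(stats::rnorm(10000 * 4), 10000, 4,
                               dimnames = list(NULL, paste0("x", 1:4))),
                        NULL, schema, validate = FALSE)
  m1 <- baseline_split_mae(ds, seed = 3)
  expect_lt(m1, 0.05)
  expect_identical(m1, baseline_split_mae(ds, seed = 3))
  small <- tabular_dataset(ds$values[1:3, ], NULL, schema, validate = FALSE)
  expect_error(baseline_split_mae(small, seed = 1), class = "tabfuse_schema_error")
})

test_that("distribution tests behave at the identity and at disjoint supports", {
  ds <- heart_sample(200, seed = 21)
  res <- distribution_tests(ds, ds)
  expect_true(all(res$statistic[res$test == "ks"] == 0))
  expect_true(all(res$p_value[res$test == "ks"] == 1))
  chis <- res[res$test == "chisq" & !startsWith(res$note, "skipped"), ]
  expect_true(all(chis$statistic == 0))
  expect_true(all(chis$p_value == 1))

  # disjoint numeric supports: D = 1, p below 1e-6
  schema <- mini_schema()
  a <- tabular_dataset(cbind(x1 = stats::runif(200, 0, 1)), NULL, schema, validate = FALSE)
  b <- tabular_dataset(cbind(x1 = stats::runif(200, 5, 6)), NULL, schema, validate = FALSE)
  r <- distribution_tests(a, b)
  expect_equal(r$statistic, 1)
  expect_lt(r$p_value, 1e-6)
})

test_that("a 3-SD marginal shift is detected by the KS test at n = 500", {
  schema <- mini_schema()
  set.seed(33)
  x <- stats::rnorm(500, 0, 1)
  y <- stats::rnorm(500, 3, 1)   # shifted by 3 SD
  a <- tabular_dataset(cbind(x1 = x), NULL, schema, validate = FALSE)
  b <- tabular_dataset(cbind(x1 = y), NULL, schema, validate = FALSE)
  r <- distribution_tests(a, b)
  expect_lt(r$p_value, 0.05)
})

test_that("quality report aggregates, passes on identity, and round-trips", {
  ds <- heart_sample(300, seed = 25)
  rep1 <- quality_report(ds, ds, seed = 4)
  expect_equal(rep1$correlation$average, 0)
  expect_true(all(rep1$tests$pass[!is.na(rep1$tests$pass)]))

  json <- tempfile(fileext = ".json")
  tsv <- tempfile(fileext = ".tsv")
  write_quality_report(rep1, json, tsv)
  back <- read_quality_report(json)
  expect_equal(back$correlation$average, rep1$correlation$average)
  expect_equal(back$baseline_average, rep1$baseline_average)
  expect_equal(back$tests$p_value, rep1$tests$p_value)
  expect_true(file.exists(tsv))
  flat <- utils::read.delim(tsv)
  expect_true(all(c("feature", "metric", "value", "pass") %in% names(flat)))
})

test_that("KS p-values are approximately uniform under the null", {
  # two halves of one i.i.d. sample, 200 seeded replicates
  schema <- mini_schema()
  pvals <- vapply(1:200, function(r) {
    set.seed(1000 + r)
    x <- stats::rnorm(200)
    a <- tabular_dataset(cbind(x1 = x[1:100]), NULL, schema, validate = FALSE)
    b <- tabular_dataset(cbind(x1 = x[101:200]), NULL, schema, validate = FALSE)
    distribution_tests(a, b)$p_value
  }, numeric(1))
  frac <- mean(pvals < 0.05)
  expect_gte(frac, 0.01)
  expect_lte(frac, 0.12)
})

test_that("generator preserves the reference correlation structure", {
  ref <- sample_synthetic(heart_reference_generator(), 5000, seed = 3)
  gen <- fit_generator(ref, seed = 1)
  synth <- sample_synthetic(gen, 5000, seed = 5)
  expect_lte(correlation_mae(ref, synth)$average, 0.03)
})
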