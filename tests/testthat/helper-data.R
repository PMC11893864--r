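# Fixtures are built in code: small schemas, seeded reference samples from
# the bundled heart population, and a linearly separable toy problem.

# Four wide-range numeric predictors + binary target: room for constructed
# data (separable clusters, i.i.d. noise) without domain violations.
toy_schema <- function(d = 4L) {
  preds <- lapply(seq_len(d), function(j) {
    feature_spec(paste0("x", j), "numeric", c(-1000, 1000))
  })
  feature_schema(preds, feature_spec("target", "nominal", 0:1))
}

# One numeric feature; used for null-calibration studies.
mini_schema <- function() {
  feature_schema(list(feature_spec("x1", "numeric", c(-1000, 1000))),
                 feature_spec("target", "nominal", 0:1))
}

# Two well-separated class-conditional Gaussian clusters: any sensible
# linear separator achieves zero errors.
separable_ds <- function(n = 200L, seed = 1L, d = 4L, gap = 8) {
  schema <- toy_schema(d)
  set.seed(seed)
  labels <- rep(c(0L, 1L), length.out = n)
  values <- matrix(stats::rnorm(n * d, sd = 0.5), n, d) + gap * labels
  colnames(values) <- paste0("x", seq_len(d))
  tabular_dataset(values, labels, schema, validate = FALSE)
}

# Seeded draw from the bundled heart reference population.
heart_sample <- function(n = 200L, seed = 1L) {
  sample_synthetic(heart_reference_generator(), n, seed = seed)
}

write_ds_csv <- function(ds, path = tempfile(fileext = ".csv")) {
  write_dataset(ds, path)
  path
}

# CSV text fixture with all 14 heart columns (deliberately shuffled order).
heart_csv_lines <- function() {
  c("sex,age,cp,trestbps,chol,fbs,restecg,thalach,exang,oldpeak,slope,ca,thal,target",
    "1,63,3,145,233,1,0,150,0,2.3,0,0,1,1",
    "1,37,2,130,250,0,1,187,0,3.5,0,0,2,1",
    "0,41,1,130,204,0,0,172,0,1.4,2,0,2,0")
}
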