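# Hand-built two-omics dataset where feature moments are easy to reason about.
prep_fixture <- function() {
  ids <- sprintf("S%02d", 1:8)
  # omics "a": four features with variances 0, 0.1, 1, 2 (up to sampling),
  # constructed from scaled standard normals plus distinct means
  set.seed(11)
  base <- scale(matrix(rnorm(8 * 3), 8, 3))  # exactly unit-variance columns
  a <- cbind(rep(5, 8),
             base[, 1] * sqrt(0.1) + 1,
             base[, 2] * 1 + 2,
             base[, 3] * sqrt(2) + 3)
  dimnames(a) <- list(ids, paste0("a", 1:4))
  b <- matrix(rnorm(8 * 5, mean = 2), 8, 5, dimnames = list(ids, paste0("b", 1:5)))
  align_samples(list(omics_matrix(a, "a"), omics_matrix(b, "b")),
                endpoint_labels("OS", ids, c(1, 0, 1, 0, 1, 0, 1, 0)))
}

test_that("variance filtering drops features below the variance quantile", {
  ds <- prep_fixture()
  v <- apply(ds$matrices$a$values, 2, var)
  expect_equal(unname(v), c(0, 0.1, 1, 2), tolerance = 1e-12)

  # independent oracle: the 0.5 quantile of (0, .1, 1, 2) is 0.55 (type-7),
  # so exactly the two features with variance 1 and 2 survive
  fp <- fit_preprocessor(ds, preprocess_spec(variance_quantile = 0.5,
                                             mean_quantile = 0))
  expect_identical(fp$omics$a$kept_feature_ids, c("a3", "a4"))

  # a constant column is dropped whenever variance filtering is on
  fp2 <- fit_preprocessor(ds, preprocess_spec(variance_quantile = 0.1,
                                              mean_quantile = 0))
  expect_false("a1" %in% fp2$omics$a$kept_feature_ids)

  # quantiles of 1 would drop everything and are rejected up front
  expect_error(preprocess_spec(variance_quantile = 1), "< 1")
})

test_that("zero quantiles with standardization off keep non-constant features", {
  ds <- tiny_dataset(n = 30, dims = c(10L, 6L), seed = 2)
  fp <- fit_preprocessor(ds, preprocess_spec(0, 0, NULL, standardize = FALSE))
  out <- apply_preprocessor(fp, ds)
  expect_identical(out$matrices$omics1$values, ds$matrices$omics1$values)
  expect_identical(out$matrices$omics2$values, ds$matrices$omics2$values)
})

test_that("standardization uses training statistics and clips at the z-cap", {
  ds <- prep_fixture()
  fp <- fit_preprocessor(ds, preprocess_spec(0, 0, outlier_z_cap = 3))
  out <- apply_preprocessor(fp, ds)
  for (m in out$matrices) {
    expect_lt(max(abs(colMeans(m$values))), 1e-9)
    expect_lt(max(abs(apply(m$values, 2, sd) - 1)), 1e-9)
  }

  # inject a 10-sd point into fresh "test" data: it clips to exactly the cap
  ds2 <- ds
  mu <- fp$omics$b$center[1]; sdev <- fp$omics$b$scale[1]
  ds2$matrices$b$values[1, 1] <- mu + 10 * sdev
  out2 <- apply_preprocessor(fp, ds2)
  expect_identical(out2$matrices$b$values[1, 1], 3)

  # applying twice to the same input gives identical output
  expect_identical(apply_preprocessor(fp, ds2), out2)
})

test_that("preprocessor fitting never sees held-out data", {
  ds <- tiny_dataset(n = 40, dims = c(12L, 8L), seed = 5)
  tr <- subset_samples(ds, 1:30)
  fp1 <- fit_preprocessor(tr, preprocess_spec())
  # perturb only held-out samples: the fit is bit-identical
  ds2 <- ds
  ds2$matrices$omics1$values[31:40, ] <- 999
  ds2$labels$y[31:40] <- 1L
  fp2 <- fit_preprocessor(subset_samples(ds2, 1:30), preprocess_spec())
  expect_identical(fp1, fp2)
})

test_that("raising the variance quantile never keeps more features", {
  ds <- tiny_dataset(n = 50, dims = c(30L, 12L), seed = 7)
  counts <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(q) {
    fp <- fit_preprocessor(ds, preprocess_spec(variance_quantile = q,
                                               mean_quantile = 0))
    length(fp$omics$omics1$kept_feature_ids)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("refitting on preprocessed training output keeps every feature", {
  ds <- tiny_dataset(n = 40, dims = c(20L, 10L), seed = 8)
  spec <- preprocess_spec(variance_quantile = 0.3, mean_quantile = 0.2)
  fp <- fit_preprocessor(ds, spec)
  out <- apply_preprocessor(fp, ds)
  # after standardization all features are identical in mean/variance, so the
  # quantile filters cannot discriminate further (ties keep everything)
  fp2 <- fit_preprocessor(out, spec)
  for (nm in names(fp$omics))
    expect_identical(fp2$omics[[nm]]$kept_feature_ids,
                     fp$omics[[nm]]$kept_feature_ids)
})

test_that("a spec that removes all features of an omics names that omics", {
  ids <- sprintf("S%d", 1:6)
  a <- matrix(rep(c(1, 2), each = 6), 6, 2, dimnames = list(ids, c("f1", "f2")))
  ds <- align_samples(list(omics_matrix(a, "flat")),
                      endpoint_labels("OS", ids, c(1, 0, 1, 0, 1, 0)))
  expect_error(fit_preprocessor(ds, preprocess_spec()), "flat")
})

test_that("fitted preprocessors round-trip through JSON", {
  ds <- tiny_dataset(n = 30, dims = c(15L, 8L), seed = 9)
  fp <- fit_preprocessor(ds, preprocess_spec(0.25, 0.25, 4))
  f <- tempfile(fileext = ".json")
  write_preprocessor(fp, f)
  fp2 <- read_preprocessor(f)
  expect_identical(fp2$omics$omics1$kept_feature_ids, fp$omics$omics1$kept_feature_ids)
  expect_equal(fp2$omics$omics2$center, fp$omics$omics2$center)
  expect_equal(fp2$omics$omics2$scale, fp$omics$omics2$scale)
  expect_equal(apply_preprocessor(fp2, ds)$matrices$omics1$values,
               apply_preprocessor(fp, ds)$matrices$omics1$values,
               tolerance = 1e-12)
})
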