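test_that("roc_auc reproduces worked examples and handles ties", {
  expect_identical(roc_auc(c(0.9, 0.1), c(1, 0)), 1)
  expect_identical(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  # 4 samples, 4 positive-negative pairs, 3 concordant
  expect_identical(roc_auc(c(0.2, 0.7, 0.4, 0.3), c(0, 1, 0, 1)), 0.75)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "both classes")
  expect_error(roc_auc(c(1, NA), c(1, 0)), "NA")
})

test_that("roc_auc equals brute-force pairwise concordance on random cases", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))  # both classes guaranteed
    scores <- if (i %% 3 == 0) sample(1:5, n, replace = TRUE) / 5  # many ties
              else rnorm(n)
    expect_equal(roc_auc(scores, y), auc_brute(scores, y), tolerance = 1e-12)
  }
})

test_that("roc_auc agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n), 1)  # include ties
    ref <- suppressMessages(as.numeric(pROC::auc(y, scores,
                                                 direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(scores, y), ref, tolerance = 1e-12)
  }
})

test_that("roc_auc is invariant under strictly increasing transforms", {
  set.seed(5)
  scores <- rnorm(40)
  y <- c(0, 1, rbinom(38, 1, 0.5))
  a <- roc_auc(scores, y)
  expect_identical(roc_auc(exp(scores), y), a)
  expect_identical(roc_auc(rank(scores, ties.method = "average"), y), a)
  expect_identical(roc_auc(100 + 3 * scores, y), a)
})

test_that("zero epochs leave parameters untouched with empty history", {
  ds <- tiny_dataset(n = 20, dims = c(25L, 10L), seed = 2)
  cfg <- tiny_config(epochs = 0L)
  m <- build_model(cfg, input_dims = omics_dims(ds))
  fit <- train_mosae(m, ds, cfg)
  expect_identical(fit$model$params, m$params)
  expect_length(fit$history, 0)
})

test_that("training is bit-deterministic given data, config and seed", {
  ds <- tiny_dataset(n = 30, dims = c(25L, 10L), seed = 8)
  cfg <- tiny_config(epochs = 4L, seed = 31)
  m <- build_model(cfg, input_dims = omics_dims(ds))
  f1 <- train_mosae(m, ds, cfg)
  f2 <- train_mosae(m, ds, cfg)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(as.data.frame(f1$history), as.data.frame(f2$history))
})

test_that("training reduces the composite loss end-to-end", {
  ds <- tiny_dataset(n = 60, dims = c(30L, 12L), seed = 3)
  cfg <- tiny_config(epochs = 40L, seed = 4)
  m <- build_model(cfg, input_dims = omics_dims(ds))
  fit <- train_mosae(m, ds, cfg)
  h <- as.data.frame(fit$history)
  expect_identical(nrow(h), 40L)
  expect_lt(h$total[40], h$total[1])
})

test_that("loss decomposition holds for every recorded training step", {
  ds <- tiny_dataset(n = 24, dims = c(20L, 8L), seed = 6)
  cfg <- tiny_config(epochs = 3L, batch_size = 8L)
  m <- build_model(cfg, input_dims = omics_dims(ds))
  fit <- train_mosae(m, ds, cfg, record = "step")
  expect_length(fit$history, 3 * 3)  # 24 samples / batch 8 = 3 steps/epoch
  for (lc in fit$history)
    expect_equal(lc$total,
                 sum(lc$recon) + lc$alpha * sum(lc$pred) + lc$beta * lc$fusion_pred,
                 tolerance = 1e-9)
})

test_that("an omics feature that equals the label is learned almost perfectly", {
  ds <- tiny_dataset(n = 120, dims = c(20L, 8L), seed = 9)
  ds$matrices$omics1$values[, 1] <- ds$labels$y  # plant a perfect feature
  cfg <- tiny_config(epochs = 50L, learning_rate = 5e-3, seed = 2)
  res <- cross_validate(ds, mosae_variant(), cfg, n_folds = 3, seed = 7,
                        prep = preprocess_spec(0, 0, NULL, standardize = TRUE))
  expect_gte(res$mean, 0.95)
})

test_that("permuted labels score near chance", {
  ds <- tiny_dataset(n = 90, dims = c(15L, 8L), seed = 10)
  cfg <- tiny_config(epochs = 15L)
  for (perm_seed in 1:2) {
    ds_null <- ds
    set.seed(perm_seed)
    ds_null$labels$y <- sample(ds$labels$y)
    res <- cross_validate(ds_null, mosae_variant(), cfg, n_folds = 3, seed = 1)
    expect_gte(res$mean, 0.5 - 0.12)
    expect_lte(res$mean, 0.5 + 0.12)
  }
})

test_that("cross-validation rejects degenerate fold requests", {
  ds <- tiny_dataset(n = 20, dims = c(10L, 6L), seed = 12)
  expect_error(cross_validate(ds, n_folds = 1), ">= 2")
  expect_error(cross_validate(ds, mosae_variant(), tiny_config(), n_folds = 20),
               "at least 2 samples")
})

test_that("cv_result statistics are consistent with fold AUCs", {
  ds <- tiny_dataset(n = 40, dims = c(15L, 6L), seed = 14)
  res <- cross_validate(ds, mosae_variant(), tiny_config(epochs = 3L),
                        n_folds = 4, seed = 3)
  expect_length(res$fold_auc, 4)
  expect_true(all(res$fold_auc >= 0 & res$fold_auc <= 1))
  expect_equal(res$mean, mean(res$fold_auc), tolerance = 1e-12)
  expect_equal(res$sd, sd(res$fold_auc), tolerance = 1e-12)
})

test_that("frozen-head baselines train their branches without label access", {
  ds <- tiny_dataset(n = 40, dims = c(20L, 8L), seed = 15)
  base <- tiny_config(epochs = 5L)
  built <- build_variant(variant_from_name("plain-AE"), omics_dims(ds), base)
  fit1 <- train_mosae(built, ds)
  # flip every label: branch parameters must be identical, head may differ
  ds_flip <- ds
  ds_flip$labels$y <- 1L - ds_flip$labels$y
  built2 <- build_variant(variant_from_name("plain-AE"), omics_dims(ds_flip), base)
  fit2 <- train_mosae(built2, ds_flip)
  expect_identical(fit1$model$params$branches, fit2$model$params$branches)
  expect_false(identical(fit1$model$params$fusion, fit2$model$params$fusion))
})
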