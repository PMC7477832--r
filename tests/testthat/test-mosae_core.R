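test_that("dimension grouping uses the strict threshold rule", {
  # the four pan-cancer layers: methylation/RNA-Seq high, miRNA/RPPA low
  expect_identical(assign_dimension_group(4183, 1000), "high")
  expect_identical(assign_dimension_group(4720, 1000), "high")
  expect_identical(assign_dimension_group(658, 1000), "low")
  expect_identical(assign_dimension_group(210, 1000), "low")
  # boundary: p == threshold is low (strict inequality)
  expect_identical(assign_dimension_group(1000, 1000), "low")
})

test_that("specific-layer widths must compress the high group and expand the low", {
  expect_error(specific_ae_config("x", 50, "high", 50, 10), "compressing")
  expect_error(specific_ae_config("x", 50, "low", 50, 10), "expanding")
  ok <- specific_ae_config("x", 50, "high", 20, 10)
  expect_s3_class(ok, "specific_ae_config")
})

test_that("builder reproduces the reference architecture and is seed-deterministic", {
  dims <- c(methylation = 4183L, mirna = 658L, rnaseq = 4720L, rppa = 210L)
  cfg <- mosae_config(seed = 3)  # reference widths 100/1000, latent 400
  m <- build_model(cfg, input_dims = dims)
  expect_identical(encoder_widths(m),
                   list(c(4183L, 100L, 400L), c(658L, 1000L, 400L),
                        c(4720L, 100L, 400L), c(210L, 1000L, 400L)))
  expect_true(all(vapply(m$params$branches,
                         function(b) identical(dim(b$decoder$W)[1], 400L),
                         logical(1))))

  m2 <- build_model(cfg, input_dims = dims)
  expect_identical(m$params, m2$params)
  cfg2 <- cfg; cfg2$seed <- 4L
  expect_false(identical(build_model(cfg2, input_dims = dims)$params, m$params))
})

test_that("fusion averages latent codes elementwise and ignores omics order", {
  # brute-force per-cell oracle on random matrices
  set.seed(20)
  Hs <- lapply(1:3, function(i) matrix(rnorm(20), 4, 5))
  fused <- fuse_average(Hs)
  oracle <- matrix(0, 4, 5)
  for (r in 1:4) for (c in 1:5)
    oracle[r, c] <- mean(c(Hs[[1]][r, c], Hs[[2]][r, c], Hs[[3]][r, c]))
  expect_equal(fused, oracle, tolerance = 1e-15)
  # addition order changes only the last ulp
  expect_equal(fuse_average(Hs[c(3, 1, 2)]), fused, tolerance = 1e-12)
  expect_identical(fuse_average(list(Hs[[1]], Hs[[1]])), Hs[[1]])
  expect_equal(fuse_average(list(matrix(0), matrix(2))), matrix(1))
  expect_error(fuse_average(list(matrix(0, 2, 2), matrix(0, 2, 3))), "shape")
})

test_that("forward pass fuses engineered latent codes as their mean", {
  cfg <- mosae_config(latent_dim = 2, high_width = 2, low_width = 9,
                      dim_threshold = 4, activation = "linear", seed = 1)
  m <- build_model(cfg, input_dims = c(a = 5, b = 3))
  # weight surgery: zero the encoder paths, set latent biases directly
  for (i in 1:2) {
    m$params$branches[[i]]$specific$W[] <- 0
    m$params$branches[[i]]$encoder$W[] <- 0
  }
  m$params$branches[[1]]$encoder$b <- c(1, 3)
  m$params$branches[[2]]$encoder$b <- c(3, 1)
  out <- mosae_forward(m, list(matrix(0, 1, 5), matrix(0, 1, 3)))
  expect_equal(out$H[[1]], matrix(c(1, 3), 1), ignore_attr = TRUE)
  expect_equal(out$H_fusion, matrix(c(2, 2), 1), ignore_attr = TRUE)
})

test_that("with one omics the fused code equals that branch's code", {
  cfg <- tiny_config()
  m <- build_model(cfg, input_dims = c(x = 30))
  X <- matrix(rnorm(150), 5, 30)
  out <- mosae_forward(m, list(X))
  expect_identical(out$H_fusion, out$H[[1]])
})

test_that("fused outputs are invariant to omics order given matched weights", {
  cfg <- tiny_config(seed = 6)
  ds <- tiny_dataset(n = 12, dims = c(25L, 10L), seed = 6)
  X <- lapply(ds$matrices, `[[`, "values")
  m <- build_model(cfg, input_dims = omics_dims(ds))
  out <- mosae_forward(m, X)

  m_rev <- m
  m_rev$meta$branches <- m$meta$branches[2:1]
  m_rev$params$branches <- m$params$branches[2:1]
  out_rev <- mosae_forward(m_rev, X[2:1])
  expect_equal(out_rev$H_fusion, out$H_fusion, tolerance = 1e-6)
  expect_equal(out_rev$Y_fusion, out$Y_fusion, tolerance = 1e-6)
})

test_that("loss components match hand-computed values and the weight algebra", {
  cfg <- mosae_config(prediction_loss = "mse", latent_dim = 1)
  # single omics, X = [[1, 0]], reconstruction [[0, 0]], predictions 0.5
  outputs <- structure(list(
    H = list(matrix(0, 1, 1)), X_recon = list(matrix(0, 1, 2)),
    Y_hat = list(0.5), H_fusion = matrix(0, 1, 1), Y_fusion = 0.5),
    class = "mosae_outputs")
  lc <- mosae_loss(outputs, list(matrix(c(1, 0), 1, 2)), 1, cfg)
  expect_identical(lc$recon, 1)
  expect_identical(lc$pred, 0.25)
  expect_identical(lc$fusion_pred, 0.25)
  expect_identical(lc$total, 1.5)

  # perfect fit gives zero loss
  perfect <- structure(list(
    H = list(matrix(0, 1, 1)), X_recon = list(matrix(c(1, 0), 1, 2)),
    Y_hat = list(1 - 1e-7), H_fusion = matrix(0, 1, 1), Y_fusion = 1 - 1e-7),
    class = "mosae_outputs")
  expect_lt(mosae_loss(perfect, list(matrix(c(1, 0), 1, 2)), 1, cfg)$total, 1e-10)

  # alpha = beta = 0 leaves the pure multi-autoencoder objective
  cfg0 <- mosae_config(alpha = 0, beta = 0, prediction_loss = "mse")
  lc0 <- mosae_loss(outputs, list(matrix(c(1, 0), 1, 2)), 1, cfg0)
  expect_identical(lc0$total, sum(lc0$recon))

  expect_error(mosae_loss(outputs, list(matrix(c(1, 0), 1, 2)), 2, cfg), "0/1")
})

test_that("probabilities stay strictly inside (0, 1)", {
  cfg <- tiny_config(activation = "linear")
  m <- build_model(cfg, input_dims = c(x = 30))
  m$params$fusion$b <- 1e4  # push the fused logit to saturation
  m$params$branches[[1]]$predictor$b <- -1e4
  out <- mosae_forward(m, list(matrix(rnorm(90), 3, 30)))
  expect_true(all(out$Y_fusion > 0 & out$Y_fusion < 1))
  expect_true(all(out$Y_hat[[1]] > 0 & out$Y_hat[[1]] < 1))
})

test_that("backprop matches central finite differences across variants", {
  ds <- tiny_dataset(n = 8, dims = c(12L, 5L), seed = 13)
  y <- ds$labels$y
  dims <- omics_dims(ds)
  cases <- list(
    list(cfg = mosae_config(latent_dim = 3, high_width = 4, low_width = 9,
                            dim_threshold = 6, seed = 2),
         fusion = "ave", dec = TRUE, pred = TRUE, specific = TRUE),
    list(cfg = mosae_config(latent_dim = 3, high_width = 4, low_width = 9,
                            dim_threshold = 6, cat_latent_dim = 3, seed = 3),
         fusion = "cat", dec = TRUE, pred = TRUE, specific = TRUE),
    list(cfg = mosae_config(latent_dim = 3, high_width = 4, low_width = 9,
                            dim_threshold = 6, alpha = 0, seed = 4),
         fusion = "ave", dec = FALSE, pred = FALSE, specific = TRUE),
    list(cfg = mosae_config(latent_dim = 3, high_width = 4, low_width = 9,
                            dim_threshold = 6, prediction_loss = "mse",
                            activation = "relu", seed = 5),
         fusion = "ave", dec = TRUE, pred = TRUE, specific = FALSE))
  for (cs in cases) {
    m <- build_model(cs$cfg, input_dims = dims, fusion = cs$fusion,
                     decoders = cs$dec, predictors = cs$pred,
                     specific = cs$specific)
    X <- lapply(ds$matrices, `[[`, "values")
    err <- max_grad_rel_error(m, X, y, cs$cfg, stride = 5L)
    expect_lt(err, 1e-4)
  }
})

test_that("mismatched shapes fail naming the offending branch", {
  cfg <- tiny_config()
  m <- build_model(cfg, input_dims = c(meth = 25, rppa = 10))
  expect_error(mosae_forward(m, list(matrix(0, 2, 25), matrix(0, 2, 11))),
               "rppa")
  expect_error(mosae_forward(m, list(matrix(0, 2, 25))), "2 branches")
})

test_that("models round-trip through the archive with manifest", {
  cfg <- tiny_config(seed = 12)
  m <- build_model(cfg, input_dims = c(x = 25, y = 8))
  f <- tempfile(fileext = ".rds")
  save_mosae_model(m, f)
  m2 <- load_mosae_model(f)
  expect_identical(m2$params, m$params)
  manifest <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_identical(manifest$latent_dim, 8L)
})
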