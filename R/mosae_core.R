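#' Assign an omics layer to the high- or low-dimension group
#'
#' Omics layers are treated differently by width: high-dimensional layers
#' (e.g. genome-wide methylation or RNA-Seq with thousands of features) are
#' routed through a narrow "compression" layer, while low-dimensional layers
#' (e.g. miRNA-Seq or RPPA with a few hundred features) are first "expanded"
#' to a wider nonlinear feature space.
#'
#' @param p number of features of the omics layer.
#' @param dim_threshold grouping threshold; `p > dim_threshold` means high.
#'   The default 1000 separates thousands-wide layers from hundreds-wide ones.
#' @return `"high"` or `"low"`.
#' @export
#' @examples
#' assign_dimension_group(4183, 1000) # "high"
#' assign_dimension_group(210, 1000)  # "low"
assign_dimension_group <- function(p, dim_threshold = 1000L) {
  p <- assert_count(p, "p")
  dim_threshold <- assert_count(dim_threshold, "dim_threshold")
  if (p > dim_threshold) "high" else "low"
}

#' Per-omics autoencoder architecture
#'
#' Describes one omics branch: an omics-specific first layer (compression
#' network for high-dimensional omics, expansion network for low-dimensional
#' ones) followed by an encoder to the shared latent width `k`. The latent
#' width must be identical across omics so latent codes can be averaged.
#'
#' @param omics_name branch label.
#' @param input_dim number of input features `p`.
#' @param group `"high"` or `"low"` (see [assign_dimension_group]).
#' @param specific_width width of the omics-specific layer; must compress
#'   (`< input_dim`) for the high group and expand (`> input_dim`) for the
#'   low group.
#' @param latent_dim shared latent width `k`.
#' @param activation hidden-layer nonlinearity (`"relu"`, `"tanh"`,
#'   `"sigmoid"` or `"linear"`).
#' @return an object of class `specific_ae_config`.
#' @export
specific_ae_config <- function(omics_name, input_dim, group, specific_width,
                               latent_dim, activation = "relu") {
  input_dim <- assert_count(input_dim, "input_dim")
  specific_width <- assert_count(specific_width, "specific_width")
  latent_dim <- assert_count(latent_dim, "latent_dim")
  group <- match.arg(group, c("high", "low"))
  if (group == "high" && specific_width >= input_dim)
    stop_mosae(sprintf("omics '%s': high-dimension group requires a compressing specific layer (width %d >= input %d)",
                       omics_name, specific_width, input_dim))
  if (group == "low" && specific_width <= input_dim)
    stop_mosae(sprintf("omics '%s': low-dimension group requires an expanding specific layer (width %d <= input %d)",
                       omics_name, specific_width, input_dim))
  structure(list(omics_name = as.character(omics_name), input_dim = input_dim,
                 group = group, specific_width = specific_width,
                 latent_dim = latent_dim, activation = activation),
            class = "specific_ae_config")
}

#' Model and training configuration
#'
#' Collects the loss weights, architecture widths and optimizer
#' hyperparameters. Defaults follow the reference setup: compression width 100
#' for high-dimensional omics, expansion width 1000 for low-dimensional ones,
#' shared latent width 400, loss weights `alpha = beta = 1`, grouping
#' threshold 1000.
#'
#' @param alpha weight on the per-omics prediction loss (>= 0).
#' @param beta weight on the fused prediction loss (>= 0).
#' @param prediction_loss `"cross-entropy"` (default, binary endpoints) or
#'   `"mse"`.
#' @param latent_dim shared latent width `k` for average fusion.
#' @param cat_latent_dim per-branch latent width used by concatenation fusion
#'   (so that with M branches the fused width is `cat_latent_dim * M`).
#' @param high_width,low_width specific-layer widths for the high/low groups.
#' @param dim_threshold feature-count threshold for [assign_dimension_group].
#' @param activation hidden-layer nonlinearity; predictor outputs are always
#'   sigmoid and reconstruction outputs linear. `tanh` is the default: its
#'   sign-symmetric codes average more gracefully across omics than
#'   rectifier codes, whose nonnegativity wastes half of each fused latent
#'   direction (`"relu"` and `"linear"` remain available).
#' @param learning_rate,epochs,batch_size Adam optimizer settings.
#' @param lr_decay per-epoch multiplicative learning-rate decay (1 = none).
#' @param head_epochs epochs for the separate head-fitting stage used by
#'   frozen-representation baselines (defaults to `epochs`).
#' @param seed integer seed; weight initialization and batch shuffling use
#'   sub-seeds derived from it.
#' @param ae_configs optional list of [specific_ae_config]; when `NULL`,
#'   configurations are derived from the data dimensions at build time.
#' @return an object of class `mosae_config`.
#' @export
mosae_config <- function(alpha = 1, beta = 1,
                         prediction_loss = c("cross-entropy", "mse"),
                         latent_dim = 400L, cat_latent_dim = 100L,
                         high_width = 100L, low_width = 1000L,
                         dim_threshold = 1000L, activation = "tanh",
                         learning_rate = 1e-3, epochs = 200L, batch_size = 64L,
                         lr_decay = 1, head_epochs = NULL, seed = 1L,
                         ae_configs = NULL) {
  structure(list(
    alpha = assert_number(alpha, "alpha", min = 0),
    beta = assert_number(beta, "beta", min = 0),
    prediction_loss = match.arg(prediction_loss),
    latent_dim = assert_count(latent_dim, "latent_dim"),
    cat_latent_dim = assert_count(cat_latent_dim, "cat_latent_dim"),
    high_width = assert_count(high_width, "high_width"),
    low_width = assert_count(low_width, "low_width"),
    dim_threshold = assert_count(dim_threshold, "dim_threshold"),
    activation = activation,
    learning_rate = assert_number(learning_rate, "learning_rate", min = 0),
    epochs = assert_count(epochs, "epochs", min = 0L),
    batch_size = assert_count(batch_size, "batch_size"),
    lr_decay = assert_number(lr_decay, "lr_decay", min = 1e-6, max = 1),
    head_epochs = if (is.null(head_epochs)) NULL else assert_count(head_epochs, "head_epochs", min = 0L),
    seed = assert_count(seed, "seed", min = 0L),
    ae_configs = ae_configs), class = "mosae_config")
}

#' Derive per-omics architecture configs from data dimensions
#'
#' @param input_dims named integer vector of per-omics feature counts.
#' @param config a [mosae_config].
#' @param latent_dim latent width override (used by concatenation fusion).
#' @return list of [specific_ae_config].
#' @export
make_ae_configs <- function(input_dims, config, latent_dim = config$latent_dim) {
  nms <- names(input_dims) %||% paste0("omics", seq_along(input_dims))
  lapply(seq_along(input_dims), function(i) {
    p <- input_dims[[i]]
    group <- assign_dimension_group(p, config$dim_threshold)
    width <- if (group == "high") config$high_width else config$low_width
    specific_ae_config(nms[i], p, group, width, latent_dim, config$activation)
  })
}

#' Build a MOSAE model
#'
#' One branch per omics: omics-specific layer (compression or expansion),
#' encoder to the shared latent width, linear decoder back to the input
#' width, and an affine+sigmoid predictor head on the latent code. Latent
#' codes are fused (element-wise average by default) and a fused
#' affine+sigmoid predictor produces the model's prediction of record.
#' Initialization is deterministic given `config$seed`.
#'
#' @param config a [mosae_config]; either carries `ae_configs` or
#'   `input_dims` must be given.
#' @param input_dims named per-omics feature counts (used when
#'   `config$ae_configs` is `NULL`).
#' @param fusion `"ave"` (element-wise mean of latent codes) or `"cat"`
#'   (concatenation).
#' @param decoders,predictors include per-branch decoders / predictor heads
#'   (disabled by ablation variants).
#' @param specific include the omics-specific first layer.
#' @return an object of class `mosae_model` with elements `meta` (architecture
#'   description) and `params` (weight matrices and biases).
#' @export
build_model <- function(config, input_dims = NULL, fusion = c("ave", "cat"),
                        decoders = TRUE, predictors = TRUE, specific = TRUE) {
  stopifnot(inherits(config, "mosae_config"))
  fusion <- match.arg(fusion)
  latent <- if (fusion == "cat") config$cat_latent_dim else config$latent_dim
  acs <- config$ae_configs
  if (is.null(acs)) {
    if (is.null(input_dims))
      stop_mosae("either config$ae_configs or input_dims must be provided")
    if (specific) {
      acs <- make_ae_configs(input_dims, config, latent_dim = latent)
    } else {
      # no omics-specific layer: every branch encodes input -> latent directly
      nms <- names(input_dims) %||% paste0("omics", seq_along(input_dims))
      acs <- lapply(seq_along(input_dims), function(i)
        structure(list(omics_name = nms[i], input_dim = as.integer(input_dims[[i]]),
                       group = NA_character_, specific_width = NA_integer_,
                       latent_dim = latent, activation = config$activation),
                  class = "specific_ae_config"))
    }
  }
  ks <- vapply(acs, `[[`, numeric(1), "latent_dim")
  if (length(unique(ks)) != 1L)
    stop_mosae("all omics branches must share one latent width")
  latent <- as.integer(ks[1L])
  M <- length(acs)
  fused_dim <- if (fusion == "cat") latent * M else latent

  params <- with_seed(derive_seed(config$seed, 1L), {
    branches <- lapply(acs, function(ac) {
      has_spec <- !is.na(ac$specific_width)
      enc_in <- if (has_spec) ac$specific_width else ac$input_dim
      list(
        specific  = if (has_spec) init_dense(ac$input_dim, ac$specific_width, ac$activation),
        encoder   = init_dense(enc_in, latent, ac$activation),
        decoder   = if (decoders) init_dense(latent, ac$input_dim, "linear"),
        predictor = if (predictors) init_dense(latent, 1L, "sigmoid"))
    })
    list(branches = branches, fusion = init_dense(fused_dim, 1L, "sigmoid"))
  })

  meta <- list(
    branches = lapply(acs, function(ac) list(
      name = ac$omics_name, input_dim = ac$input_dim, group = ac$group,
      specific_width = ac$specific_width,
      has_specific = !is.na(ac$specific_width),
      has_decoder = decoders, has_predictor = predictors)),
    M = M, latent_dim = latent, fusion_type = fusion, fused_dim = fused_dim,
    activation = config$activation)
  structure(list(meta = meta, params = params), class = "mosae_model")
}

#' @export
print.mosae_model <- function(x, ...) {
  cat(sprintf("<mosae_model> %d branch(es), latent %d, fusion %s\n",
              x$meta$M, x$meta$latent_dim, x$meta$fusion_type))
  for (b in x$meta$branches) {
    chain <- if (b$has_specific)
      sprintf("%d -> %d -> %d", b$input_dim, b$specific_width, x$meta$latent_dim)
    else sprintf("%d -> %d", b$input_dim, x$meta$latent_dim)
    cat(sprintf("  %-16s encoder %s%s%s\n", b$name, chain,
                if (b$has_decoder) sprintf(", decoder -> %d", b$input_dim) else "",
                if (b$has_predictor) ", predictor head" else ""))
  }
  invisible(x)
}

#' Encoder layer widths of each branch
#' @param model a `mosae_model`.
#' @return list of integer vectors, e.g. `c(4183, 100, 400)`.
#' @export
encoder_widths <- function(model) {
  lapply(model$meta$branches, function(b)
    if (b$has_specific) c(b$input_dim, b$specific_width, model$meta$latent_dim)
    else c(b$input_dim, model$meta$latent_dim))
}

#' Average-fuse latent representations
#'
#' Element-wise mean of M equally shaped latent matrices. Averaging (rather
#' than concatenating) forces corresponding latent dimensions of different
#' omics to carry the same meaning, and is symmetric in omics order.
#'
#' @param H_list list of N x k numeric matrices.
#' @return N x k matrix, the element-wise mean.
#' @export
fuse_average <- function(H_list) {
  if (!length(H_list)) stop_mosae("empty latent list")
  d <- dim(H_list[[1L]])
  for (H in H_list)
    if (!identical(dim(H), d))
      stop_mosae("all latent matrices must share the same N x k shape")
  Reduce(`+`, H_list) / length(H_list)
}

# Forward pass keeping intermediate activations for backprop.
forward_cache <- function(model, X_list) {
  meta <- model$meta
  if (length(X_list) != meta$M)
    stop_mosae(sprintf("model has %d branches but %d matrices were supplied",
                       meta$M, length(X_list)))
  act <- activation_fun(meta$activation)
  caches <- vector("list", meta$M)
  for (i in seq_len(meta$M)) {
    b <- meta$branches[[i]]
    p <- model$params$branches[[i]]
    X <- X_list[[i]]
    if (!is.matrix(X)) X <- as.matrix(X)
    if (ncol(X) != b$input_dim)
      stop_mosae(sprintf("branch '%s' expects %d features, got %d",
                         b$name, b$input_dim, ncol(X)))
    if (b$has_specific) {
      Z1 <- sweep_add(X %*% p$specific$W, p$specific$b)
      A1 <- act(Z1)
    } else {
      Z1 <- NULL; A1 <- X
    }
    Zh <- sweep_add(A1 %*% p$encoder$W, p$encoder$b)
    H <- act(Zh)
    Xr <- if (b$has_decoder) sweep_add(H %*% p$decoder$W, p$decoder$b)
    logit_p <- if (b$has_predictor) drop(H %*% p$predictor$W) + p$predictor$b
    caches[[i]] <- list(X = X, Z1 = Z1, A1 = A1, Zh = Zh, H = H, Xr = Xr,
                        logit = logit_p)
  }
  H_list <- lapply(caches, `[[`, "H")
  H_fus <- if (meta$fusion_type == "ave") fuse_average(H_list) else do.call(cbind, H_list)
  logit_f <- drop(H_fus %*% model$params$fusion$W) + model$params$fusion$b
  list(branches = caches, H_fus = H_fus, logit_f = logit_f)
}

sweep_add <- function(M, b) {
  if (length(b) == 1L) M + b else M + rep(b, each = nrow(M))
}

#' Run the model forward
#'
#' @param model a `mosae_model`.
#' @param X_list list of M numeric matrices (samples x features, matching the
#'   branch input widths). A `multi_omics_dataset` is also accepted.
#' @return an object of class `mosae_outputs`: per-branch latent codes `H`,
#'   reconstructions `X_recon`, predicted probabilities `Y_hat`, the fused
#'   code `H_fusion` and fused probability `Y_fusion`. Probabilities are
#'   clamped to the open interval (0, 1).
#' @export
mosae_forward <- function(model, X_list) {
  if (inherits(X_list, "multi_omics_dataset"))
    X_list <- lapply(X_list$matrices, `[[`, "values")
  cache <- forward_cache(model, X_list)
  structure(list(
    H = lapply(cache$branches, `[[`, "H"),
    X_recon = lapply(cache$branches, `[[`, "Xr"),
    Y_hat = lapply(cache$branches, function(cb)
      if (is.null(cb$logit)) NULL else sigmoid_clamp(stats::plogis(cb$logit))),
    H_fusion = cache$H_fus,
    Y_fusion = sigmoid_clamp(stats::plogis(cache$logit_f))),
    class = "mosae_outputs")
}

prediction_loss_value <- function(y, p, kind) {
  p <- sigmoid_clamp(p)
  if (kind == "cross-entropy") -sum(y * log(p) + (1 - y) * log(1 - p))
  else sum((y - p)^2)
}

#' Composite MOSAE loss
#'
#' `total = sum_i ||X_i - Xrec_i||_F^2 + alpha * sum_i L(y, Yhat_i)
#'  + beta * L(y, Y_fusion)` where `L` is binary cross-entropy or squared
#' error, summed over samples (batch averaging happens in the optimizer, not
#' here, so `alpha`/`beta` weight loss sums of comparable convention).
#' All label usage is concentrated in this one loss, which is what keeps
#' held-out labels out of representation learning during cross-validation.
#'
#' @param outputs a [mosae_forward] result.
#' @param X_list list of the M input matrices.
#' @param y binary 0/1 label vector.
#' @param config a [mosae_config] (uses `alpha`, `beta`, `prediction_loss`).
#' @return an object of class `loss_components`: `recon` (length M), `pred`
#'   (length M), `fusion_pred`, `total`.
#' @export
mosae_loss <- function(outputs, X_list, y, config) {
  if (inherits(X_list, "multi_omics_dataset"))
    X_list <- lapply(X_list$matrices, `[[`, "values")
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop_mosae("labels must be 0/1")
  M <- length(X_list)
  recon <- vapply(seq_len(M), function(i) {
    if (is.null(outputs$X_recon[[i]])) 0 else sum((X_list[[i]] - outputs$X_recon[[i]])^2)
  }, numeric(1))
  pred <- vapply(seq_len(M), function(i) {
    if (is.null(outputs$Y_hat[[i]])) 0
    else prediction_loss_value(y, outputs$Y_hat[[i]], config$prediction_loss)
  }, numeric(1))
  fusion_pred <- prediction_loss_value(y, outputs$Y_fusion, config$prediction_loss)
  structure(list(recon = recon, pred = pred, fusion_pred = fusion_pred,
                 alpha = config$alpha, beta = config$beta,
                 total = sum(recon) + config$alpha * sum(pred) +
                   config$beta * fusion_pred),
            class = "loss_components")
}

#' @export
print.loss_components <- function(x, ...) {
  cat(sprintf("<loss_components> total %.6g (recon %.6g, pred %.6g, fusion %.6g)\n",
              x$total, sum(x$recon), sum(x$pred), x$fusion_pred))
  invisible(x)
}

# Gradient of the (sum-convention) composite loss wrt every parameter.
# Returns a tree parallel to model$params, plus the loss components evaluated
# at the same parameters (shared intermediates, so recording a training
# history costs no extra forward pass). Derivation is plain backprop through
# affine layers; for sigmoid + cross-entropy the logit gradient is (p - y),
# for sigmoid + squared error it is 2 (p - y) p (1 - p).
mosae_backward <- function(model, X_list, y, config, cache = NULL) {
  meta <- model$meta
  if (is.null(cache)) cache <- forward_cache(model, X_list)
  dact <- activation_grad(meta$activation)
  alpha <- config$alpha; beta <- config$beta
  N <- length(y)

  logit_grad <- function(logit, weight) {
    p <- stats::plogis(logit)
    g <- if (config$prediction_loss == "cross-entropy") p - y
         else 2 * (p - y) * p * (1 - p)
    weight * g
  }

  dlf <- logit_grad(cache$logit_f, beta)                        # N
  gW_f <- crossprod(cache$H_fus, matrix(dlf, ncol = 1L))        # fused_dim x 1
  gb_f <- sum(dlf)
  dH_fus <- matrix(dlf, ncol = 1L) %*% t(model$params$fusion$W) # N x fused_dim

  k <- meta$latent_dim
  gbranches <- vector("list", meta$M)
  recon <- numeric(meta$M)
  pred <- numeric(meta$M)
  for (i in seq_len(meta$M)) {
    b <- meta$branches[[i]]
    p <- model$params$branches[[i]]
    cb <- cache$branches[[i]]
    dH <- if (meta$fusion_type == "ave") dH_fus / meta$M
          else dH_fus[, ((i - 1L) * k + 1L):(i * k), drop = FALSE]
    g <- list(specific = NULL, encoder = NULL, decoder = NULL, predictor = NULL)
    if (b$has_decoder) {
      R <- cb$Xr - X_list[[i]]
      recon[i] <- sum(R * R)
      dXr <- 2 * R
      g$decoder <- list(W = crossprod(cb$H, dXr), b = colSums(dXr))
      dH <- dH + dXr %*% t(p$decoder$W)
    }
    if (b$has_predictor) {
      pred[i] <- prediction_loss_value(y, stats::plogis(cb$logit),
                                       config$prediction_loss)
      dlp <- logit_grad(cb$logit, alpha)
      g$predictor <- list(W = crossprod(cb$H, matrix(dlp, ncol = 1L)), b = sum(dlp))
      dH <- dH + matrix(dlp, ncol = 1L) %*% t(p$predictor$W)
    }
    dZh <- dH * dact(cb$Zh, cb$H)
    g$encoder <- list(W = crossprod(cb$A1, dZh), b = colSums(dZh))
    if (b$has_specific) {
      dA1 <- dZh %*% t(p$encoder$W)
      dZ1 <- dA1 * dact(cb$Z1, cb$A1)
      g$specific <- list(W = crossprod(cb$X, dZ1), b = colSums(dZ1))
    }
    gbranches[[i]] <- g
  }
  fusion_pred <- prediction_loss_value(y, stats::plogis(cache$logit_f),
                                       config$prediction_loss)
  list(grads = list(branches = gbranches, fusion = list(W = gW_f, b = gb_f)),
       loss = structure(list(recon = recon, pred = pred,
                             fusion_pred = fusion_pred,
                             alpha = alpha, beta = beta,
                             total = sum(recon) + alpha * sum(pred) +
                               beta * fusion_pred),
                        class = "loss_components"))
}
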