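#' Train a model by mini-batch Adam on the composite loss
#'
#' Batch order is derived deterministically from `config$seed`, so the same
#' data, configuration and seed reproduce bit-identical parameters. Gradients
#' are averaged over the batch (the loss itself is a sum, see [mosae_loss]).
#' For `frozen_head` variants training has two stages: the branches are first
#' fitted on reconstruction alone (no label use), then the fused prediction
#' head is fitted on the frozen latent code.
#'
#' @param model a `mosae_model` (or a [build_variant] result, whose adjusted
#'   config then takes precedence).
#' @param train_data a `multi_omics_dataset`, or a list of input matrices
#'   matching the model's branches.
#' @param config a [mosae_config].
#' @param y binary labels (taken from `train_data` when it is a dataset).
#' @param record `"epoch"` records loss components once per epoch on the full
#'   training set; `"step"` records after every optimizer step (for
#'   diagnostics on small problems).
#' @return list with `model` (trained) and `history` (class `mosae_history`:
#'   list of `loss_components` in recording order).
#' @export
train_mosae <- function(model, train_data, config = NULL, y = NULL,
                        record = c("epoch", "step")) {
  record <- match.arg(record)
  spec <- NULL
  if (is.list(model) && !inherits(model, "mosae_model") && !is.null(model$model)) {
    spec <- model$spec
    config <- config %||% model$config
    model <- model$model
  }
  stopifnot(inherits(model, "mosae_model"), inherits(config, "mosae_config"))
  if (inherits(train_data, "multi_omics_dataset")) {
    y <- y %||% train_data$labels$y
    X_list <- if (!is.null(spec)) variant_inputs(spec, train_data)
              else lapply(train_data$matrices, `[[`, "values")
  } else {
    X_list <- train_data
  }
  if (is.null(y)) stop_mosae("labels are required for training")
  if (!is.null(spec) && spec$frozen_head)
    return(train_frozen_head(model, X_list, y, config, record))

  fit <- train_loop(model$params, model$meta, X_list, y, config,
                    epochs = config$epochs, record = record)
  model$params <- fit$params
  list(model = model,
       history = structure(fit$history, class = "mosae_history"))
}

# Core Adam loop over mini-batches; `freeze` restricts updates to the fusion
# head (used by the frozen-head second stage).
train_loop <- function(params, meta, X_list, y, config, epochs, record,
                       head_only = FALSE) {
  model <- structure(list(meta = meta, params = params), class = "mosae_model")
  n <- length(y)
  batch_size <- min(config$batch_size, n)
  state <- adam_state(params)
  history <- list()
  if (epochs > 0L) {
    batch_orders <- with_seed(derive_seed(config$seed, 2L),
      lapply(seq_len(epochs), function(e) sample.int(n)))
    lr_decay <- config$lr_decay %||% 1
    for (e in seq_len(epochs)) {
      ord <- batch_orders[[e]]
      starts <- seq(1L, n, by = batch_size)
      lr_e <- config$learning_rate * lr_decay^(e - 1L)
      epoch_loss <- NULL
      for (s in starts) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        Xb <- lapply(X_list, function(X) X[idx, , drop = FALSE])
        yb <- y[idx]
        bk <- mosae_backward(model, Xb, yb, config)
        grads <- map_params(function(g) g / length(idx), bk$grads)
        if (head_only)
          grads$branches <- map_params(function(g) g * 0, grads$branches)
        upd <- adam_step(model$params, grads, state, lr_e)
        model$params <- upd$params
        state <- upd$state
        if (record == "step") {
          history[[length(history) + 1L]] <- bk$loss
        } else {
          # training loss of the epoch = sum of batch losses (standard
          # running convention; evaluated at the parameters each batch saw)
          epoch_loss <- if (is.null(epoch_loss)) bk$loss else
            structure(list(recon = epoch_loss$recon + bk$loss$recon,
                           pred = epoch_loss$pred + bk$loss$pred,
                           fusion_pred = epoch_loss$fusion_pred + bk$loss$fusion_pred,
                           alpha = bk$loss$alpha, beta = bk$loss$beta,
                           total = epoch_loss$total + bk$loss$total),
                      class = "loss_components")
        }
      }
      if (record == "epoch")
        history[[length(history) + 1L]] <- epoch_loss
      last <- history[[length(history)]]
      if (!is.finite(last$total)) {
        bad <- c(recon = !all(is.finite(last$recon)),
                 pred = !all(is.finite(last$pred)),
                 fusion_pred = !is.finite(last$fusion_pred))
        stop_mosae(sprintf("training diverged at epoch %d (non-finite %s); lower the learning rate",
                           e, paste(names(bad)[bad], collapse = ", ")))
      }
    }
  }
  list(params = model$params, history = history)
}

# Stage 1: reconstruction-only branch training (alpha = beta = 0, labels
# untouched). Stage 2: fused head alone, fitted by the same mini-batch Adam
# on the now-frozen latent codes (computed once).
train_frozen_head <- function(model, X_list, y, config, record) {
  cfg1 <- config; cfg1$alpha <- 0; cfg1$beta <- 0
  fit1 <- train_loop(model$params, model$meta, X_list, y, cfg1,
                     epochs = config$epochs, record = record)
  model$params <- fit1$params

  cache <- forward_cache(model, X_list)
  H_fus <- cache$H_fus
  head <- model$params$fusion
  state <- adam_state(head)
  head_epochs <- config$head_epochs %||% config$epochs
  n <- length(y)
  batch_size <- min(config$batch_size, n)
  history2 <- list()
  if (head_epochs > 0L) {
    batch_orders <- with_seed(derive_seed(config$seed, 3L),
      lapply(seq_len(head_epochs), function(e) sample.int(n)))
    lr_decay <- config$lr_decay %||% 1
    for (e in seq_len(head_epochs)) {
      ord <- batch_orders[[e]]
      lr_e <- config$learning_rate * lr_decay^(e - 1L)
      for (s in seq(1L, n, by = batch_size)) {
        idx <- ord[s:min(s + batch_size - 1L, n)]
        Hb <- H_fus[idx, , drop = FALSE]
        yb <- y[idx]
        logit <- drop(Hb %*% head$W) + head$b
        p <- stats::plogis(logit)
        dl <- if (config$prediction_loss == "cross-entropy") p - yb
              else 2 * (p - yb) * p * (1 - p)
        g <- list(W = crossprod(Hb, matrix(dl, ncol = 1L)) / length(idx),
                  b = sum(dl) / length(idx))
        upd <- adam_step(head, g, state, lr_e)
        head <- upd$params
        state <- upd$state
      }
      logit <- drop(H_fus %*% head$W) + head$b
      fl <- prediction_loss_value(y, stats::plogis(logit), config$prediction_loss)
      history2[[e]] <- structure(
        list(recon = numeric(model$meta$M), pred = numeric(model$meta$M),
             fusion_pred = fl, alpha = 0, beta = config$beta,
             total = config$beta * fl),
        class = "loss_components")
    }
  }
  model$params$fusion <- head
  list(model = model,
       history = structure(c(fit1$history, history2), class = "mosae_history"))
}

#' @export
as.data.frame.mosae_history <- function(x, ...) {
  data.frame(step = seq_along(x),
             recon = vapply(x, function(l) sum(l$recon), numeric(1)),
             pred = vapply(x, function(l) sum(l$pred), numeric(1)),
             fusion_pred = vapply(x, `[[`, numeric(1), "fusion_pred"),
             total = vapply(x, `[[`, numeric(1), "total"))
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) formula: the fraction of
#' positive-negative pairs ranked concordantly, ties counting one half. This
#' equals the probability that a random positive sample outscores a random
#' negative one (the C-index).
#'
#' @param scores numeric score vector (higher = more positive).
#' @param y binary 0/1 labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.2, 0.7, 0.4, 0.3), c(0, 1, 0, 1)) # 0.75
roc_auc <- function(scores, y) {
  if (length(scores) != length(y)) stop_mosae("scores and labels differ in length")
  if (anyNA(scores) || anyNA(y)) stop_mosae("scores and labels must not contain NA")
  if (!all(y %in% c(0, 1))) stop_mosae("labels must be 0/1")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0L || n_neg == 0L)
    stop_mosae("ROC AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Score a dataset with a trained model
#'
#' @param object a trained `mosae_model` or a [train_mosae] result.
#' @param newdata a `multi_omics_dataset` or input matrix list.
#' @param spec the `variant_spec` the model was built for (needed to
#'   concatenate inputs for single-branch variants).
#' @param ... unused.
#' @return numeric vector of fused predicted probabilities.
#' @export
predict.mosae_model <- function(object, newdata, spec = NULL, ...) {
  X_list <- if (inherits(newdata, "multi_omics_dataset")) {
    if (!is.null(spec)) variant_inputs(spec, newdata)
    else lapply(newdata$matrices, `[[`, "values")
  } else newdata
  mosae_forward(object, X_list)$Y_fusion
}

#' Cross-validated ROC AUC of one variant
#'
#' For every fold: fit the preprocessor on the training folds only, transform
#' both partitions with the training statistics, build and train the variant,
#' then score the held-out fold with the fused prediction head. Held-out
#' values and labels are never seen by preprocessing or training, which the
#' test suite checks at bit level.
#'
#' @param dataset a `multi_omics_dataset`.
#' @param variant a [variant_spec] (default: the full model).
#' @param base a [mosae_config]; per-fold models train with sub-seeds derived
#'   from `seed`.
#' @param n_folds number of folds (>= 2; every held-out fold must contain
#'   both classes and at least 2 samples, so leave-one-out is rejected).
#' @param seed integer seed driving fold shuffling and per-fold model
#'   initialization.
#' @param prep a [preprocess_spec].
#' @param stratified stratify folds on the labels (default TRUE).
#' @param folds optional precomputed `fold_assignment` (used for paired
#'   variant comparisons).
#' @param keep_fits keep per-fold fitted preprocessors and models (for
#'   audits); off by default to save memory.
#' @return an object of class `cv_result`: `endpoint`, `variant`, `fold_auc`,
#'   `mean`, `sd` (sample standard deviation across folds, n-1 denominator),
#'   `n_folds`, `seed`; with `keep_fits`, a `fits` list.
#' @export
cross_validate <- function(dataset, variant = mosae_variant(),
                           base = mosae_config(), n_folds = 5L, seed = 1L,
                           prep = preprocess_spec(), stratified = TRUE,
                           folds = NULL, keep_fits = FALSE) {
  stopifnot(inherits(dataset, "multi_omics_dataset"),
            inherits(variant, "variant_spec"))
  n_folds <- assert_count(n_folds, "n_folds", min = 2L)
  if (is.null(folds))
    folds <- split_folds(dataset, n_folds, seed = derive_seed(seed, 0L),
                         stratified = stratified)
  stopifnot(inherits(folds, "fold_assignment"), folds$n_folds == n_folds)
  fold_auc <- numeric(n_folds)
  fits <- if (keep_fits) vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    te_idx <- which(folds$fold_of == f)
    tr_idx <- which(folds$fold_of != f)
    if (length(te_idx) < 2L)
      stop_mosae("held-out folds need at least 2 samples (leave-one-out is not supported: AUC is undefined on single-sample folds)")
    y_te <- dataset$labels$y[te_idx]
    if (length(unique(y_te)) < 2L)
      stop_mosae(sprintf("fold %d holds only one label class; use stratified folds", f))
    train_ds <- subset_samples(dataset, tr_idx)
    test_ds <- subset_samples(dataset, te_idx)
    fp <- fit_preprocessor(train_ds, prep)
    train_pp <- apply_preprocessor(fp, train_ds)
    test_pp <- apply_preprocessor(fp, test_ds)
    cfg <- base
    cfg$seed <- derive_seed(seed, f)
    built <- build_variant(variant, omics_dims(train_pp), cfg)
    fit <- train_mosae(built, train_pp)
    scores <- predict(fit$model, test_pp, spec = variant)
    fold_auc[f] <- roc_auc(scores, y_te)
    if (keep_fits)
      fits[[f]] <- list(preprocessor = fp, model = fit$model,
                        history = fit$history)
  }
  structure(list(endpoint = dataset$labels$endpoint, variant = variant$name,
                 fold_auc = fold_auc, mean = mean(fold_auc),
                 sd = stats::sd(fold_auc), n_folds = n_folds,
                 seed = as.integer(seed), fits = fits),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s on %s: AUC %.4f(±%.4f) over %d folds\n",
              x$variant, x$endpoint, x$mean, x$sd, x$n_folds))
  invisible(x)
}

#' Write cross-validation results as TSV
#'
#' Writes `<prefix>_folds.tsv` (columns variant, endpoint, fold, auc) and
#' `<prefix>_summary.tsv` (variant, endpoint, mean_auc, sd_auc, formatted to
#' 4 decimals). Output is byte-identical across reruns with the same config
#' and seed.
#'
#' @param results a `cv_result` or list of them.
#' @param prefix output path prefix.
#' @return character vector of the files written, invisibly.
#' @export
write_cv_result <- function(results, prefix) {
  if (inherits(results, "cv_result")) results <- list(results)
  folds <- do.call(rbind, lapply(results, function(r)
    data.frame(variant = r$variant, endpoint = r$endpoint,
               fold = seq_len(r$n_folds),
               auc = sprintf("%.6f", r$fold_auc))))
  summary <- do.call(rbind, lapply(results, function(r)
    data.frame(variant = r$variant, endpoint = r$endpoint,
               mean_auc = sprintf("%.4f", r$mean),
               sd_auc = sprintf("%.4f", r$sd))))
  paths <- paste0(prefix, c("_folds.tsv", "_summary.tsv"))
  data.table::fwrite(folds, paths[1L], sep = "\t", quote = FALSE)
  data.table::fwrite(summary, paths[2L], sep = "\t", quote = FALSE)
  invisible(paths)
}

#' Save / load a trained model
#'
#' The archive stores the architecture description and all weights; a JSON
#' manifest next to it records omics names, layer widths and the seed for
#' audit without loading the archive.
#'
#' @param model a `mosae_model`.
#' @param path archive path (`.rds`).
#' @return `save_mosae_model`: `path` invisibly; `load_mosae_model`: the
#'   model.
#' @export
save_mosae_model <- function(model, path) {
  stopifnot(inherits(model, "mosae_model"))
  saveRDS(model, path)
  manifest <- list(
    branches = lapply(model$meta$branches, function(b)
      list(name = b$name, input_dim = b$input_dim, group = b$group,
           specific_width = if (b$has_specific) b$specific_width else NULL)),
    latent_dim = model$meta$latent_dim, fusion = model$meta$fusion_type,
    activation = model$meta$activation)
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_mosae_model
#' @export
load_mosae_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "mosae_model"))
  model
}
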