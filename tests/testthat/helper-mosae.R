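# Shared fixtures and independent oracles, all built in code.

# Small synthetic dataset for fast unit tests.
tiny_dataset <- function(n = 80, dims = c(40L, 16L), seed = 1L, d = 3L,
                         weights = rep(1 / length(dims), length(dims))) {
  generate_multiomics(synthetic_params(
    n_samples = n, omics_dims = dims, latent_dim = max(d, length(dims)),
    signal_weights = weights, seed = seed))
}

# Config sized for toy problems (threshold chosen so the first layer of
# tiny_dataset is "high", the second "low").
tiny_config <- function(..., latent_dim = 8L, high_width = 12L,
                        low_width = 60L, dim_threshold = 20L, epochs = 10L,
                        batch_size = 32L, learning_rate = 3e-3, seed = 1L) {
  mosae_config(latent_dim = latent_dim, high_width = high_width,
               low_width = low_width, dim_threshold = dim_threshold,
               epochs = epochs, batch_size = batch_size,
               learning_rate = learning_rate, seed = seed, ...)
}

# Brute-force pairwise-concordance AUC: the independent oracle for roc_auc.
auc_brute <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Flatten a parameter tree into (path, index) leaf references, for
# finite-difference checks.
param_leaves <- function(tree, path = integer()) {
  if (is.null(tree)) return(list())
  if (is.list(tree))
    return(unlist(lapply(seq_along(tree), function(i)
      param_leaves(tree[[i]], c(path, i))), recursive = FALSE))
  lapply(seq_along(tree), function(j) list(path = path, j = j))
}

leaf_get <- function(tree, path) {
  for (i in path) tree <- tree[[i]]
  tree
}

leaf_modify <- function(tree, path, j, delta) {
  if (!length(path)) {
    tree[j] <- tree[j] + delta
    return(tree)
  }
  tree[[path[1]]] <- leaf_modify(tree[[path[1]]], path[-1], j, delta)
  tree
}

# Central finite-difference gradient of the composite loss at a sample of
# parameter coordinates; returns the max relative disagreement with backprop.
max_grad_rel_error <- function(model, X_list, y, config, stride = 7L,
                               h = 1e-5) {
  bk <- mosae:::mosae_backward(model, X_list, y, config)
  loss_at <- function(params) {
    m2 <- model
    m2$params <- params
    mosae_loss(mosae_forward(m2, X_list), X_list, y, config)$total
  }
  leaves <- param_leaves(model$params)
  worst <- 0
  for (lf in leaves[seq(1, length(leaves), by = stride)]) {
    up <- loss_at(leaf_modify(model$params, lf$path, lf$j, h))
    dn <- loss_at(leaf_modify(model$params, lf$path, lf$j, -h))
    fd <- (up - dn) / (2 * h)
    an <- leaf_get(bk$grads, lf$path)[lf$j]
    worst <- max(worst, abs(fd - an) / max(1e-6, abs(fd) + abs(an)))
  }
  worst
}

# Collect every weight matrix/bias as one numeric vector (bit-level
# comparisons of trained models).
flatten_params <- function(params) {
  out <- numeric(0)
  rec <- function(x) {
    if (is.null(x)) return()
    if (is.list(x)) { for (el in x) rec(el); return() }
    out <<- c(out, as.numeric(x))
  }
  rec(params)
  out
}
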