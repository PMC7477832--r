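# Minimal dense-network machinery: parameter trees, activations and Adam.
# Model parameters live in nested lists whose leaves are numeric matrices or
# vectors; map_params() walks several parallel trees at once, which keeps the
# optimizer independent of any particular architecture.

map_params <- function(f, ...) {
  trees <- list(...)
  rec <- function(nodes) {
    x1 <- nodes[[1L]]
    if (is.null(x1)) return(NULL)
    if (is.list(x1)) {
      out <- vector("list", length(x1))
      names(out) <- names(x1)
      for (i in seq_along(x1))
        out[i] <- list(rec(lapply(nodes, `[[`, i)))  # [i] <- list(): keep NULLs
      out
    } else {
      do.call(f, nodes)
    }
  }
  rec(trees)
}

activation_fun <- function(name) {
  switch(name,
    relu    = function(z) { z[z < 0] <- 0; z },
    linear  = function(z) z,
    tanh    = function(z) tanh(z),
    sigmoid = function(z) stats::plogis(z),
    stop_mosae(sprintf("unknown activation '%s'", name)))
}

# derivative wrt pre-activation z, given z and a = act(z)
activation_grad <- function(name) {
  switch(name,
    relu    = function(z, a) (z > 0) * 1,
    linear  = function(z, a) 1,
    tanh    = function(z, a) 1 - a^2,
    sigmoid = function(z, a) a * (1 - a),
    stop_mosae(sprintf("unknown activation '%s'", name)))
}

# He-style initialization for rectifiers, Xavier-style otherwise; biases zero.
# Deterministic under the caller-supplied RNG state.
init_dense <- function(fan_in, fan_out, activation) {
  sd <- if (activation == "relu") sqrt(2 / fan_in) else sqrt(1 / fan_in)
  list(W = matrix(stats::rnorm(fan_in * fan_out, sd = sd), fan_in, fan_out),
       b = numeric(fan_out))
}

adam_state <- function(params) {
  list(m = map_params(function(x) x * 0, params),
       v = map_params(function(x) x * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map_params(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- map_params(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  lr_t <- lr * sqrt(1 - beta2^state$t) / (1 - beta1^state$t)
  params <- map_params(function(p, m, v) p - lr_t * m / (sqrt(v) + eps),
                       params, state$m, state$v)
  list(params = params, state = state)
}

sigmoid_clamp <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)
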