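#' Parameters of the synthetic multi-omics generator
#'
#' The generator emulates the structure of a pan-cancer multi-omics cohort:
#' M sample-aligned feature matrices of widely differing widths, all driven by
#' a shared low-dimensional latent factor, with a binary clinical endpoint
#' whose predictive signal is split across the omics layers. Each omics gets
#' one private latent coordinate that only it measures; the remaining
#' coordinates are background structure loaded by every omics. The label
#' score is a weighted combination of the private coordinates, so no single
#' omics carries the full signal unless its weight is 1 — the situation in
#' which fusing omics should beat any single layer.
#'
#' @param n_samples number of samples.
#' @param omics_dims integer vector of per-omics feature counts; the default
#'   `c(4000, 650, 4500, 200)` mirrors the magnitude ordering of DNA
#'   methylation, miRNA-Seq, RNA-Seq and RPPA layers (two high-, two
#'   low-dimensional at grouping threshold 1000).
#' @param latent_dim dimension `d` of the shared factor (must be >= number of
#'   omics; coordinates beyond the first M are shared background).
#' @param signal_weights fraction of the label signal carried by each omics;
#'   nonnegative, summing to 1.
#' @param noise_sd standard deviation of the additive feature noise.
#' @param prevalence expected fraction of positive labels, in (0, 1).
#' @param effect_size slope of the logistic label model on the (unit-variance)
#'   latent score; 2 gives a Bayes AUC ceiling around 0.8, comparable to a
#'   well-predictable clinical endpoint.
#' @param omics_names optional branch names (defaults to
#'   methylation/mirna/rnaseq/rppa when M = 4).
#' @param endpoint endpoint name for the labels.
#' @param seed integer seed; generation is fully reproducible from it.
#' @return an object of class `synthetic_params`.
#' @export
synthetic_params <- function(n_samples = 600L,
                             omics_dims = c(4000L, 650L, 4500L, 200L),
                             latent_dim = 5L,
                             signal_weights = rep(1 / length(omics_dims),
                                                  length(omics_dims)),
                             noise_sd = 1, prevalence = 0.3, effect_size = 2,
                             omics_names = NULL, endpoint = "OS", seed = 1L) {
  n_samples <- assert_count(n_samples, "n_samples", min = 4L)
  omics_dims <- vapply(omics_dims, assert_count, integer(1), name = "omics_dims", min = 2L)
  M <- length(omics_dims)
  latent_dim <- assert_count(latent_dim, "latent_dim", min = 1L)
  if (latent_dim < M)
    stop_mosae("latent_dim must be >= the number of omics (one private coordinate each)")
  if (length(signal_weights) != M || any(signal_weights < 0))
    stop_mosae("signal_weights must be M nonnegative values")
  if (abs(sum(signal_weights) - 1) > 1e-9)
    stop_mosae("signal_weights must sum to 1")
  prevalence <- assert_number(prevalence, "prevalence")
  if (prevalence <= 0 || prevalence >= 1)
    stop_mosae("prevalence must be strictly inside (0, 1)")
  if (is.null(omics_names))
    omics_names <- if (M == 4L) c("methylation", "mirna", "rnaseq", "rppa")
                   else paste0("omics", seq_len(M))
  if (length(omics_names) != M) stop_mosae("omics_names must match omics_dims")
  structure(list(n_samples = n_samples, omics_dims = omics_dims,
                 latent_dim = latent_dim,
                 signal_weights = as.numeric(signal_weights),
                 noise_sd = assert_number(noise_sd, "noise_sd", min = 1e-12),
                 prevalence = prevalence,
                 effect_size = assert_number(effect_size, "effect_size", min = 0),
                 omics_names = as.character(omics_names),
                 endpoint = endpoint, seed = assert_count(seed, "seed", min = 0L)),
            class = "synthetic_params")
}

# Intercept b such that E_{s ~ N(0,1)}[ plogis(effect * s + b) ] = prevalence.
label_intercept <- function(effect_size, prevalence) {
  target <- function(b)
    stats::integrate(function(s) stats::plogis(effect_size * s + b) * stats::dnorm(s),
                     -Inf, Inf, rel.tol = 1e-10)$value - prevalence
  stats::uniroot(target, c(-50, 50), tol = 1e-10)$root
}

#' Generate a synthetic multi-omics dataset
#'
#' Draws a shared standard-normal factor `z` per sample; omics `i` observes
#' its private coordinate `z_i` plus the shared background coordinates
#' through random Gaussian loadings, with additive noise. Labels follow
#' `y ~ Bernoulli(plogis(effect_size * s + b))` where the score
#' `s = sum_i sqrt(w_i) z_i` has unit variance and the intercept `b` is
#' solved numerically so that `E[y]` equals the requested prevalence.
#'
#' @param params a [synthetic_params].
#' @return a `multi_omics_dataset`; attribute `"generator_truth"` carries the
#'   latent factors, true score and intercept for oracle checks.
#' @export
generate_multiomics <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  M <- length(params$omics_dims)
  n <- params$n_samples
  d <- params$latent_dim
  b0 <- label_intercept(params$effect_size, params$prevalence)
  out <- with_seed(params$seed, {
    z <- matrix(stats::rnorm(n * d), n, d)
    s <- drop(z[, seq_len(M), drop = FALSE] %*% sqrt(params$signal_weights))
    y <- stats::rbinom(n, 1L, stats::plogis(params$effect_size * s + b0))
    mats <- lapply(seq_len(M), function(i) {
      coords <- c(i, if (d > M) (M + 1L):d)
      p <- params$omics_dims[i]
      W <- matrix(stats::rnorm(length(coords) * p, sd = 1 / sqrt(length(coords))),
                  length(coords), p)
      X <- z[, coords, drop = FALSE] %*% W +
        matrix(stats::rnorm(n * p, sd = params$noise_sd), n, p)
      dimnames(X) <- list(sprintf("S%05d", seq_len(n)),
                          sprintf("%s_f%04d", params$omics_names[i], seq_len(p)))
      omics_matrix(X, params$omics_names[i])
    })
    list(mats = mats, z = z, s = s, y = y)
  })
  if (length(unique(out$y)) < 2L)
    stop_mosae("generated labels are single-class; increase n_samples or move prevalence away from 0/1")
  labels <- endpoint_labels(params$endpoint, sprintf("S%05d", seq_len(n)), out$y)
  ds <- align_samples(out$mats, labels)
  attr(ds, "generator_truth") <- list(z = out$z, score = out$s,
                                      intercept = b0, params = params)
  ds
}

#' Monte-Carlo Bayes AUC ceiling of the generative model
#'
#' AUC of the true latent score against labels drawn from the label model —
#' the performance ceiling no classifier trained on the observed matrices can
#' exceed beyond sampling error, because the observed data are conditionally
#' independent of the labels given that score.
#'
#' @param params a [synthetic_params].
#' @param n_mc number of Monte-Carlo draws (>= 1e4).
#' @param seed seed for the Monte-Carlo draw (defaults to `params$seed`).
#' @return estimated AUC in `[0, 1]`.
#' @export
bayes_auc_estimate <- function(params, n_mc = 1e5, seed = params$seed) {
  stopifnot(inherits(params, "synthetic_params"))
  n_mc <- assert_count(n_mc, "n_mc", min = 1e4)
  b0 <- label_intercept(params$effect_size, params$prevalence)
  with_seed(derive_seed(seed, 9L), {
    s <- stats::rnorm(n_mc)
    y <- stats::rbinom(n_mc, 1L, stats::plogis(params$effect_size * s + b0))
    roc_auc(s, y)
  })
}

#' Write / read a multi-omics dataset as TSV plus a JSON sidecar
#'
#' One TSV per omics (the dialect [read_omics_matrix] understands), a
#' two-column label TSV, and `dataset.json` recording omics names, sample
#' order and the endpoint.
#'
#' @param dataset a `multi_omics_dataset`.
#' @param dir output (input) directory.
#' @return `write_multiomics`: `dir` invisibly; `read_multiomics`: a
#'   `multi_omics_dataset`.
#' @export
write_multiomics <- function(dataset, dir) {
  stopifnot(inherits(dataset, "multi_omics_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  for (m in dataset$matrices) {
    f <- file.path(dir, paste0(m$omics_name, ".tsv"))
    write_omics_matrix(m, f)
    files[[m$omics_name]] <- basename(f)
  }
  lab <- data.frame(sample_id = dataset$labels$sample_ids, label = dataset$labels$y)
  data.table::fwrite(lab, file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE)
  sidecar <- list(omics = files, labels = "labels.tsv",
                  endpoint = dataset$labels$endpoint,
                  sample_ids = dataset$sample_ids)
  jsonlite::write_json(sidecar, file.path(dir, "dataset.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_multiomics
#' @export
read_multiomics <- function(dir) {
  sidecar_path <- file.path(dir, "dataset.json")
  if (!file.exists(sidecar_path))
    stop_mosae(sprintf("no dataset.json found in '%s'", dir))
  sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  mats <- lapply(names(sidecar$omics), function(nm)
    read_omics_matrix(file.path(dir, sidecar$omics[[nm]]), nm))
  labels <- read_labels(file.path(dir, sidecar$labels),
                        endpoint = sidecar$endpoint)
  align_samples(mats, labels)
}
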