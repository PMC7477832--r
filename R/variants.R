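#' Describe an ablation variant
#'
#' The model decomposes into switchable modules: MO (one branch per omics
#' vs. a single branch on the concatenated features), fusion mode (average
#' vs. concatenation of latent codes), Sup (per-branch supervised heads),
#' Spec (dimension-dependent specific layers) and the backbone (AE keeps
#' decoders and the reconstruction term; NN drops them). The full model is
#' `{AE, multi-omics, ave, supervised, specific}`; the plain autoencoder
#' baseline is `{AE, single-branch, unsupervised}` trained on reconstruction
#' only with a classifier head fitted afterwards on the frozen latent code.
#'
#' @param backbone `"AE"` (decoders + reconstruction loss) or `"NN"` (none).
#' @param multi_omics one branch per omics (`TRUE`) or a single branch on the
#'   concatenated feature matrix (`FALSE`).
#' @param fusion `"ave"` or `"cat"`; only meaningful with `multi_omics = TRUE`
#'   (supplying it otherwise is an error).
#' @param supervised per-branch prediction heads and loss terms (the Sup
#'   module); when off, `alpha` is forced to 0 and branches receive label
#'   signal only through the fused head.
#' @param specific dimension-dependent specific layers (the Spec module);
#'   when off every branch encodes input -> latent directly.
#' @param frozen_head train branches without any label use (reconstruction
#'   only), then fit the fused prediction head on the frozen latent code.
#'   Used by the plain-autoencoder baseline; requires `backbone = "AE"`.
#' @param name optional display name; derived from the switches when `NULL`.
#' @return an object of class `variant_spec`.
#' @export
variant_spec <- function(backbone = c("AE", "NN"), multi_omics = TRUE,
                         fusion = NULL, supervised = TRUE, specific = TRUE,
                         frozen_head = FALSE, name = NULL) {
  backbone <- match.arg(backbone)
  multi_omics <- assert_flag(multi_omics, "multi_omics")
  if (!multi_omics && !is.null(fusion))
    stop_mosae("fusion mode is only meaningful when multi_omics = TRUE")
  if (multi_omics) fusion <- match.arg(fusion %||% "ave", c("ave", "cat"))
  supervised <- assert_flag(supervised, "supervised")
  specific <- assert_flag(specific, "specific")
  frozen_head <- assert_flag(frozen_head, "frozen_head")
  if (frozen_head && backbone != "AE")
    stop_mosae("frozen_head training needs a reconstruction loss (backbone = 'AE')")
  if (frozen_head && supervised)
    stop_mosae("frozen_head contradicts supervised per-branch training")
  if (is.null(name)) {
    parts <- c(backbone,
               if (multi_omics) "MO",
               if (multi_omics) (if (fusion == "ave") "Ave" else "Cat"),
               if (supervised) "Sup",
               if (specific && multi_omics) "Spec")
    name <- paste(parts, collapse = "+")
  }
  structure(list(backbone = backbone, multi_omics = multi_omics,
                 fusion = fusion, supervised = supervised, specific = specific,
                 frozen_head = frozen_head, name = name),
            class = "variant_spec")
}

#' The full MOSAE variant
#' @return a [variant_spec] equal to `{AE, multi-omics, ave, supervised,
#'   specific}`.
#' @export
mosae_variant <- function() {
  variant_spec("AE", multi_omics = TRUE, fusion = "ave", supervised = TRUE,
               specific = TRUE, name = "MOSAE")
}

#' Standard ablation grids
#'
#' `module_ablation_grid()` switches the modules on one at a time, from the
#' plain autoencoder baseline up to the full model:
#' plain AE, MO+Cat, MO+Ave, MO+Ave+Sup, MO+Ave+Sup+Spec (= MOSAE).
#' `backbone_ablation_grid()` crosses the same module ladder with the AE vs.
#' NN backbone to isolate the contribution of the reconstruction term.
#'
#' @return named list of [variant_spec].
#' @export
module_ablation_grid <- function() {
  list(
    `plain-AE` = variant_spec("AE", multi_omics = FALSE, supervised = FALSE,
                              specific = FALSE, frozen_head = TRUE,
                              name = "plain-AE"),
    `MO+Cat` = variant_spec("AE", fusion = "cat", supervised = FALSE,
                            specific = FALSE, name = "MO+Cat"),
    `MO+Ave` = variant_spec("AE", fusion = "ave", supervised = FALSE,
                            specific = FALSE, name = "MO+Ave"),
    `MO+Ave+Sup` = variant_spec("AE", fusion = "ave", supervised = TRUE,
                                specific = FALSE, name = "MO+Ave+Sup"),
    `MO+Ave+Sup+Spec` = mosae_variant())
}

#' @rdname module_ablation_grid
#' @export
backbone_ablation_grid <- function() {
  grids <- list()
  for (bk in c("NN", "AE")) {
    grids[[bk]] <- variant_spec(bk, multi_omics = FALSE,
                                supervised = FALSE, specific = FALSE,
                                frozen_head = bk == "AE", name = bk)
    grids[[paste0(bk, "+MO+Ave")]] <-
      variant_spec(bk, fusion = "ave", supervised = FALSE, specific = FALSE)
    grids[[paste0(bk, "+MO+Ave+Sup")]] <-
      variant_spec(bk, fusion = "ave", supervised = TRUE, specific = FALSE)
    grids[[paste0(bk, "+MO+Ave+Sup+Spec")]] <-
      variant_spec(bk, fusion = "ave", supervised = TRUE, specific = TRUE)
  }
  grids
}

#' Parse a variant name such as "NN+MO+Ave+Sup"
#'
#' Recognized tokens: `AE`/`NN` backbone prefix, `MO`, `Ave`/`Cat`, `Sup`,
#' `Spec`, plus the special names `MOSAE` and `plain-AE`/`plain-NN`.
#'
#' @param name character variant name.
#' @return a [variant_spec].
#' @export
variant_from_name <- function(name) {
  if (name == "MOSAE") return(mosae_variant())
  if (name %in% c("plain-AE", "AE"))
    return(variant_spec("AE", multi_omics = FALSE, supervised = FALSE,
                        specific = FALSE, frozen_head = TRUE, name = name))
  if (name %in% c("plain-NN", "NN"))
    return(variant_spec("NN", multi_omics = FALSE, supervised = FALSE,
                        specific = FALSE, name = name))
  toks <- strsplit(name, "+", fixed = TRUE)[[1L]]
  backbone <- if (toks[1L] %in% c("AE", "NN")) { b <- toks[1L]; toks <- toks[-1L]; b } else "AE"
  bad <- setdiff(toks, c("MO", "Ave", "Cat", "Sup", "Spec"))
  if (length(bad))
    stop_mosae(sprintf("unknown variant token '%s' in '%s'", bad[1L], name))
  mo <- "MO" %in% toks
  variant_spec(backbone, multi_omics = mo,
               fusion = if (mo) (if ("Cat" %in% toks) "cat" else "ave"),
               supervised = "Sup" %in% toks, specific = "Spec" %in% toks,
               name = name)
}

#' Build the model for an ablation variant
#'
#' @param spec a [variant_spec].
#' @param dataset_dims named integer vector of per-omics feature counts.
#' @param base a [mosae_config].
#' @return list with the built `model` (class `mosae_model`) and the
#'   (possibly adjusted) `config` used to train it: `alpha` is forced to 0
#'   when per-branch supervision is off, and `alpha`/`beta` to 0 during the
#'   representation stage of frozen-head training.
#' @export
build_variant <- function(spec, dataset_dims, base) {
  stopifnot(inherits(spec, "variant_spec"), inherits(base, "mosae_config"))
  config <- base
  if (!spec$supervised) config$alpha <- 0
  if (spec$multi_omics) {
    model <- build_model(config, input_dims = dataset_dims,
                         fusion = spec$fusion,
                         decoders = spec$backbone == "AE",
                         predictors = spec$supervised,
                         specific = spec$specific)
  } else {
    total_p <- sum(dataset_dims)
    model <- build_model(config,
                         input_dims = stats::setNames(total_p, "concatenated"),
                         fusion = "ave",
                         decoders = spec$backbone == "AE",
                         predictors = spec$supervised,
                         specific = FALSE)
  }
  list(model = model, config = config, spec = spec)
}

# Assemble the input list a variant's model consumes: per-omics matrices for
# multi-omics variants, one concatenated matrix otherwise.
variant_inputs <- function(spec, dataset) {
  X <- lapply(dataset$matrices, `[[`, "values")
  if (spec$multi_omics) X else list(concatenated = do.call(cbind, unname(X)))
}

#' Run an ablation grid under paired cross-validation
#'
#' Every variant is evaluated with the same fold assignment (paired
#' comparison), the same preprocessing rules and the same seed-derived
#' initialization streams, so differences in mean AUC reflect the modules,
#' not fold luck.
#'
#' @param dataset a `multi_omics_dataset`.
#' @param specs list of [variant_spec] (a grid such as
#'   [module_ablation_grid()]).
#' @param base a [mosae_config].
#' @param n_folds number of cross-validation folds.
#' @param seed integer seed shared across variants.
#' @param prep a [preprocess_spec] fitted per training fold.
#' @param stratified stratify the folds on the labels.
#' @return data.frame with columns `variant`, `mean_auc`, `sd_auc` (row order
#'   = input order); attribute `"fold_auc"` holds the per-fold AUC matrix and
#'   attribute `"cv_results"` the full per-variant `cv_result` objects.
#' @export
run_ablation <- function(dataset, specs, base = mosae_config(), n_folds = 5L,
                         seed = 1L, prep = preprocess_spec(),
                         stratified = TRUE) {
  if (inherits(specs, "variant_spec")) specs <- list(specs)
  if (!length(specs)) stop_mosae("at least one variant spec is required")
  folds <- split_folds(dataset, n_folds, seed = derive_seed(seed, 0L),
                       stratified = stratified)
  results <- lapply(specs, function(sp)
    cross_validate(dataset, sp, base, n_folds = n_folds, seed = seed,
                   prep = prep, folds = folds))
  tab <- data.frame(
    variant = vapply(results, `[[`, character(1), "variant"),
    mean_auc = vapply(results, `[[`, numeric(1), "mean"),
    sd_auc = vapply(results, `[[`, numeric(1), "sd"),
    stringsAsFactors = FALSE)
  attr(tab, "fold_auc") <- do.call(rbind, lapply(results, `[[`, "fold_auc"))
  attr(tab, "cv_results") <- results
  tab
}
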