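#' Specify feature filtering and standardization
#'
#' Omics feature matrices are cleaned before modelling by dropping
#' low-variance and low-mean features and taming outliers. Thresholds are
#' quantiles of the per-feature statistics within each omics, so one spec works
#' across layers of very different scale (methylation betas vs. RNA-Seq
#' counts vs. protein levels).
#'
#' @param variance_quantile drop features whose variance falls below this
#'   quantile of the omics' feature variances; fraction in `[0, 1)`.
#' @param mean_quantile after the variance step, drop features whose mean falls
#'   below this quantile of the remaining feature means; fraction in `[0, 1)`.
#' @param outlier_z_cap clip standardized values to `+/- outlier_z_cap`
#'   (interpreting "outlier filtering" as winsorization rather than sample
#'   removal, so sample counts are preserved); `NULL` disables clipping.
#'   Only applied when `standardize = TRUE`.
#' @param standardize center and scale each kept feature using training-fold
#'   statistics.
#' @return an object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(variance_quantile = 0.2, mean_quantile = 0.2,
                            outlier_z_cap = 6, standardize = TRUE) {
  variance_quantile <- assert_number(variance_quantile, "variance_quantile", 0, 1)
  mean_quantile <- assert_number(mean_quantile, "mean_quantile", 0, 1)
  if (variance_quantile >= 1 || mean_quantile >= 1)
    stop_mosae("filter quantiles must be < 1 (cannot drop all features)")
  if (!is.null(outlier_z_cap))
    outlier_z_cap <- assert_number(outlier_z_cap, "outlier_z_cap", min = .Machine$double.eps)
  structure(list(variance_quantile = variance_quantile,
                 mean_quantile = mean_quantile,
                 outlier_z_cap = outlier_z_cap,
                 standardize = assert_flag(standardize, "standardize")),
            class = "preprocess_spec")
}

#' Fit a preprocessor on training data only
#'
#' Computes, independently for each omics: (1) the variance filter, (2) the
#' mean filter on surviving features, (3) per-feature center (mean) and scale
#' (standard deviation, unbiased N-1 denominator) for standardization.
#' Zero-variance features are always dropped. Fitting sees only the data it is
#' given — fit on training folds and apply to held-out folds to keep
#' cross-validation leakage-free.
#'
#' @param train a `multi_omics_dataset` (training folds only).
#' @param spec a [preprocess_spec].
#' @return an object of class `fitted_preprocessor`: per-omics kept feature
#'   ids, centers and scales, plus the spec used.
#' @export
fit_preprocessor <- function(train, spec = preprocess_spec()) {
  stopifnot(inherits(train, "multi_omics_dataset"), inherits(spec, "preprocess_spec"))
  omics <- lapply(train$matrices, function(m) {
    n <- nrow(m$values)
    mu_all <- colMeans(m$values)
    # unbiased (n-1) variance, vectorized two-pass (numerically centered)
    centered <- m$values - rep(mu_all, each = n)
    v <- colSums(centered^2) / (n - 1)
    keep <- v > 0
    # ">= threshold" with a relative tie tolerance, so exactly tied features
    # (e.g. an already-standardized matrix) are all kept or all dropped
    ge_thr <- function(x, thr) (x - thr) >= -1e-9 * max(abs(thr), 1)
    if (spec$variance_quantile > 0) {
      thr <- stats::quantile(v, spec$variance_quantile, names = FALSE)
      keep <- keep & ge_thr(v, thr)
    }
    if (spec$mean_quantile > 0) {
      mu <- mu_all[keep]
      thr <- stats::quantile(mu, spec$mean_quantile, names = FALSE)
      keep[keep] <- ge_thr(mu, thr)
    }
    if (!any(keep))
      stop_mosae(sprintf("preprocessing removed every feature of omics '%s'", m$omics_name))
    list(kept_feature_ids = m$feature_ids[keep],
         center = mu_all[keep], scale = sqrt(v[keep]))
  })
  names(omics) <- names(train$matrices)
  structure(list(omics = omics, spec = spec), class = "fitted_preprocessor")
}

#' Apply a fitted preprocessor
#'
#' Selects the kept features (in recorded order) and, if the spec asks for it,
#' standardizes with the training-fold center/scale and clips standardized
#' values at the configured z-cap.
#'
#' @param fp a [fit_preprocessor] result.
#' @param data a `multi_omics_dataset` containing every kept feature.
#' @return a transformed `multi_omics_dataset`.
#' @export
apply_preprocessor <- function(fp, data) {
  stopifnot(inherits(fp, "fitted_preprocessor"), inherits(data, "multi_omics_dataset"))
  if (!setequal(names(fp$omics), names(data$matrices)))
    stop_mosae("preprocessor and dataset carry different omics layers")
  spec <- fp$spec
  mats <- lapply(names(fp$omics), function(nm) {
    m <- data$matrices[[nm]]
    o <- fp$omics[[nm]]
    miss <- setdiff(o$kept_feature_ids, m$feature_ids)
    if (length(miss))
      stop_mosae(sprintf("omics '%s' is missing %d kept features (first: %s)",
                         nm, length(miss), miss[1L]))
    x <- m$values[, o$kept_feature_ids, drop = FALSE]
    if (spec$standardize) {
      x <- sweep(sweep(x, 2L, o$center, "-"), 2L, o$scale, "/")
      if (!is.null(spec$outlier_z_cap))
        x <- pmin(pmax(x, -spec$outlier_z_cap), spec$outlier_z_cap)
    }
    omics_matrix(x, m$omics_name)
  })
  names(mats) <- names(fp$omics)
  out <- data
  out$matrices <- mats
  out
}

#' Serialize / restore a fitted preprocessor as JSON
#'
#' Feature lists, centers and scales are written at 15-digit precision for
#' auditing what a cross-validation fold actually saw; a restored
#' preprocessor reproduces transforms to ~1e-12 relative accuracy.
#'
#' @param fp a `fitted_preprocessor`.
#' @param path output (input) JSON path.
#' @return `write_preprocessor`: `path` invisibly; `read_preprocessor`: a
#'   `fitted_preprocessor`.
#' @export
write_preprocessor <- function(fp, path) {
  stopifnot(inherits(fp, "fitted_preprocessor"))
  obj <- list(spec = unclass(fp$spec), omics = fp$omics)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_preprocessor
#' @export
read_preprocessor <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- preprocess_spec(variance_quantile = obj$spec$variance_quantile,
                          mean_quantile = obj$spec$mean_quantile,
                          outlier_z_cap = obj$spec$outlier_z_cap,
                          standardize = obj$spec$standardize)
  omics <- lapply(obj$omics, function(o) {
    center <- unlist(o$center); scale <- unlist(o$scale)
    names(center) <- names(scale) <- o$kept_feature_ids
    list(kept_feature_ids = o$kept_feature_ids, center = center, scale = scale)
  })
  structure(list(omics = omics, spec = spec), class = "fitted_preprocessor")
}
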