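#' Construct an omics matrix
#'
#' An `omics_matrix` is one omics layer's samples-by-features numeric matrix
#' (e.g. DNA methylation beta values, RNA-Seq expression, RPPA protein levels)
#' together with its sample and feature identifiers.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param omics_name character label for the omics layer.
#' @param sample_ids character vector of unique sample identifiers
#'   (default: rownames of `values`).
#' @param feature_ids character vector of unique feature identifiers
#'   (default: colnames of `values`).
#' @return an object of class `omics_matrix`: a list with elements
#'   `omics_name`, `sample_ids`, `feature_ids` and `values` (the matrix carries
#'   the identifiers as dimnames).
#' @export
#' @examples
#' m <- omics_matrix(matrix(rnorm(6), 3, 2,
#'                          dimnames = list(c("s1", "s2", "s3"), c("g1", "g2"))),
#'                   "rna")
#' dim(m$values)
omics_matrix <- function(values, omics_name,
                         sample_ids = rownames(values),
                         feature_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_mosae("'values' must be a numeric matrix")
  if (is.null(sample_ids) || is.null(feature_ids))
    stop_mosae("sample and feature identifiers are required (dimnames or arguments)")
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values) || length(feature_ids) != ncol(values))
    stop_mosae("identifier lengths do not match matrix dimensions")
  if (anyDuplicated(sample_ids))
    stop_mosae(sprintf("duplicate sample ids in omics '%s': %s", omics_name,
                       paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  if (anyDuplicated(feature_ids))
    stop_mosae(sprintf("duplicate feature ids in omics '%s': %s", omics_name,
                       paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", ")))
  if (anyNA(values) || any(!is.finite(values)))
    stop_mosae(sprintf("omics '%s' contains missing or non-finite values; impute or filter upstream",
                       omics_name))
  if (nrow(values) < 2L) stop_mosae("an omics matrix needs at least 2 samples")
  if (ncol(values) < 1L) stop_mosae("an omics matrix needs at least 1 feature")
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(list(omics_name = as.character(omics_name)[1L],
                 sample_ids = sample_ids,
                 feature_ids = feature_ids,
                 values = values),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> %s: %d samples x %d features\n",
              x$omics_name, length(x$sample_ids), length(x$feature_ids)))
  invisible(x)
}

#' Read an omics matrix from delimited text
#'
#' Reads the tab-separated "genomicMatrix" dialect used by UCSC Xena exports:
#' one header row, one identifier column, numeric body. Files may store samples
#' in rows or in columns; the result is always samples-by-features.
#'
#' @param path path to a delimited text file.
#' @param omics_name label for the omics layer.
#' @param orientation `"rows-are-samples"` or `"rows-are-features"`.
#' @param sep field separator (default tab).
#' @return an [omics_matrix].
#' @export
read_omics_matrix <- function(path, omics_name,
                              orientation = c("rows-are-samples", "rows-are-features"),
                              sep = "\t") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_mosae(sprintf("file not found: %s", path))
  nf <- utils::count.fields(path, sep = sep, quote = "", comment.char = "")
  if (length(nf) < 2L) stop_mosae(sprintf("'%s' has no data rows", path))
  bad <- which(nf != nf[1L])
  if (length(bad))
    stop_mosae(sprintf("parse error in '%s': line %d has %d fields, expected %d",
                       path, bad[1L], nf[bad[1L]], nf[1L]))
  dt <- data.table::fread(path, sep = sep, header = TRUE, colClasses = list(character = 1L),
                          data.table = FALSE, showProgress = FALSE)
  row_ids <- as.character(dt[[1L]])
  col_ids <- colnames(dt)[-1L]
  body <- dt[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      v <- suppressWarnings(as.numeric(body[[j]]))
      i <- which(is.na(v) & !is.na(body[[j]]))[1L]
      if (!is.na(i))
        stop_mosae(sprintf("non-numeric value '%s' at row '%s', column '%s' of '%s'",
                           body[[j]][i], row_ids[i], col_ids[j], path))
      body[[j]] <- v
    }
  }
  values <- as.matrix(body)
  rownames(values) <- row_ids
  if (orientation == "rows-are-features") values <- t(values)
  omics_matrix(values, omics_name)
}

#' Write an omics matrix as tab-separated text
#'
#' Writes the same dialect [read_omics_matrix] reads; numeric values use the
#' shortest decimal representation that round-trips exactly, so a
#' read/write/read cycle reproduces identifiers verbatim and values bit-for-bit.
#'
#' @param x an [omics_matrix].
#' @param path output file path.
#' @param orientation layout to write (default samples in rows).
#' @param id_header name for the identifier column header cell.
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(x, path,
                               orientation = c("rows-are-samples", "rows-are-features"),
                               id_header = "sample") {
  orientation <- match.arg(orientation)
  stopifnot(inherits(x, "omics_matrix"))
  values <- if (orientation == "rows-are-samples") x$values else t(x$values)
  # 17 significant digits: every double round-trips bit-exactly through text
  body <- matrix(sprintf("%.17g", values), nrow(values), ncol(values))
  dt <- data.table::data.table(id = rownames(values))
  data.table::setnames(dt, "id", id_header)
  body <- data.table::as.data.table(body)
  data.table::setnames(body, colnames(values))
  dt <- cbind(dt, body)
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Construct endpoint labels
#'
#' Binary labels for one clinical outcome endpoint: overall survival (OS),
#' disease-specific survival (DSS), progression-free interval (PFI) or
#' disease-free interval (DFI). Labels arrive pre-binarized (1 = event).
#'
#' @param endpoint one of `"OS"`, `"DSS"`, `"PFI"`, `"DFI"`.
#' @param sample_ids character vector of unique sample identifiers.
#' @param y integer/numeric vector of 0/1 labels, same length.
#' @return an object of class `endpoint_labels`.
#' @export
endpoint_labels <- function(endpoint, sample_ids, y) {
  endpoint <- match.arg(endpoint, c("OS", "DSS", "PFI", "DFI"))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop_mosae("duplicate sample ids in labels")
  if (length(y) != length(sample_ids))
    stop_mosae("labels and sample ids differ in length")
  if (anyNA(y) || !all(y %in% c(0, 1)))
    stop_mosae("labels must be 0/1 with no missing values")
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop_mosae("both label classes must be present (required for ROC AUC)")
  structure(list(endpoint = endpoint, sample_ids = sample_ids, y = y),
            class = "endpoint_labels")
}

#' Read endpoint labels from a two-column TSV (sample_id, 0/1)
#'
#' @param path path to a tab-separated file with a header row.
#' @param endpoint endpoint name for the resulting labels.
#' @return an [endpoint_labels].
#' @export
read_labels <- function(path, endpoint = "OS") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = 1L))
  if (ncol(dt) < 2L) stop_mosae(sprintf("'%s' must have two columns: sample_id, label", path))
  endpoint_labels(endpoint, dt[[1L]], dt[[2L]])
}

#' Align omics matrices and labels into one multi-omics dataset
#'
#' Keeps exactly the samples present in every omics matrix and in the label
#' table, and reorders every block to one canonical order (lexicographically
#' sorted sample ids) so downstream computation is independent of file layout.
#'
#' @param matrices list of [omics_matrix] objects (named or not; names default
#'   to each matrix's `omics_name`).
#' @param labels an [endpoint_labels].
#' @return an object of class `multi_omics_dataset`: list with `matrices`
#'   (named list of aligned [omics_matrix]), `labels` and `sample_ids`.
#' @export
align_samples <- function(matrices, labels) {
  if (inherits(matrices, "omics_matrix")) matrices <- list(matrices)
  if (!length(matrices)) stop_mosae("at least one omics matrix is required")
  if (!all(vapply(matrices, inherits, logical(1), "omics_matrix")))
    stop_mosae("'matrices' must be a list of omics_matrix objects")
  stopifnot(inherits(labels, "endpoint_labels"))
  common <- Reduce(intersect, c(lapply(matrices, `[[`, "sample_ids"),
                                list(labels$sample_ids)))
  if (!length(common))
    stop_mosae("no samples shared by all omics matrices and the label table")
  common <- sort(common)
  y <- labels$y[match(common, labels$sample_ids)]
  if (length(unique(y)) < 2L)
    stop_mosae("aligned samples contain only one label class")
  aligned <- lapply(matrices, function(m) {
    omics_matrix(m$values[match(common, m$sample_ids), , drop = FALSE], m$omics_name)
  })
  names(aligned) <- vapply(aligned, `[[`, character(1), "omics_name")
  structure(list(matrices = aligned,
                 labels = structure(list(endpoint = labels$endpoint,
                                         sample_ids = common, y = y),
                                    class = "endpoint_labels"),
                 sample_ids = common),
            class = "multi_omics_dataset")
}

#' @export
print.multi_omics_dataset <- function(x, ...) {
  cat(sprintf("<multi_omics_dataset> %d samples, %d omics, endpoint %s (%d positive)\n",
              length(x$sample_ids), length(x$matrices), x$labels$endpoint,
              sum(x$labels$y)))
  for (m in x$matrices)
    cat(sprintf("  %-16s %d features\n", m$omics_name, length(m$feature_ids)))
  invisible(x)
}

#' Number of samples / per-omics feature counts of a dataset
#' @param dataset a `multi_omics_dataset`.
#' @return `n_samples`: integer; `omics_dims`: named integer vector.
#' @export
n_samples <- function(dataset) length(dataset$sample_ids)

#' @rdname n_samples
#' @export
omics_dims <- function(dataset)
  vapply(dataset$matrices, function(m) length(m$feature_ids), integer(1))

#' Subset a multi-omics dataset by sample index
#'
#' @param dataset a `multi_omics_dataset`.
#' @param idx integer or logical index into the dataset's sample order.
#' @return a `multi_omics_dataset` with the selected samples (original relative
#'   order preserved; not re-sorted).
#' @export
subset_samples <- function(dataset, idx) {
  stopifnot(inherits(dataset, "multi_omics_dataset"))
  ids <- dataset$sample_ids[idx]
  mats <- lapply(dataset$matrices, function(m)
    omics_matrix(m$values[idx, , drop = FALSE], m$omics_name))
  y <- dataset$labels$y[idx]
  structure(list(matrices = mats,
                 labels = structure(list(endpoint = dataset$labels$endpoint,
                                         sample_ids = ids, y = y),
                                    class = "endpoint_labels"),
                 sample_ids = ids),
            class = "multi_omics_dataset")
}

#' Restrict a dataset to a subset of its omics layers
#'
#' Useful for single-omics baselines: the labels and sample order are kept.
#'
#' @param dataset a `multi_omics_dataset`.
#' @param which character names or integer indices of the layers to keep.
#' @return a `multi_omics_dataset` with the selected layers.
#' @export
select_omics <- function(dataset, which) {
  stopifnot(inherits(dataset, "multi_omics_dataset"))
  mats <- dataset$matrices[which]
  if (!length(mats) || any(vapply(mats, is.null, logical(1))))
    stop_mosae("unknown omics layer requested")
  out <- dataset
  out$matrices <- mats
  out
}

#' Assign cross-validation folds
#'
#' Deterministic shuffling from a single integer seed. In stratified mode
#' (the default) positive samples are dealt round-robin across folds before
#' negatives continue the same cycle, so fold sizes differ by at most one and
#' per-fold positive counts differ by at most one.
#'
#' @param dataset a `multi_omics_dataset`.
#' @param n_folds number of folds (>= 2).
#' @param seed integer seed controlling the shuffle.
#' @param stratified keep label prevalence balanced across folds (default TRUE).
#' @return an object of class `fold_assignment`: list with `n_folds` and
#'   `fold_of`, an integer vector of fold indices in `1:n_folds`, one per
#'   sample in dataset order.
#' @export
split_folds <- function(dataset, n_folds = 5L, seed = 1L, stratified = TRUE) {
  stopifnot(inherits(dataset, "multi_omics_dataset"))
  n_folds <- assert_count(n_folds, "n_folds", min = 2L)
  n <- n_samples(dataset)
  if (n_folds > n)
    stop_mosae(sprintf("n_folds (%d) exceeds the number of samples (%d)", n_folds, n))
  y <- dataset$labels$y
  ord <- with_seed(seed, {
    if (stratified) {
      pos <- which(y == 1L); neg <- which(y == 0L)
      c(pos[sample.int(length(pos))], neg[sample.int(length(neg))])
    } else {
      sample.int(n)
    }
  })
  fold_of <- integer(n)
  fold_of[ord] <- rep_len(seq_len(n_folds), n)
  structure(list(n_folds = n_folds, fold_of = fold_of,
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "fold_assignment")
}
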