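#' Expression dataset container
#'
#' The central container used throughout the package: a gene x sample matrix
#' of non-negative expression values (counts, normalized counts, or log2),
#' an explicit missing-value mask, optional per-gene annotation (GC fraction
#' and length, needed for GC normalization) and optional per-sample metadata
#' (cell-type label, study of origin).
#'
#' A value is "missing" when the source file did not report it; missingness
#' is tracked separately from the numeric payload so that filtering,
#' normalization, and the dummy (-1) encoding applied before model fitting
#' can treat absent values correctly. Sparse zeros are *not* missing.
#'
#' @param values numeric gene x sample matrix with rownames (gene ids) and
#'   colnames (sample ids). Non-negative wherever not missing.
#' @param missing_mask logical matrix of the same shape; `TRUE` marks values
#'   absent in the source. Defaults to all-`FALSE`.
#' @param gene_annotation `NULL` or a data.frame with columns `gene_id`,
#'   `gc_fraction` (in \[0,1\]) and `length_bp` (positive integer).
#' @param sample_meta `NULL` or a data.frame with columns `sample_id`,
#'   `cell_type` (may be `NA` for unlabeled cells) and `study_id`.
#' @param value_scale one of `"raw_counts"`, `"normalized_counts"`, `"log2"`.
#' @return an object of class `ExpressionDataset`.
#' @export
ExpressionDataset <- function(values, missing_mask = NULL,
                              gene_annotation = NULL, sample_meta = NULL,
                              value_scale = c("raw_counts",
                                              "normalized_counts", "log2")) {
  value_scale <- match.arg(value_scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (is.null(missing_mask))
    missing_mask <- matrix(FALSE, nrow(values), ncol(values),
                           dimnames = dimnames(values))
  if (!is.logical(missing_mask) || !identical(dim(missing_mask), dim(values)))
    stop("`missing_mask` must be a logical matrix with the same dimensions as `values`",
         call. = FALSE)
  dimnames(missing_mask) <- dimnames(values)
  ds <- structure(
    list(values = values, missing_mask = missing_mask,
         gene_annotation = gene_annotation, sample_meta = sample_meta,
         value_scale = value_scale),
    class = "ExpressionDataset")
  validate_expression_dataset(ds)
  ds
}

#' Validate an ExpressionDataset's invariants
#'
#' Checks dimension consistency, identifier uniqueness, and non-negativity
#' of non-missing values (log2-scale datasets may carry the -1 dummy at
#' masked positions only).
#'
#' @param ds an `ExpressionDataset`.
#' @return `ds`, invisibly; errors on violation.
#' @export
validate_expression_dataset <- function(ds) {
  g <- gene_ids(ds); s <- sample_ids(ds)
  if (anyDuplicated(g))
    stop("duplicate gene id(s): ",
         paste(unique(g[duplicated(g)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(s))
    stop("duplicate sample id(s): ",
         paste(unique(s[duplicated(s)]), collapse = ", "), call. = FALSE)
  v <- ds$values[!ds$missing_mask]
  if (anyNA(v))
    stop("non-missing values contain NA; use the missing_mask", call. = FALSE)
  if (length(v) && min(v) < 0)
    stop("negative expression value at a non-missing position", call. = FALSE)
  masked <- ds$values[ds$missing_mask]
  if (length(masked) && any(!is.na(masked) & masked < 0 & masked != -1))
    stop("the only permitted negative value is the -1 dummy at masked positions",
         call. = FALSE)
  if (!is.null(ds$gene_annotation)) {
    need <- c("gene_id", "gc_fraction", "length_bp")
    if (!all(need %in% names(ds$gene_annotation)))
      stop("gene_annotation needs columns gene_id, gc_fraction, length_bp",
           call. = FALSE)
  }
  if (!is.null(ds$sample_meta)) {
    if (!"sample_id" %in% names(ds$sample_meta))
      stop("sample_meta needs a sample_id column", call. = FALSE)
    if (!all(s %in% ds$sample_meta$sample_id))
      stop("sample_meta does not cover all samples", call. = FALSE)
  }
  invisible(ds)
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$value_scale))
  nm <- sum(x$missing_mask)
  if (nm > 0)
    cat(sprintf("  missing values: %d (%.2f%%)\n", nm,
                100 * nm / length(x$missing_mask)))
  if (!is.null(x$gene_annotation)) cat("  gene annotation: GC fraction, length\n")
  if (!is.null(x$sample_meta)) {
    ct <- cell_types(x)
    if (any(!is.na(ct)))
      cat("  cell types:", paste(levels(factor(ct)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname ExpressionDataset
#' @export
gene_ids <- function(ds) rownames(ds$values)

#' @rdname ExpressionDataset
#' @export
sample_ids <- function(ds) colnames(ds$values)

#' Per-sample cell-type labels (NA where unlabeled)
#' @param ds an `ExpressionDataset`.
#' @return character vector aligned with `sample_ids(ds)`.
#' @export
cell_types <- function(ds) {
  if (is.null(ds$sample_meta)) return(rep(NA_character_, ncol(ds$values)))
  m <- match(sample_ids(ds), ds$sample_meta$sample_id)
  as.character(ds$sample_meta$cell_type[m])
}

#' Subset an ExpressionDataset by genes and/or samples
#'
#' @param ds an `ExpressionDataset`.
#' @param genes,samples character vectors of identifiers, or indices; `NULL`
#'   keeps everything. Order of the selection is preserved.
#' @return the subsetted `ExpressionDataset`.
#' @export
subset_dataset <- function(ds, genes = NULL, samples = NULL) {
  gi <- if (is.null(genes)) seq_len(nrow(ds$values)) else {
    if (is.character(genes)) {
      idx <- match(genes, gene_ids(ds))
      if (anyNA(idx))
        stop("unknown gene id(s): ",
             paste(genes[is.na(idx)], collapse = ", "), call. = FALSE)
      idx
    } else genes
  }
  si <- if (is.null(samples)) seq_len(ncol(ds$values)) else {
    if (is.character(samples)) {
      idx <- match(samples, sample_ids(ds))
      if (anyNA(idx))
        stop("unknown sample id(s): ",
             paste(samples[is.na(idx)], collapse = ", "), call. = FALSE)
      idx
    } else samples
  }
  ann <- ds$gene_annotation
  if (!is.null(ann)) ann <- ann[ann$gene_id %in% rownames(ds$values)[gi], ,
                                drop = FALSE]
  sm <- ds$sample_meta
  if (!is.null(sm)) sm <- sm[sm$sample_id %in% colnames(ds$values)[si], ,
                             drop = FALSE]
  ExpressionDataset(ds$values[gi, si, drop = FALSE],
                    ds$missing_mask[gi, si, drop = FALSE],
                    gene_annotation = ann, sample_meta = sm,
                    value_scale = ds$value_scale)
}

#' Train/test split specification
#'
#' Holds disjoint train and test sample-id sets for a labeled dataset, with
#' every cell-type label represented in the training split.
#'
#' @param ds a labeled `ExpressionDataset`.
#' @param train_sample_ids,test_sample_ids disjoint subsets of
#'   `sample_ids(ds)`.
#' @return an object of class `SplitSpec`.
#' @export
SplitSpec <- function(ds, train_sample_ids, test_sample_ids) {
  all_ids <- sample_ids(ds)
  bad <- setdiff(c(train_sample_ids, test_sample_ids), all_ids)
  if (length(bad))
    stop("split references unknown sample id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (length(intersect(train_sample_ids, test_sample_ids)))
    stop("train and test sample sets overlap", call. = FALSE)
  ct <- cell_types(ds)
  lv <- unique(ct[!is.na(ct)])
  tr_ct <- ct[match(train_sample_ids, all_ids)]
  miss <- setdiff(lv, tr_ct)
  if (length(miss))
    stop("cell type(s) absent from the training split: ",
         paste(miss, collapse = ", "), call. = FALSE)
  structure(list(train_sample_ids = train_sample_ids,
                 test_sample_ids = test_sample_ids),
            class = "SplitSpec")
}

#' Stratified train/test split
#'
#' Splits a labeled dataset into train and test subsets, stratified by
#' cell-type label so every label is represented in the training split.
#'
#' @param ds a labeled `ExpressionDataset`.
#' @param train_fraction fraction of each label's samples assigned to
#'   training (default 0.6, rounded up so small classes keep >= 1 training
#'   sample).
#' @param seed integer seed controlling the random assignment.
#' @return a `SplitSpec`.
#' @export
split_dataset <- function(ds, train_fraction = 0.6, seed = 1L) {
  ct <- cell_types(ds)
  if (all(is.na(ct))) stop("dataset has no cell-type labels", call. = FALSE)
  ids <- sample_ids(ds)
  train <- with_seed(seed, {
    out <- character(0)
    for (lv in unique(ct[!is.na(ct)])) {
      pool <- ids[!is.na(ct) & ct == lv]
      n_tr <- max(1L, ceiling(train_fraction * length(pool)))
      out <- c(out, sample(pool, n_tr))
    }
    out
  })
  SplitSpec(ds, train, setdiff(ids[!is.na(ct)], train))
}
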