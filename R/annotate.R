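#' Annotate single cells with a trained classifier
#'
#' Aligns the single-cell matrix to the model's genes (genes the cells do
#' not report become the -1 dummy), optionally applies training-like
#' preprocessing, and assigns each cell the argmax-posterior label. By
#' default preprocessing is limited to the log2 transform of raw counts:
#' cells are not sequencing lanes, so the between-lane quantile step is
#' skipped unless `preprocess_like_training = TRUE` restores the full
#' chain (GC stage included only when annotation is available).
#'
#' @param model a multiclass `ClassifierModel`.
#' @param sc_ds an [ExpressionDataset] of cells (raw counts or log2).
#' @param preprocess_like_training apply filter + normalization before the
#'   log2 transform (default `FALSE`).
#' @param min_overlap minimum fraction of model genes the cells must report
#'   (default 0.5); below the floor annotation errors, naming the missing
#'   genes.
#' @param min_confidence cells whose maximum posterior falls below this
#'   floor are labeled `"unassigned"` (default 0: always assign).
#' @return a `CellAnnotationTable` data.frame: `cell_id`,
#'   `assigned_label`, `confidence`, plus one posterior column per class.
#' @export
annotate_cells <- function(model, sc_ds, preprocess_like_training = FALSE,
                           min_overlap = 0.5, min_confidence = 0) {
  overlap <- intersect(model$gene_ids, gene_ids(sc_ds))
  frac <- length(overlap) / length(model$gene_ids)
  if (frac < min_overlap) {
    miss <- setdiff(model$gene_ids, gene_ids(sc_ds))
    stopf(paste0("only %.0f%% of the %d model genes are present ",
                 "(floor %.0f%%); missing e.g.: %s"), 100 * frac,
          length(model$gene_ids), 100 * min_overlap,
          paste(head(miss, 5), collapse = ", "))
  }
  ds <- sc_ds
  if (preprocess_like_training && ds$value_scale != "log2") {
    ds <- preprocess_pipeline(ds, annotation = ds$gene_annotation,
                              skip_gc = is.null(ds$gene_annotation))$dataset
  } else if (ds$value_scale != "log2") {
    ds <- log2_transform(ds)
  }
  keep <- intersect(model$gene_ids, gene_ids(ds))
  x <- encode_missing(subset_dataset(ds, genes = keep))
  prob <- predict_proba(model, x, fill_missing = TRUE)
  conf <- apply(prob, 1, max)
  lab <- model$class_labels[apply(prob, 1, which.max)]
  lab[conf < min_confidence] <- "unassigned"
  out <- data.frame(cell_id = sample_ids(ds), assigned_label = lab,
                    confidence = conf, row.names = NULL)
  out <- cbind(out, as.data.frame(prob, row.names = NULL))
  class(out) <- c("CellAnnotationTable", "data.frame")
  out
}

#' Per-specimen cell-type composition (percentages)
#'
#' @param annotations a `CellAnnotationTable` (or data.frame with
#'   `cell_id`, `assigned_label`).
#' @param specimen_map named character vector or data.frame (`cell_id`,
#'   `specimen_id`) mapping cells to specimens.
#' @param group_meta optional data.frame (`specimen_id`, plus metadata such
#'   as treatment status) attached as the `groups` attribute.
#' @return a `CompositionTable`: specimen x cell-type matrix of
#'   percentages; rows sum to 100; zero-count labels kept as 0.
#' @export
compose_by_specimen <- function(annotations, specimen_map,
                                group_meta = NULL) {
  if (is.data.frame(specimen_map))
    specimen_map <- setNames(as.character(specimen_map$specimen_id),
                             specimen_map$cell_id)
  spec_of <- specimen_map[annotations$cell_id]
  if (anyNA(spec_of))
    stopf("no specimen for cell(s): %s",
          paste(head(annotations$cell_id[is.na(spec_of)], 5),
                collapse = ", "))
  known <- setdiff(names(annotations),
                   c("cell_id", "assigned_label", "confidence"))
  lv <- if (length(known)) union(known, unique(annotations$assigned_label))
        else unique(annotations$assigned_label)
  tab <- table(specimen = spec_of,
               label = factor(annotations$assigned_label, levels = lv))
  pct <- 100 * tab / rowSums(tab)
  m <- matrix(as.numeric(pct), nrow(tab), ncol(tab),
              dimnames = dimnames(tab))
  structure(m, class = c("CompositionTable", "matrix"), groups = group_meta)
}

#' PCA with a scrambled-data component-retention control
#'
#' Centers the composition columns and decomposes by SVD. As a negative
#' control, each column is independently permuted `n_scrambles` times; the
#' retention threshold is the largest explained-variance fraction achieved
#' by the leading component of any scrambled replicate. Components whose
#' explained-variance fraction exceeds the threshold are retained — the
#' rest are indistinguishable from random chance.
#'
#' @param comp a `CompositionTable` (or numeric specimen x feature matrix,
#'   >= 3 specimens).
#' @param n_scrambles number of scrambled replicates (default 50).
#' @param seed integer seed for the permutations.
#' @return list with `n_retained`, `threshold`, `explained_variance`
#'   (fractions summing to 1), `scores`, `loadings`.
#' @export
pca_with_scrambled_control <- function(comp, n_scrambles = 50L, seed = 1L) {
  m <- unclass(comp)
  if (nrow(m) < 3) stop("need at least 3 specimens", call. = FALSE)
  ctr <- scale(m, center = TRUE, scale = FALSE)
  sv <- svd(ctr)
  ev <- sv$d^2
  evf <- ev / sum(ev)
  thr <- with_seed(seed, {
    max(vapply(seq_len(n_scrambles), function(i) {
      s <- apply(m, 2, sample)
      d2 <- svd(scale(s, center = TRUE, scale = FALSE), nu = 0, nv = 0)$d^2
      max(d2 / sum(d2))
    }, 0))
  })
  n_ret <- sum(evf > thr)
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  dimnames(scores) <- list(rownames(m), paste0("PC", seq_along(sv$d)))
  loadings <- sv$v
  dimnames(loadings) <- list(colnames(m), paste0("PC", seq_along(sv$d)))
  list(n_retained = n_ret, threshold = thr, explained_variance = evf,
       scores = scores, loadings = loadings)
}

#' Hierarchical clustering of specimens by composition
#'
#' Agglomerative clustering on euclidean distances between the percentage
#' rows. The cluster count is user-supplied (no automatic index-based
#' selection).
#'
#' @param comp a `CompositionTable` or numeric matrix.
#' @param k number of clusters (1..n specimens).
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"complete"`).
#' @return named integer vector of cluster labels.
#' @export
cluster_specimens <- function(comp, k, linkage = "complete") {
  m <- unclass(comp)
  if (k < 1 || k > nrow(m))
    stopf("k must be between 1 and the number of specimens (%d)", nrow(m))
  cutree(hclust(dist(m), method = linkage), k = k)
}
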