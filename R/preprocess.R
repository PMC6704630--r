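#' Filter genes with low expression
#'
#' Keeps exactly the genes whose count is `>= min_count` in at least
#' `min_samples` samples; missing entries never count toward the threshold.
#' This is applied once before normalization and again afterwards (second
#' pass, same rule). The defaults follow the immune-cell runs (count >= 5
#' in >= 5 samples); T-helper runs, having fewer samples, use
#' `min_samples = 4`.
#'
#' @param ds an [ExpressionDataset] on the counts scale.
#' @param min_count non-negative count threshold (default 5).
#' @param min_samples minimum number of samples meeting the threshold
#'   (default 5).
#' @return the filtered [ExpressionDataset], gene order preserved.
#' @export
filter_low_expression <- function(ds, min_count = 5, min_samples = 5L) {
  if (ds$value_scale == "log2")
    stop("filtering applies to the counts scale, not log2", call. = FALSE)
  if (min_samples > ncol(ds$values))
    stopf("min_samples (%d) exceeds the number of samples (%d)",
          min_samples, ncol(ds$values))
  ok <- ds$values >= min_count & !ds$missing_mask
  keep <- rowSums(ok) >= min_samples
  if (!any(keep))
    stopf(paste0("no gene passes the filter (count >= %g in >= %d samples); ",
                 "lower min_count or min_samples"), min_count, min_samples)
  subset_dataset(ds, genes = which(keep))
}

#' Within-lane GC-content normalization
#'
#' Removes, sample by sample ("lane" by "lane"), the dependence of counts on
#' gene GC content. For each sample a local-regression smoother of
#' `log(count + 0.5)` on GC fraction is fitted over the non-missing genes;
#' each value is rescaled so the fitted GC trend is removed while the
#' sample's median log-count is preserved. A coarser median-bin variant
#' (piecewise-constant trend over GC deciles) is available as a fallback for
#' very small gene sets.
#'
#' @param ds an [ExpressionDataset] of raw counts.
#' @param annotation per-gene annotation data.frame (`gene_id`,
#'   `gc_fraction`, `length_bp`); defaults to the dataset's own.
#' @param span loess span (default 0.3).
#' @param method `"loess"` (default) or `"median_bin"`.
#' @return the normalized [ExpressionDataset]
#'   (`value_scale = "normalized_counts"`); missing entries untouched.
#' @export
within_lane_gc_normalize <- function(ds, annotation = NULL, span = 0.3,
                                     method = c("loess", "median_bin")) {
  method <- match.arg(method)
  if (ds$value_scale == "log2")
    stop("GC normalization applies to the counts scale", call. = FALSE)
  annotation <- annotation %||% ds$gene_annotation
  if (is.null(annotation))
    stop("gene annotation with gc_fraction is required", call. = FALSE)
  gc <- annotation$gc_fraction[match(gene_ids(ds), annotation$gene_id)]
  if (anyNA(gc)) {
    off <- gene_ids(ds)[is.na(gc)]
    stopf("no GC annotation for gene(s): %s%s",
          paste(head(off, 5), collapse = ", "),
          if (length(off) > 5) sprintf(" (+%d more)", length(off) - 5) else "")
  }
  out <- ds$values
  for (j in seq_len(ncol(out))) {
    obs <- !ds$missing_mask[, j]
    if (sum(obs) < 20)
      stopf("sample '%s' has %d non-missing genes; >= 20 needed for the GC smoother",
            sample_ids(ds)[j], sum(obs))
    y <- log(out[obs, j] + 0.5)
    x <- gc[obs]
    trend <- if (method == "loess" && length(unique(x)) >= 10) {
      fit <- suppressWarnings(
        loess(y ~ x, span = span, degree = 1,
              control = loess.control(surface = "direct")))
      predict(fit, x)
    } else if (method == "median_bin" || length(unique(x)) < 10) {
      bins <- cut(x, breaks = unique(quantile(x, probs = seq(0, 1, 0.1))),
                  include.lowest = TRUE)
      med <- tapply(y, bins, stats::median)
      as.numeric(med[bins])
    }
    adj <- y - trend + stats::median(y)
    out[obs, j] <- pmax(exp(adj) - 0.5, 0)
  }
  ds$values <- out
  ds$value_scale <- "normalized_counts"
  validate_expression_dataset(ds)
  ds
}

#' Between-lane full-quantile normalization
#'
#' Forces every sample to share one distribution: the across-sample mean of
#' order statistics. Ranks are computed per sample over non-missing values
#' only; ties receive the average of the quantile values they span, so the
#' per-sample rank order is preserved. With samples of unequal non-missing
#' counts, each sample is mapped through linear interpolation of the mean
#' quantile function. Applying the normalization twice equals applying it
#' once.
#'
#' @param ds an [ExpressionDataset] on the counts scale with >= 2 samples
#'   (a single sample is returned unchanged, with a warning).
#' @return the normalized [ExpressionDataset].
#' @export
between_lane_full_quantile <- function(ds) {
  if (ds$value_scale == "log2")
    stop("quantile normalization applies to the counts scale", call. = FALSE)
  n_s <- ncol(ds$values)
  if (n_s < 2) {
    warnf("single sample: full-quantile normalization is the identity")
    return(ds)
  }
  obs_list <- lapply(seq_len(n_s), function(j) which(!ds$missing_mask[, j]))
  counts <- lengths(obs_list)
  if (any(counts == 0)) stopf("a sample has no non-missing values")
  n_ref <- max(counts)
  probs <- if (n_ref == 1) 0.5 else seq(0, 1, length.out = n_ref)
  qmat <- vapply(seq_len(n_s), function(j)
    quantile(ds$values[obs_list[[j]], j], probs = probs, names = FALSE,
             type = 7), numeric(n_ref))
  ref <- rowMeans(qmat)
  out <- ds$values
  for (j in seq_len(n_s)) {
    idx <- obs_list[[j]]
    x <- ds$values[idx, j]
    n <- length(x)
    # value assigned to integer rank r, then ties averaged over their ranks
    by_rank <- if (n_ref == 1) rep(ref, n) else
      approx(probs, ref, xout = if (n == 1) 0.5 else (seq_len(n) - 1) / (n - 1),
             rule = 2)$y
    assigned <- numeric(n)
    assigned[order(x)] <- by_rank
    out[idx, j] <- ave(assigned, factor(x), FUN = mean)
  }
  ds$values <- out
  ds$value_scale <- "normalized_counts"
  validate_expression_dataset(ds)
  ds
}

#' Log2 transform
#'
#' Each non-missing value v becomes log2(v + 1); missing entries are
#' untouched (the -1 dummy encoding happens later, at model-fitting time).
#'
#' @param ds an [ExpressionDataset] with non-negative non-missing values.
#' @return the transformed dataset with `value_scale = "log2"`.
#' @export
log2_transform <- function(ds) {
  if (ds$value_scale == "log2")
    stop("dataset is already on the log2 scale", call. = FALSE)
  v <- ds$values[!ds$missing_mask]
  if (length(v) && min(v) < 0)
    stop("negative value encountered before log2 transform", call. = FALSE)
  ds$values[!ds$missing_mask] <- log2(v + 1)
  ds$value_scale <- "log2"
  ds
}

#' The full filtering and normalization chain
#'
#' Fixed stage order: low-expression filter, within-lane GC normalization,
#' between-lane full-quantile normalization, a second filter pass with the
#' same rule, then the log2 transform. Returns the processed dataset
#' together with a `NormalizationReport` recording gene counts before/after
#' each stage (non-increasing across the filter stages) and per-sample
#' scaling diagnostics.
#'
#' @inheritParams filter_low_expression
#' @inheritParams within_lane_gc_normalize
#' @param skip_gc skip the GC stage (e.g. when no annotation exists).
#' @return list with elements `dataset` (log2-scale [ExpressionDataset]) and
#'   `report` (a `NormalizationReport`).
#' @export
preprocess_pipeline <- function(ds, annotation = NULL, min_count = 5,
                                min_samples = 5L, span = 0.3,
                                skip_gc = FALSE) {
  stages <- c("filter1", if (!skip_gc) "gc_normalize", "full_quantile",
              "filter2", "log2")
  genes <- c(before = nrow(ds$values))
  ds <- filter_low_expression(ds, min_count, min_samples)
  genes["filter1"] <- nrow(ds$values)
  if (!skip_gc) {
    ds <- within_lane_gc_normalize(ds, annotation, span = span)
    genes["gc_normalize"] <- nrow(ds$values)
  }
  med_before <- apply(ds$values, 2, stats::median)
  ds <- between_lane_full_quantile(ds)
  genes["full_quantile"] <- nrow(ds$values)
  med_after <- apply(ds$values, 2, stats::median)
  ds <- filter_low_expression(ds, min_count, min_samples)
  genes["filter2"] <- nrow(ds$values)
  ds <- log2_transform(ds)
  genes["log2"] <- nrow(ds$values)
  report <- structure(list(
    stage_order = stages,
    genes = genes,
    sample_medians = data.frame(sample_id = sample_ids(ds) %||% character(0),
                                median_before_quantile = med_before,
                                median_after_quantile = med_after,
                                row.names = NULL),
    params = list(min_count = min_count, min_samples = min_samples,
                  span = span, skip_gc = skip_gc)),
    class = "NormalizationReport")
  list(dataset = ds, report = report)
}

#' @export
print.NormalizationReport <- function(x, ...) {
  cat("NormalizationReport\n  stages:",
      paste(x$stage_order, collapse = " -> "), "\n  genes:",
      paste(sprintf("%s=%d", names(x$genes), x$genes), collapse = ", "), "\n")
  invisible(x)
}
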