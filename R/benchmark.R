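#' Benchmark configuration
#'
#' @param binarize_threshold log2-scale expression threshold separating
#'   measured expression from background (default 2.48, chosen from
#'   expression histograms of the training data).
#' @param n_boot bootstrap iterations (default 1000).
#' @param ci_level confidence level of the ROC bands (default 0.95).
#' @param fpr_grid common false-positive-rate grid for curve averaging.
#' @param seed integer seed.
#' @return a `BenchmarkConfig` list.
#' @export
benchmark_config <- function(binarize_threshold = 2.48, n_boot = 1000L,
                             ci_level = 0.95,
                             fpr_grid = seq(0, 1, by = 0.02), seed = 1L) {
  if (!is.finite(binarize_threshold))
    stop("binarize_threshold must be finite", call. = FALSE)
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  if (ci_level <= 0 || ci_level >= 1)
    stop("ci_level must be in (0,1)", call. = FALSE)
  structure(list(binarize_threshold = binarize_threshold,
                 n_boot = as.integer(n_boot), ci_level = ci_level,
                 fpr_grid = fpr_grid, seed = as.integer(seed)),
            class = "BenchmarkConfig")
}

#' Binarize log2 expression
#'
#' A gene counts as expressed when its value is strictly greater than the
#' threshold; values at the threshold, and missing values, are not
#' expressed (boundary rule: strict `>`).
#'
#' @param ds a log2-scale [ExpressionDataset].
#' @param threshold log2 threshold (default 2.48).
#' @return logical gene x sample matrix.
#' @export
binarize <- function(ds, threshold = 2.48) {
  if (ds$value_scale != "log2")
    stop("binarization expects a log2-scale dataset", call. = FALSE)
  ds$values > threshold & !ds$missing_mask
}

#' Fisher exact enrichment score for one sample
#'
#' Builds the 2x2 table (in-set vs out-of-set) x (expressed vs not) for one
#' sample's binarized expression and returns the one-sided (enrichment)
#' hypergeometric p-value; the score used downstream is `-log10(p)`.
#'
#' @param sample_bits named logical vector (expressed per gene).
#' @param gene_set character vector of gene ids (subset of the universe).
#' @param universe character vector of all gene ids (default:
#'   `names(sample_bits)`).
#' @return list with `p_value`, `score` (`-log10(p)`), and the 2x2 `table`.
#' @export
fisher_score <- function(sample_bits, gene_set, universe = NULL) {
  universe <- universe %||% names(sample_bits)
  if (is.null(universe)) stop("universe (gene ids) required", call. = FALSE)
  bad <- setdiff(gene_set, universe)
  if (length(bad))
    stopf("gene set contains gene(s) outside the universe: %s",
          paste(head(bad, 5), collapse = ", "))
  if (!length(setdiff(universe, gene_set)))
    stop("universe equals the gene set; no complement to test against",
         call. = FALSE)
  bits <- sample_bits[universe]
  in_set <- universe %in% gene_set
  k <- sum(bits & in_set)          # expressed, in set
  m <- sum(in_set)                 # set size
  n <- length(universe) - m        # complement size
  q <- sum(bits)                   # expressed overall
  # P[X >= k] for X ~ Hypergeometric(m, n, q)
  p <- phyper(k - 1, m, n, q, lower.tail = FALSE)
  list(p_value = p, score = -log10(p),
       table = matrix(c(k, m - k, q - k, n - (q - k)), 2, 2,
                      dimnames = list(c("expressed", "not_expressed"),
                                      c("in_set", "out_set"))))
}

#' Scramble a dataset by gene- and sample-wise resampling
#'
#' Draws every entry with replacement: the scrambled value of gene g in
#' sample s is the original value of gene g in a randomly chosen sample,
#' independently per entry. The result has the same shape, each gene's
#' marginal support is preserved up to resampling, and cross-gene (and
#' cross-sample) correlation structure is destroyed.
#'
#' @param ds an [ExpressionDataset].
#' @param seed integer seed.
#' @return a scrambled [ExpressionDataset] with an all-false missing mask
#'   (resampled entries carry the -1 encoding if the source was masked).
#' @export
scramble_dataset <- function(ds, seed = 1L) {
  v <- ds$values
  v[ds$missing_mask] <- -1
  n_g <- nrow(v); n_s <- ncol(v)
  out <- with_seed(seed, {
    pick_sample <- matrix(sample.int(n_s, n_g * n_s, replace = TRUE),
                          n_g, n_s)
    matrix(v[cbind(rep(seq_len(n_g), n_s), as.vector(pick_sample))],
           n_g, n_s)
  })
  dimnames(out) <- dimnames(v)
  mask <- out == -1
  out[mask] <- 0
  ExpressionDataset(out, mask, gene_annotation = ds$gene_annotation,
                    sample_meta = ds$sample_meta,
                    value_scale = ds$value_scale)
}

# interpolate one ROC onto a common FPR grid (step-function, conservative)
interp_roc <- function(roc, fpr_grid) {
  vapply(fpr_grid, function(f) max(roc$tpr[roc$fpr <= f], 0), 0)
}

#' Benchmark gene sets by Fisher-exact ROC with bootstrap bands
#'
#' Per iteration: the labeled dataset is scrambled (gene- and sample-wise
#' resampling); real samples (positives) and scrambled samples (negatives)
#' are scored by the `-log10` Fisher enrichment p-value of the gene set on
#' their binarized expression; the scores are swept into one ROC per
#' iteration. When a gene set's name matches a cell-type label of the
#' dataset, the positives are that type's own samples (a cell-type
#' signature is only expected to light up its own type); otherwise all
#' labeled samples count as positives. Curves are interpolated onto a
#' common FPR grid and averaged, with percentile confidence bands across
#' the `n_boot` iterations.
#'
#' @param ds a labeled log2-scale [ExpressionDataset] (>= 30 samples
#'   recommended for bootstrap validity; fewer draws a warning).
#' @param gene_sets named list of character vectors (see
#'   [read_gene_sets()]).
#' @param config a [benchmark_config()].
#' @return a `BenchmarkResultList`: per gene set, `mean_auc`, `auc_ci`,
#'   `fpr_grid`, `mean_tpr`, `lower`, `upper`, `n_genes_used`, `flagged`
#'   (TRUE when the set has no overlap with the dataset's genes).
#' @export
benchmark_gene_sets <- function(ds, gene_sets, config = benchmark_config()) {
  if (ncol(ds$values) < 30)
    warnf("only %d samples; bootstrap negative controls are calibrated for >= 30",
          ncol(ds$values))
  bits_true <- binarize(ds, config$binarize_threshold)
  universe <- gene_ids(ds)
  results <- vector("list", length(gene_sets))
  names(results) <- names(gene_sets)
  for (si in seq_along(gene_sets)) {
    gs <- intersect(gene_sets[[si]], universe)
    if (!length(gs)) {
      results[[si]] <- structure(
        list(name = names(gene_sets)[si], flagged = TRUE, n_genes_used = 0L,
             mean_auc = NA_real_, auc_ci = c(NA_real_, NA_real_),
             fpr_grid = config$fpr_grid,
             mean_tpr = rep(NA_real_, length(config$fpr_grid)),
             lower = rep(NA_real_, length(config$fpr_grid)),
             upper = rep(NA_real_, length(config$fpr_grid))),
        class = "BenchmarkResult")
      next
    }
    in_set <- universe %in% gs
    m <- sum(in_set); n_out <- length(universe) - m
    score_cols <- function(bits) {
      k <- colSums(bits[in_set, , drop = FALSE])
      q <- colSums(bits)
      -log10(phyper(k - 1, m, n_out, q, lower.tail = FALSE))
    }
    labels <- cell_types(ds)
    pos_cols <- if (names(gene_sets)[si] %in% labels)
      which(labels == names(gene_sets)[si]) else seq_along(labels)
    pos_scores <- score_cols(bits_true)[pos_cols]
    aucs <- numeric(config$n_boot)
    tprs <- matrix(0, config$n_boot, length(config$fpr_grid))
    for (b in seq_len(config$n_boot)) {
      scr <- scramble_dataset(ds, seed = derive_seed(config$seed,
                                                     paste0("boot", b)))
      neg_scores <- score_cols(binarize(scr, config$binarize_threshold))
      roc <- roc_points(pos_scores, neg_scores)
      aucs[b] <- auc_trapezoid(roc)
      tprs[b, ] <- interp_roc(roc, config$fpr_grid)
    }
    a <- (1 - config$ci_level) / 2
    results[[si]] <- structure(
      list(name = names(gene_sets)[si], flagged = FALSE, n_genes_used = m,
           mean_auc = mean(aucs),
           auc_ci = unname(quantile(aucs, c(a, 1 - a))),
           fpr_grid = config$fpr_grid, mean_tpr = colMeans(tprs),
           lower = apply(tprs, 2, quantile, a),
           upper = apply(tprs, 2, quantile, 1 - a)),
      class = "BenchmarkResult")
  }
  structure(results, class = "BenchmarkResultList")
}

#' @export
print.BenchmarkResult <- function(x, ...) {
  if (x$flagged)
    cat(sprintf("BenchmarkResult '%s': FLAGGED (no overlap with universe)\n",
                x$name))
  else
    cat(sprintf("BenchmarkResult '%s': %d genes, mean AUC %.3f [%.3f, %.3f]\n",
                x$name, x$n_genes_used, x$mean_auc, x$auc_ci[1],
                x$auc_ci[2]))
  invisible(x)
}

#' @export
print.BenchmarkResultList <- function(x, ...) {
  for (r in x) print(r)
  invisible(x)
}
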