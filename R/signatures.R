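#' Build one cell type's gene signature (binary refinement)
#'
#' Step two of the two-step procedure. Both splits are restricted to the
#' genes selected by the parent multiclass classifier; labels become
#' one-vs-rest for `cell_type`; the training split is augmented exactly as
#' in step one; a binary elastic-net is fitted per lambda (warm-started);
#' each lambda is scored by ROC with held-out samples of `cell_type` as
#' positives (scored by the positive-class probability) and bootstrap
#' synthetic samples as negatives; the penalty is selected by the same rule
#' family; the signature is the nonzero-coefficient genes at the selected
#' lambda. Genes with negative coefficients are flagged: their presence
#' argues *against* the cell type.
#'
#' @param ds_train,ds_test labeled log2-scale [ExpressionDataset]s sharing
#'   the parent's gene universe.
#' @param parent_model the multiclass `ClassifierModel` (>= 1 selected
#'   gene).
#' @param cell_type label to refine (must be present in the training
#'   labels with >= 2 samples).
#' @param lambda_grid,spec,params,rule,n_negatives,seed as in
#'   [train_celltype_classifier()].
#' @return a `GeneSignature`: list with `cell_type`, `entries` (data.frame
#'   `gene_id`, `coefficient`, `negative_impact`), `lambda_used`,
#'   `auc_at_selection`, `auc_one_vs_rest` (diagnostic against real
#'   negatives), `evaluations`.
#' @export
build_signature <- function(ds_train, ds_test, parent_model, cell_type,
                            lambda_grid = default_lambda_grid(),
                            spec = penalty_spec(), params = augment_params(),
                            rule = "max_auc_smallest_lambda",
                            n_negatives = NULL, seed = 1L) {
  genes <- selected_genes(parent_model)
  if (!length(genes))
    stop("parent model has no selected genes", call. = FALSE)
  y_tr <- cell_types(ds_train)
  if (sum(y_tr == cell_type, na.rm = TRUE) < 2)
    stopf("cell type '%s' has fewer than 2 training samples", cell_type)
  tr <- subset_dataset(ds_train, genes = genes)
  te <- subset_dataset(ds_test, genes = genes)
  aug <- augment_training_set(tr, params)
  y_bin <- factor(ifelse(aug$y == cell_type, cell_type, "rest"),
                  levels = c("rest", cell_type))
  fits <- fit_enet_grid(aug$x, y_bin, lambda_grid, spec,
                        family = "binomial")
  x_test <- encode_missing(te)
  y_te <- cell_types(te)
  pos_idx <- which(y_te == cell_type)
  if (!length(pos_idx))
    stopf("cell type '%s' has no held-out samples", cell_type)
  x_neg <- make_bootstrap_negatives(te, n_negatives, seed = seed)
  evals <- lapply(fits, function(model) {
    p_pos <- predict_proba(model, x_test)[, cell_type]
    p_neg <- predict_proba(model, x_neg)[, cell_type]
    roc <- roc_points(p_pos[pos_idx], p_neg)
    ovr <- roc_points(p_pos[pos_idx], p_pos[-pos_idx])
    structure(list(lambda = model$penalty$lambda, roc = roc,
                   auc = auc_trapezoid(roc),
                   auc_one_vs_rest = if (length(pos_idx) < length(y_te))
                     auc_trapezoid(ovr) else NA_real_,
                   n_nonzero_genes = length(selected_genes(model)),
                   model = model, converged = model$converged),
              class = "LambdaEvaluation")
  })
  evals <- structure(evals, class = "LambdaEvaluationList")
  lambda <- select_lambda(evals, rule)
  sel <- evals[[which(vapply(evals, `[[`, 0, "lambda") == lambda)[1]]]
  beta <- sel$model$coefficients[, 1]
  nz <- beta[beta != 0]
  if (!length(nz))
    stopf(paste0("signature for '%s' is empty at every acceptable lambda ",
                 "(selected lambda %g); AUCs: %s"), cell_type, lambda,
          paste(sprintf("%.3f", vapply(evals, `[[`, 0, "auc")),
                collapse = ", "))
  structure(list(
    cell_type = cell_type,
    entries = data.frame(gene_id = names(nz), coefficient = unname(nz),
                         negative_impact = unname(nz) < 0),
    lambda_used = lambda, auc_at_selection = sel$auc,
    auc_one_vs_rest = sel$auc_one_vs_rest,
    evaluations = evals), class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("GeneSignature '%s': %d genes (%d negative-impact), lambda = %g, AUC = %.3f\n",
              x$cell_type, nrow(x$entries), sum(x$entries$negative_impact),
              x$lambda_used, x$auc_at_selection))
  invisible(x)
}

#' Build signatures for every cell type of a parent classifier
#'
#' @inheritParams build_signature
#' @return named list of `GeneSignature`s (class `GeneSignatureList`), one
#'   per class label of the parent model; the per-type lambda/AUC table is
#'   available via [signature_summary()].
#' @export
build_all_signatures <- function(ds_train, ds_test, parent_model,
                                 lambda_grid = default_lambda_grid(),
                                 spec = penalty_spec(),
                                 params = augment_params(),
                                 rule = "max_auc_smallest_lambda",
                                 n_negatives = NULL, seed = 1L) {
  sigs <- lapply(parent_model$class_labels, function(ct)
    build_signature(ds_train, ds_test, parent_model, ct, lambda_grid, spec,
                    params, rule, n_negatives,
                    seed = derive_seed(seed, paste0("signature_", ct))))
  structure(setNames(sigs, parent_model$class_labels),
            class = "GeneSignatureList")
}

#' Per-cell-type lambda and AUC summary of a signature list
#' @param sigs a `GeneSignatureList`.
#' @return data.frame with one row per cell type.
#' @export
signature_summary <- function(sigs) {
  data.frame(cell_type = vapply(sigs, `[[`, "", "cell_type"),
             n_genes = vapply(sigs, function(s) nrow(s$entries), 0L),
             n_negative = vapply(sigs, function(s)
               sum(s$entries$negative_impact), 0L),
             lambda = vapply(sigs, `[[`, 0, "lambda_used"),
             auc = vapply(sigs, `[[`, 0, "auc_at_selection"),
             auc_one_vs_rest = vapply(sigs, `[[`, 0, "auc_one_vs_rest"),
             row.names = NULL)
}

#' Write / read gene signatures (TSV)
#'
#' Columns: `cell_type`, `gene_id`, `coefficient`, `negative_impact`.
#' Round-trips losslessly (selection metadata lambda/AUC travels in
#' companion columns `lambda_used`, `auc_at_selection`).
#'
#' @param sigs a `GeneSignatureList` (or list of `GeneSignature`).
#' @param path TSV path.
#' @return `export_signatures()` returns `path` invisibly;
#'   `read_signatures()` a `GeneSignatureList` (without evaluation traces).
#' @export
export_signatures <- function(sigs, path) {
  rows <- lapply(sigs, function(s)
    cbind(s$entries, cell_type = s$cell_type, lambda_used = s$lambda_used,
          auc_at_selection = s$auc_at_selection))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), coefficient = numeric(0),
               negative_impact = logical(0), cell_type = character(0),
               lambda_used = numeric(0), auc_at_selection = numeric(0))
  df <- df[c("cell_type", "gene_id", "coefficient", "negative_impact",
             "lambda_used", "auc_at_selection")]
  write.table(format(df, digits = 17, scientific = NA, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname export_signatures
#' @export
read_signatures <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("cell_type", "gene_id", "coefficient", "negative_impact",
            "lambda_used", "auc_at_selection")
  if (!all(need %in% names(df)))
    stopf("signature file %s lacks column(s): %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  if (!nrow(df)) return(structure(list(), class = "GeneSignatureList"))
  sigs <- lapply(split(df, df$cell_type), function(d)
    structure(list(cell_type = d$cell_type[1],
                   entries = data.frame(gene_id = d$gene_id,
                                        coefficient = d$coefficient,
                                        negative_impact =
                                          as.logical(d$negative_impact)),
                   lambda_used = d$lambda_used[1],
                   auc_at_selection = d$auc_at_selection[1],
                   auc_one_vs_rest = NA_real_, evaluations = NULL),
              class = "GeneSignature"))
  structure(sigs[unique(df$cell_type)], class = "GeneSignatureList")
}
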