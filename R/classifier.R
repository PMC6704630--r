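#' Missing-value augmentation parameters
#'
#' The training set is duplicated `duplication_factor` times; within each
#' replicate an independent `dropout_fraction` of the originally non-missing
#' entries is blanked, and every blank (original or introduced) is encoded
#' as the dummy constant -1. Teaching the model to treat -1 as noise lets it
#' tolerate the genuinely missing values of merged multi-study data.
#'
#' @param duplication_factor replicates of the training set (default 100).
#' @param dropout_fraction fraction of non-missing entries blanked per
#'   replicate, in \[0,1) (default 0.10).
#' @param seed integer seed for the dropout draws.
#' @return an `AugmentParams` list; the dummy value is fixed at -1.
#' @export
augment_params <- function(duplication_factor = 100L, dropout_fraction = 0.10,
                           seed = 1L) {
  if (duplication_factor < 1) stop("duplication_factor must be >= 1",
                                   call. = FALSE)
  if (dropout_fraction < 0 || dropout_fraction >= 1)
    stop("dropout_fraction must be in [0, 1)", call. = FALSE)
  structure(list(duplication_factor = as.integer(duplication_factor),
                 dropout_fraction = dropout_fraction, dummy_value = -1,
                 seed = as.integer(seed)),
            class = "AugmentParams")
}

#' Augment a log2-scale training set with dummy-encoded dropout
#'
#' @param ds_train a labeled log2-scale [ExpressionDataset].
#' @param params an [augment_params()].
#' @return list with `x` (augmented samples x genes matrix, -1 at every
#'   masked position) and `y` (replicated cell-type labels).
#' @export
augment_training_set <- function(ds_train, params = augment_params()) {
  if (ds_train$value_scale != "log2")
    stop("augmentation expects a log2-scale dataset", call. = FALSE)
  y0 <- cell_types(ds_train)
  if (anyNA(y0)) stop("all training samples must be labeled", call. = FALSE)
  base <- t(ds_train$values)            # samples x genes
  base_missing <- t(ds_train$missing_mask)
  n <- nrow(base); p <- ncol(base); f <- params$duplication_factor
  x <- base[rep(seq_len(n), f), , drop = FALSE]
  drop_mask <- with_seed(params$seed, {
    keep_pool <- !base_missing[rep(seq_len(n), f), , drop = FALSE]
    keep_pool & matrix(runif(n * f * p) < params$dropout_fraction, n * f, p)
  })
  x[drop_mask] <- params$dummy_value
  x[base_missing[rep(seq_len(n), f), , drop = FALSE]] <- params$dummy_value
  rownames(x) <- paste0(rep(rownames(base), f), "_rep",
                        rep(seq_len(f), each = n))
  list(x = x, y = factor(rep(y0, f)))
}

#' Encode a test matrix for prediction (plain -1 at missing positions)
#'
#' Test samples are never duplicated or dropped out; genuinely missing
#' entries become the -1 dummy.
#'
#' @param ds a log2-scale [ExpressionDataset].
#' @return samples x genes matrix.
#' @export
encode_missing <- function(ds) {
  if (ds$value_scale != "log2")
    stop("dummy encoding expects a log2-scale dataset", call. = FALSE)
  x <- t(ds$values)
  x[t(ds$missing_mask)] <- -1
  x
}

#' Bootstrap synthetic negatives
#'
#' Builds synthetic samples gene-wise: for each gene of each synthetic
#' sample, a value is drawn (with replacement) from a randomly chosen real
#' test sample. Each gene's marginal distribution is preserved while the
#' cross-gene correlation structure of real samples is destroyed; the
#' synthetic pool has size and complexity similar to the test set and
#' serves as the True-Negative class for ROC-based lambda selection.
#'
#' @param ds_test a log2-scale [ExpressionDataset] (the held-out split).
#' @param n_negatives number of synthetic samples (default: the number of
#'   test samples).
#' @param seed integer seed.
#' @return synthetic samples x genes matrix (-1 encoding applied where the
#'   resampled entry was missing).
#' @export
make_bootstrap_negatives <- function(ds_test, n_negatives = NULL, seed = 1L) {
  if (!ncol(ds_test$values)) stop("empty test set", call. = FALSE)
  x <- encode_missing(ds_test)
  n <- nrow(x); p <- ncol(x)
  n_neg <- n_negatives %||% n
  picks <- with_seed(seed, matrix(sample.int(n, n_neg * p, replace = TRUE),
                                  n_neg, p))
  out <- matrix(x[cbind(as.vector(picks), rep(seq_len(p), each = n_neg))],
                n_neg, p)
  colnames(out) <- colnames(x)
  rownames(out) <- sprintf("synthetic_negative_%d", seq_len(n_neg))
  out
}

#' Max-posterior confidence score
#'
#' The score used to sweep ROC thresholds: the maximum class posterior from
#' [predict_proba()], in \[1/K, 1\].
#'
#' @inheritParams predict_proba
#' @return numeric vector of per-sample scores.
#' @export
score_confidence <- function(model, X, fill_missing = FALSE) {
  apply(predict_proba(model, X, fill_missing = fill_missing), 1, max)
}

# ROC by threshold sweep over the pooled scores; points from (0,0) to
# (1,1), one step per distinct threshold, ties handled jointly.
roc_points <- function(pos_scores, neg_scores) {
  thr <- sort(unique(c(pos_scores, neg_scores)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos_scores >= t), 0)
  fpr <- vapply(thr, function(t) mean(neg_scores >= t), 0)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
}

#' Evaluate a lambda grid by bootstrap-negative ROC
#'
#' For each lambda: fit the multinomial elastic-net on the augmented
#' training data (warm-started along the grid), score the real test samples
#' (True Positives) and the bootstrap synthetic negatives with the
#' max-posterior confidence, sweep the score threshold into a ROC curve,
#' and record the trapezoidal AUC and the nonzero-gene count.
#'
#' @param ds_train,ds_test labeled log2-scale [ExpressionDataset]s sharing
#'   a gene set.
#' @param lambda_grid positive lambdas (default [default_lambda_grid()]).
#' @param spec a [penalty_spec()].
#' @param params an [augment_params()].
#' @param n_negatives synthetic negatives (default: size of test set).
#' @param seed integer seed for negatives (augmentation uses
#'   `params$seed`).
#' @return a `LambdaEvaluationList`: per lambda, a list with `lambda`,
#'   `roc` (data.frame of fpr/tpr), `auc`, `n_nonzero_genes`, `model`,
#'   `converged`.
#' @export
evaluate_lambda <- function(ds_train, ds_test,
                            lambda_grid = default_lambda_grid(),
                            spec = penalty_spec(), params = augment_params(),
                            n_negatives = NULL, seed = 1L) {
  if (!length(lambda_grid)) stop("lambda grid is empty", call. = FALSE)
  if (!identical(gene_ids(ds_train), gene_ids(ds_test)))
    stop("train and test datasets must share the same gene set",
         call. = FALSE)
  aug <- augment_training_set(ds_train, params)
  x_test <- encode_missing(ds_test)
  x_neg <- make_bootstrap_negatives(ds_test, n_negatives, seed = seed)
  fits <- fit_enet_grid(aug$x, aug$y, lambda_grid, spec,
                        family = "multinomial")
  evals <- lapply(fits, function(model) {
    pos <- score_confidence(model, x_test)
    neg <- score_confidence(model, x_neg)
    roc <- roc_points(pos, neg)
    structure(list(lambda = model$penalty$lambda, roc = roc,
                   auc = auc_trapezoid(roc),
                   n_nonzero_genes = length(selected_genes(model)),
                   model = model, converged = model$converged),
              class = "LambdaEvaluation")
  })
  structure(evals, class = "LambdaEvaluationList")
}

#' @export
print.LambdaEvaluationList <- function(x, ...) {
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.LambdaEvaluationList <- function(x, ...) {
  data.frame(lambda = vapply(x, `[[`, 0, "lambda"),
             auc = vapply(x, `[[`, 0, "auc"),
             n_nonzero_genes = vapply(x, `[[`, 0L, "n_nonzero_genes"),
             converged = vapply(x, `[[`, TRUE, "converged"))
}

#' Select the penalty strength from a lambda evaluation
#'
#' Two rules:
#' * `"max_auc_smallest_lambda"`: among lambdas whose AUC is within
#'   `tie_tol` of the maximum, the smallest (keeps the most genes for the
#'   signature-building step).
#' * `"inflection"`: the largest lambda beyond which increasing lambda
#'   reduces the AUC — operationalized as the AUC-maximizing lambda with
#'   ties resolved toward the larger lambda.
#'
#' @param evals a `LambdaEvaluationList` (or data.frame with `lambda`,
#'   `auc`) of length >= 2.
#' @param rule `"max_auc_smallest_lambda"` (default) or `"inflection"`.
#' @param tie_tol AUC tie tolerance (default 1e-3).
#' @return the chosen lambda.
#' @export
select_lambda <- function(evals, rule = c("max_auc_smallest_lambda",
                                          "inflection"), tie_tol = 1e-3) {
  rule <- match.arg(rule)
  df <- as.data.frame(evals)
  if (nrow(df) == 1) return(df$lambda)
  if (nrow(df) < 2) stop("need at least one evaluation", call. = FALSE)
  if (diff(range(df$auc)) < .Machine$double.eps^0.5) {
    warnf("all AUCs equal; selection rule is degenerate, returning the smallest lambda")
    return(min(df$lambda))
  }
  if (rule == "max_auc_smallest_lambda") {
    cand <- df$lambda[df$auc >= max(df$auc) - tie_tol]
    min(cand)
  } else {
    cand <- df$lambda[df$auc == max(df$auc)]
    max(cand)
  }
}

#' Train a cell-type classifier end to end
#'
#' Augments the training split, fits the multinomial elastic-net over the
#' lambda grid, evaluates every lambda by bootstrap-negative ROC, selects
#' the penalty by the requested rule, and returns the selected model
#' together with the full evaluation table and the 10-fold CV deviance
#' curve (reported alongside as a diagnostic).
#'
#' @inheritParams evaluate_lambda
#' @param rule lambda-selection rule, see [select_lambda()].
#' @param nfolds folds for the CV-deviance diagnostic (default 10; `0`
#'   skips it).
#' @return list with `model`, `lambda`, `evaluations`, `cv` (or `NULL`).
#' @export
train_celltype_classifier <- function(ds_train, ds_test,
                                      lambda_grid = default_lambda_grid(),
                                      spec = penalty_spec(),
                                      params = augment_params(),
                                      rule = "max_auc_smallest_lambda",
                                      n_negatives = NULL, nfolds = 10L,
                                      seed = 1L) {
  evals <- evaluate_lambda(ds_train, ds_test, lambda_grid, spec, params,
                           n_negatives, seed = derive_seed(seed, "negatives"))
  lambda <- select_lambda(evals, rule)
  model <- evals[[which(vapply(evals, `[[`, 0, "lambda") == lambda)[1]]]$model
  cv <- NULL
  if (nfolds >= 2) {
    aug <- augment_training_set(ds_train, params)
    cv <- suppressWarnings(
      cross_validate(aug$x, aug$y, lambda_grid, spec,
                     family = "multinomial", nfolds = nfolds,
                     seed = derive_seed(seed, "cv")))
  }
  model$training_provenance <- list(
    n_train = ncol(ds_train$values), n_test = ncol(ds_test$values),
    augmentation = unclass(params), selection_rule = rule,
    lambda_grid = lambda_grid, seed = seed)
  list(model = model, lambda = lambda, evaluations = evals, cv = cv)
}
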