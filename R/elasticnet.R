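#' Elastic-net penalty specification
#'
#' @param alpha mixing between ridge (0) and lasso (1); default 0.93, the
#'   value used throughout the cell-type classifier workflow.
#' @param lambda overall penalty strength (single positive value) or `NULL`
#'   when a grid is supplied at fit time.
#' @param grouped multinomial only: zero all class coefficients of a gene
#'   simultaneously (group-lasso penalty, default `TRUE`).
#' @param standardize penalize unit-variance-scaled features (population
#'   1/N variance) and back-transform the coefficients (default `TRUE`).
#' @param tol relative objective-change convergence threshold
#'   (default 1e-7).
#' @param max_iter maximum outer iterations (default 500).
#' @return a `PenaltySpec` list.
#' @export
penalty_spec <- function(alpha = 0.93, lambda = NULL, grouped = TRUE,
                         standardize = TRUE, tol = 1e-7, max_iter = 500L) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0,1]", call. = FALSE)
  if (!is.null(lambda) && any(lambda <= 0))
    stop("lambda values must be positive", call. = FALSE)
  if (tol <= 0 || max_iter < 1)
    stop("tol must be positive and max_iter >= 1", call. = FALSE)
  structure(list(alpha = alpha, lambda = lambda, grouped = grouped,
                 standardize = standardize, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "PenaltySpec")
}

#' The default lambda grid for classifier training
#' @return the seven-value grid `c(0.1, 0.05, 0.01, 0.005, 0.001, 5e-4, 1e-4)`.
#' @export
default_lambda_grid <- function() c(0.1, 0.05, 0.01, 0.005, 0.001, 5e-4, 1e-4)

new_classifier_model <- function(family, class_labels, gene_ids, intercepts,
                                 coefficients, penalty, converged = TRUE,
                                 training_provenance = NULL) {
  structure(list(family = family, class_labels = class_labels,
                 gene_ids = gene_ids, intercepts = intercepts,
                 coefficients = coefficients, penalty = penalty,
                 converged = converged,
                 training_provenance = training_provenance),
            class = "ClassifierModel")
}

#' @export
print.ClassifierModel <- function(x, ...) {
  cat(sprintf("ClassifierModel (%s): %d classes, %d genes (%d selected)\n",
              x$family, length(x$class_labels), length(x$gene_ids),
              length(selected_genes(x))))
  cat(sprintf("  alpha = %g, lambda = %g%s\n", x$penalty$alpha,
              x$penalty$lambda,
              if (isTRUE(x$converged)) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Genes with any nonzero coefficient
#' @param model a `ClassifierModel`.
#' @return character vector of selected gene ids.
#' @export
selected_genes <- function(model) {
  if (!nrow(model$coefficients)) return(character(0))
  model$gene_ids[rowSums(model$coefficients != 0) > 0]
}

# Standardize columns with population (1/N) variance; constant columns get
# scale 1 and can never acquire a nonzero coefficient (their centered values
# are all zero).
standardize_columns <- function(X) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  scl <- sqrt(colMeans(Xc^2))
  scl[scl == 0] <- 1
  list(X = sweep(Xc, 2, scl, "/"), center = ctr, scale = scl)
}

# Shared path fitter behind the two public fit functions.
fit_enet_path <- function(X, Y, lambda_grid, spec, binary) {
  ord <- order(lambda_grid, decreasing = TRUE)
  lam <- lambda_grid[ord]
  std <- NULL
  Xf <- X
  if (spec$standardize) {
    std <- standardize_columns(X)
    Xf <- std$X
  }
  fit <- .enet_path(Xf, Y, lam, spec$alpha, spec$grouped, spec$tol,
                    spec$max_iter, binary)
  back <- lapply(seq_along(lam), function(i) {
    B <- fit$beta[[i]]
    b0 <- as.numeric(fit$intercepts[[i]])
    if (!is.null(std)) {
      B <- B / std$scale
      b0 <- b0 - as.numeric(crossprod(B, std$center))
    }
    list(beta = B, b0 = b0, objective = fit$objective[i],
         converged = fit$converged[i], lambda = lam[i])
  })
  back[order(ord)]  # restore caller's grid order
}

#' Fit a multinomial elastic-net logistic regression
#'
#' Minimizes the negative multinomial log-likelihood (averaged over samples)
#' plus `lambda * sum_j P_j`, where for `grouped = TRUE`
#' `P_j = (1-alpha)/2 * ||beta_j||_2^2 + alpha * ||beta_j||_2` over the K
#' class coefficients of gene j (group lasso: a gene's coefficients vanish
#' all together), and for `grouped = FALSE` the l2/l1 mix applies
#' componentwise. Solved by cyclic block coordinate descent with group
#' soft-thresholding inside an outer quadratic majorization; when a grid is
#' supplied, lambdas are fitted from largest to smallest with warm starts.
#'
#' @param X sample x gene numeric matrix (log2 scale; -1 dummies allowed),
#'   with column names.
#' @param y cell-type labels, one per row of X (at least 2 classes, each
#'   with at least 2 samples).
#' @param spec a [penalty_spec()]; `spec$lambda` must hold a single value
#'   (use [fit_enet_grid()] for a whole path).
#' @return a `ClassifierModel`.
#' @export
fit_multinomial_elasticnet <- function(X, y, spec = penalty_spec()) {
  fits <- fit_enet_grid(X, y, lambda_grid = spec$lambda, spec = spec,
                        family = "multinomial")
  fits[[1]]
}

#' Fit a binary elastic-net logistic regression
#'
#' Single-coefficient-vector parameterization of the two-class problem; the
#' second level of `factor(y)` (or the value 1/TRUE) is the positive class.
#' One-vs-rest encoding is the caller's responsibility.
#'
#' @inheritParams fit_multinomial_elasticnet
#' @param y binary labels (logical, 0/1, or a 2-level factor).
#' @return a `ClassifierModel` with `family = "binomial"`.
#' @export
fit_binary_elasticnet <- function(X, y, spec = penalty_spec()) {
  fits <- fit_enet_grid(X, y, lambda_grid = spec$lambda, spec = spec,
                        family = "binomial")
  fits[[1]]
}

#' Fit an elastic-net path over a lambda grid (warm-started)
#'
#' @inheritParams fit_multinomial_elasticnet
#' @param lambda_grid positive lambda values (any order; fitted descending).
#' @param family `"multinomial"` or `"binomial"`.
#' @return list of `ClassifierModel`s, one per grid value, in the order of
#'   `lambda_grid`.
#' @export
fit_enet_grid <- function(X, y, lambda_grid, spec = penalty_spec(),
                          family = c("multinomial", "binomial")) {
  family <- match.arg(family)
  if (is.null(lambda_grid) || !length(lambda_grid))
    stop("lambda grid is empty", call. = FALSE)
  if (any(lambda_grid <= 0)) stop("lambda must be positive", call. = FALSE)
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    stop("X must carry gene ids as column names", call. = FALSE)
  if (!all(is.finite(X))) stop("X contains non-finite values", call. = FALSE)
  yf <- factor(y)
  if (length(yf) != nrow(X))
    stop("length(y) does not match nrow(X)", call. = FALSE)
  K <- nlevels(yf)
  if (K < 2) stop("need at least two classes", call. = FALSE)
  if (family == "binomial" && K != 2)
    stop("binary fit needs exactly two classes", call. = FALSE)
  if (any(table(yf) < 2))
    stop("every class needs at least two samples", call. = FALSE)
  binary <- family == "binomial"
  Y <- if (binary) matrix(as.numeric(yf == levels(yf)[2]), ncol = 1) else {
    Z <- matrix(0, nrow(X), K)
    Z[cbind(seq_len(nrow(X)), as.integer(yf))] <- 1
    Z
  }
  path <- fit_enet_path(X, Y, lambda_grid, spec, binary)
  lapply(path, function(f) {
    co <- f$beta
    rownames(co) <- colnames(X)
    colnames(co) <- if (binary) levels(yf)[2] else levels(yf)
    if (any(!f$converged))
      warnf("elastic-net fit at lambda = %g did not converge in %d iterations",
            f$lambda, spec$max_iter)
    new_classifier_model(
      family = family, class_labels = levels(yf), gene_ids = colnames(X),
      intercepts = setNames(f$b0, colnames(co)), coefficients = co,
      penalty = list(alpha = spec$alpha, lambda = f$lambda,
                     grouped = spec$grouped && !binary,
                     standardize = spec$standardize, tol = spec$tol,
                     max_iter = spec$max_iter),
      converged = all(f$converged))
  })
}

#' Smallest lambda that forces an all-zero coefficient matrix
#'
#' Data-derived null-model boundary: with intercepts at the class
#' log-frequencies, `lambda_max = max_j ||(1/N) X_j'(Y - P0)|| / alpha`
#' (group 2-norm when grouped, absolute value otherwise), computed on the
#' standardized design when `spec$standardize`.
#'
#' @inheritParams fit_enet_grid
#' @return the boundary lambda (infinite when `alpha = 0`).
#' @export
lambda_max <- function(X, y, spec = penalty_spec(),
                       family = c("multinomial", "binomial")) {
  family <- match.arg(family)
  X <- as.matrix(X)
  yf <- factor(y)
  if (spec$alpha == 0) return(Inf)
  if (spec$standardize) X <- standardize_columns(X)$X
  N <- nrow(X)
  if (family == "binomial") {
    yb <- as.numeric(yf == levels(yf)[2])
    g <- abs(crossprod(X, yb - mean(yb)) / N)
    return(max(g) / spec$alpha)
  }
  K <- nlevels(yf)
  Y <- matrix(0, N, K); Y[cbind(seq_len(N), as.integer(yf))] <- 1
  P0 <- matrix(colMeans(Y), N, K, byrow = TRUE)
  G <- crossprod(X, Y - P0) / N
  if (spec$grouped) max(sqrt(rowSums(G^2))) / spec$alpha
  else max(abs(G)) / spec$alpha
}

#' Class posterior probabilities
#'
#' Aligns the columns of `X` to the model's genes and returns the softmax of
#' the class scores (binary models return two columns, `1 - p` and `p`).
#' Genes absent from `X` are filled with the -1 dummy only when
#' `fill_missing = TRUE`; otherwise a misaligned gene set is an error.
#'
#' @param model a `ClassifierModel`.
#' @param X sample x gene matrix with column names.
#' @param fill_missing fill genes absent from `X` with -1 (default `FALSE`).
#' @return sample x class probability matrix; rows sum to 1.
#' @export
predict_proba <- function(model, X, fill_missing = FALSE) {
  X <- as.matrix(X)
  genes <- model$gene_ids
  if (length(genes)) {
    missing <- setdiff(genes, colnames(X))
    if (length(missing) && !fill_missing)
      stopf(paste0("%d model gene(s) absent from X (e.g. %s); ",
                   "set fill_missing = TRUE to encode them as -1"),
            length(missing), paste(head(missing, 5), collapse = ", "))
    Xa <- matrix(-1, nrow(X), length(genes),
                 dimnames = list(rownames(X), genes))
    common <- intersect(genes, colnames(X))
    Xa[, common] <- X[, common, drop = FALSE]
  } else {
    Xa <- matrix(0, nrow(X), 0)
  }
  if (model$family == "binomial") {
    eta <- as.numeric(model$intercepts[1] + Xa %*% model$coefficients[, 1])
    p <- 1 / (1 + exp(-eta))
    out <- cbind(1 - p, p)
    colnames(out) <- model$class_labels
  } else {
    eta <- sweep(Xa %*% model$coefficients, 2, model$intercepts, "+")
    eta <- eta - apply(eta, 1, max)
    e <- exp(eta)
    out <- e / rowSums(e)
    colnames(out) <- model$class_labels
  }
  rownames(out) <- rownames(X)
  out
}

#' Hard class assignment (argmax posterior; ties break to the first class
#' in the model's class order)
#' @inheritParams predict_proba
#' @return character vector of class labels.
#' @export
predict_class <- function(model, X, fill_missing = FALSE) {
  p <- predict_proba(model, X, fill_missing = fill_missing)
  model$class_labels[apply(p, 1, which.max)]
}

#' Cross-validated deviance along a lambda grid
#'
#' Stratified k-fold assignment derived from `seed`; per lambda, the mean
#' held-out multinomial (or binomial) deviance `-2/n * sum log p_true`
#' across folds. When a class has fewer members than `nfolds` the
#' stratification degrades gracefully (that class simply misses some folds)
#' with a warning.
#'
#' @inheritParams fit_enet_grid
#' @param nfolds number of folds (default 10).
#' @param seed integer seed for fold assignment.
#' @return data.frame with columns `lambda`, `cv_deviance`, `cv_se`.
#' @export
cross_validate <- function(X, y, lambda_grid, spec = penalty_spec(),
                           family = c("multinomial", "binomial"),
                           nfolds = 10L, seed = 1L) {
  family <- match.arg(family)
  if (is.null(lambda_grid) || !length(lambda_grid))
    stop("lambda grid is empty", call. = FALSE)
  X <- as.matrix(X)
  yf <- factor(y)
  if (min(table(yf)) < nfolds)
    warnf("smallest class (%d samples) has fewer members than nfolds (%d); stratification is partial",
          min(table(yf)), nfolds)
  folds <- with_seed(seed, {
    f <- integer(length(yf))
    for (lv in levels(yf)) {
      idx <- which(yf == lv)
      f[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
    }
    f
  })
  dev <- matrix(NA_real_, nfolds, length(lambda_grid))
  for (k in seq_len(nfolds)) {
    tr <- folds != k
    if (all(tr) || !any(tr)) next
    if (nlevels(droplevels(yf[tr])) < nlevels(yf)) next
    fits <- fit_enet_grid(X[tr, , drop = FALSE], yf[tr], lambda_grid, spec,
                          family)
    for (i in seq_along(fits)) {
      p <- predict_proba(fits[[i]], X[!tr, , drop = FALSE])
      ptrue <- p[cbind(seq_len(sum(!tr)), as.integer(yf[!tr]))]
      dev[k, i] <- -2 * mean(log(pmax(ptrue, 1e-15)))
    }
  }
  data.frame(lambda = lambda_grid,
             cv_deviance = colMeans(dev, na.rm = TRUE),
             cv_se = apply(dev, 2, function(z)
               sd(z, na.rm = TRUE) / sqrt(sum(!is.na(z)))))
}
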