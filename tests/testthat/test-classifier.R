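log2_ds <- function(m, miss = NULL, labels = NULL) {
  dimnames(m) <- list(paste0("g", seq_len(nrow(m))),
                      paste0("s", seq_len(ncol(m))))
  if (!is.null(miss)) dimnames(miss) <- dimnames(m)
  meta <- if (!is.null(labels))
    data.frame(sample_id = colnames(m), cell_type = labels,
               study_id = "st1")
  ds <- ExpressionDataset(m, miss, sample_meta = meta,
                          value_scale = "log2")
  ds
}

test_that("augmentation yields factor-many rows and the expected dummy fraction", {
  set.seed(5)
  p <- 200; n <- 10
  miss <- matrix(runif(p * n) < 0.2, p, n)
  m <- matrix(runif(p * n, 0, 10), p, n)
  m[miss] <- 0
  ds <- log2_ds(m, miss, labels = rep(c("a", "b"), 5))
  aug <- augment_training_set(ds, augment_params(duplication_factor = 100,
                                                 dropout_fraction = 0.10,
                                                 seed = 7))
  expect_identical(nrow(aug$x), 1000L)           # 10 samples x 100
  expect_identical(length(aug$y), 1000L)
  expect_identical(as.character(aug$y), rep(rep(c("a", "b"), 5), 100))
  m_frac <- mean(miss)
  expected <- m_frac + 0.10 * (1 - m_frac)
  expect_equal(mean(aug$x == -1), expected, tolerance = 0.01)
  # originally-missing entries are -1 in every replicate
  first_rep <- aug$x[1:10, ]
  expect_true(all(first_rep[t(miss)] == -1))
})

test_that("augmentation degenerates to exact copies without dropout or missing", {
  m <- matrix(runif(60, 1, 5), 6, 10)
  ds <- log2_ds(m, labels = rep(c("a", "b"), 5))
  aug <- augment_training_set(ds, augment_params(duplication_factor = 3,
                                                 dropout_fraction = 0))
  expect_identical(nrow(aug$x), 30L)
  for (r in 1:3)
    expect_equal(unname(aug$x[(r - 1) * 10 + 1:10, ]), unname(t(m)))
  expect_error(augment_params(dropout_fraction = 1), "dropout")
  same1 <- augment_training_set(ds, augment_params(seed = 3))
  same2 <- augment_training_set(ds, augment_params(seed = 3))
  expect_identical(same1, same2)
})

test_that("bootstrap negatives resample per-gene marginals and break correlation", {
  set.seed(6)
  n <- 40
  g1 <- runif(n, 0, 10)
  m <- rbind(g1, g1 * 0.9 + 0.3, matrix(runif(5 * n, 0, 10), 5, n))
  ds <- log2_ds(m, labels = rep(c("a", "b"), n / 2))
  neg <- make_bootstrap_negatives(ds, n_negatives = 500, seed = 9)
  expect_identical(dim(neg), c(500L, 7L))
  x <- encode_missing(ds)
  for (j in 1:7) expect_true(all(neg[, j] %in% x[, j]))
  # planted co-expressed pair: correlation collapses in the synthetic pool
  r_real <- cor(x[, 1], x[, 2])
  r_syn <- cor(neg[, 1], neg[, 2])
  expect_lt(abs(r_syn), 0.2 * abs(r_real))
  # single test sample: synthetic samples are copies
  one <- log2_ds(matrix(1:5, 5, 1), labels = "a")
  neg1 <- make_bootstrap_negatives(one, n_negatives = 3, seed = 1)
  for (i in 1:3) expect_equal(unname(neg1[i, ]), as.numeric(1:5))
  # default pool size equals the test-set size, deterministic under seed
  expect_equal(nrow(make_bootstrap_negatives(ds, seed = 2)), n)
  expect_identical(make_bootstrap_negatives(ds, seed = 2),
                   make_bootstrap_negatives(ds, seed = 2))
})

test_that("confidence scores span [1/K, 1] and ignore class order", {
  fx <- small_fixture()
  model <- fx$trained$model
  K <- length(model$class_labels)
  X <- encode_missing(fx$test)
  s <- score_confidence(model, X)
  expect_true(all(s >= 1 / K - 1e-12 & s <= 1))
  # uniform posterior scores exactly 1/K
  unif <- model
  unif$coefficients[] <- 0
  unif$intercepts[] <- 0
  expect_equal(unname(score_confidence(unif, X)), rep(1 / K, nrow(X)))
  # permuting class columns leaves the max-posterior score unchanged
  perm <- c(2, 1, 4, 3)
  pm <- model
  pm$class_labels <- model$class_labels[perm]
  pm$intercepts <- model$intercepts[perm]
  pm$coefficients <- model$coefficients[, perm]
  expect_equal(score_confidence(pm, X), s)
})

test_that("ROC construction matches pair-counting on fixed score sets", {
  r1 <- enetsig:::roc_points(c(0.9, 0.8), c(0.7, 0.6))
  expect_equal(enetsig:::auc_trapezoid(r1), 1)
  r2 <- enetsig:::roc_points(c(0.9, 0.6), c(0.8, 0.7))
  expect_equal(enetsig:::auc_trapezoid(r2), 0.5)
  expect_equal(r1$fpr[1], 0)
  expect_equal(r1$tpr[nrow(r1)], 1)
  expect_true(all(diff(r1$fpr) >= 0) && all(diff(r1$tpr) >= 0))
})

test_that("ROC/AUC agrees with the independent pROC implementation", {
  set.seed(14)
  pos <- rnorm(80, 1); neg <- rnorm(120)
  mine <- enetsig:::auc_trapezoid(enetsig:::roc_points(pos, neg))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 80), rep(0, 120)), predictor = c(pos, neg),
    quiet = TRUE, direction = "<")))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("stored ROC curves satisfy the trapezoid and monotonicity invariants", {
  fx <- small_fixture()
  for (ev in fx$trained$evaluations) {
    expect_true(all(diff(ev$roc$fpr) >= 0))
    expect_true(all(diff(ev$roc$tpr) >= 0))
    expect_equal(ev$roc$fpr[1], 0)
    expect_equal(ev$auc, enetsig:::auc_trapezoid(ev$roc),
                 tolerance = 1e-12)
    expect_true(ev$auc >= 0 && ev$auc <= 1)
  }
})

test_that("lambda selection implements both published rules", {
  df1 <- data.frame(lambda = c(0.1, 0.01, 0.001),
                    auc = c(0.90, 0.95, 0.95))
  expect_equal(select_lambda(df1, "max_auc_smallest_lambda"), 0.001)
  df2 <- data.frame(lambda = c(0.1, 0.05, 0.01),
                    auc = c(0.90, 0.97, 0.96))
  expect_equal(select_lambda(df2, "inflection"), 0.05)
  # inflection ties resolve to the larger lambda
  df3 <- data.frame(lambda = c(0.1, 0.05, 0.01),
                    auc = c(0.90, 0.97, 0.97))
  expect_equal(select_lambda(df3, "inflection"), 0.05)
  expect_equal(select_lambda(data.frame(lambda = 0.3, auc = 0.8)), 0.3)
  expect_warning(sel <- select_lambda(
    data.frame(lambda = c(0.1, 0.01), auc = c(0.9, 0.9))), "degenerate")
  expect_equal(sel, 0.01)
})

test_that("lambda evaluation separates a well-trained model from chance", {
  fx <- small_fixture()
  evals <- fx$trained$evaluations
  expect_identical(vapply(evals, `[[`, 0, "lambda"), default_lambda_grid())
  expect_gt(max(vapply(evals, `[[`, 0, "auc")), 0.95)
  # identical seeds reproduce the evaluation bitwise
  again <- suppressWarnings(evaluate_lambda(
    fx$train, fx$test, lambda_grid = c(0.1, 0.05),
    params = augment_params(duplication_factor = 5, seed = 3),
    seed = 77))
  again2 <- suppressWarnings(evaluate_lambda(
    fx$train, fx$test, lambda_grid = c(0.1, 0.05),
    params = augment_params(duplication_factor = 5, seed = 3),
    seed = 77))
  expect_identical(lapply(again, `[`, c("lambda", "roc", "auc")),
                   lapply(again2, `[`, c("lambda", "roc", "auc")))
})

test_that("marker genes earn positive own-type coefficients, absent genes negative", {
  fx <- small_fixture()
  model <- fx$trained$model
  truth <- fx$bulk$truth
  sel <- selected_genes(model)
  pos_ok <- 0; pos_tot <- 0
  for (ct in names(truth$markers)) {
    found <- intersect(truth$markers[[ct]], sel)
    pos_tot <- pos_tot + length(found)
    pos_ok <- pos_ok + sum(model$coefficients[found, ct] > 0)
  }
  expect_gte(pos_ok / pos_tot, 0.9)
  neg_ok <- 0; neg_tot <- 0
  for (ct in names(truth$absent)) {
    found <- intersect(truth$absent[[ct]], sel)
    neg_tot <- neg_tot + length(found)
    neg_ok <- neg_ok + sum(model$coefficients[found, ct] < 0)
  }
  expect_gte(neg_ok / neg_tot, 0.9)
})
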