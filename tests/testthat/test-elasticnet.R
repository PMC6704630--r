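test_that("solver reaches the generic-optimizer optimum on tiny instances", {
  for (inst in tiny_instances()) {
    K <- length(unique(inst$y))
    for (alpha in c(0, 0.5, 0.93, 1)) {
      for (grouped in if (K > 2) c(TRUE, FALSE) else TRUE) {
        spec <- penalty_spec(alpha = alpha, lambda = 0.05,
                             grouped = grouped, standardize = FALSE,
                             tol = 1e-10, max_iter = 5000)
        fit <- fit_multinomial_elasticnet(inst$X, inst$y, spec)
        mine <- model_objective(fit, inst$X, inst$y, alpha, 0.05, grouped)
        oracle <- oracle_enet_objective(inst$X, inst$y, alpha, 0.05,
                                        grouped, binary = FALSE)
        expect_lte(mine, oracle + 1e-6)
      }
    }
  }
})

test_that("binary solver matches the generic optimizer including pure ridge", {
  inst <- tiny_instances()[[4]]
  for (alpha in c(0, 0.5, 0.93, 1)) {
    spec <- penalty_spec(alpha = alpha, lambda = 0.05, standardize = FALSE,
                         tol = 1e-10, max_iter = 5000)
    fit <- fit_binary_elasticnet(inst$X, inst$y, spec)
    mine <- model_objective(fit, inst$X, inst$y, alpha, 0.05, FALSE)
    oracle <- oracle_enet_objective(inst$X, inst$y, alpha, 0.05, FALSE,
                                    binary = TRUE)
    expect_lte(mine, oracle + 1e-6)
  }
})

test_that("solver agrees with the reference penalized-regression implementation", {
  set.seed(7)
  N <- 60; p <- 10
  X <- matrix(rnorm(N * p), N, p, dimnames = list(NULL, paste0("g", 1:p)))
  y <- factor(sample(letters[1:3], N, TRUE))
  grid <- c(0.1, 0.05, 0.01)
  fits <- fit_enet_grid(X, y, grid, penalty_spec(tol = 1e-9,
                                                 max_iter = 3000),
                        family = "multinomial")
  ref <- glmnet::glmnet(X, y, family = "multinomial", alpha = 0.93,
                        lambda = grid, type.multinomial = "grouped",
                        thresh = 1e-12)
  for (i in seq_along(grid)) {
    co <- glmnet::coef.glmnet(ref, s = grid[i])
    B_ref <- do.call(cbind, lapply(co, function(m) as.numeric(m)[-1]))
    dimnames(B_ref) <- dimnames(fits[[i]]$coefficients)
    expect_equal(fits[[i]]$coefficients, B_ref, tolerance = 1e-4)
    expect_identical(rowSums(fits[[i]]$coefficients != 0) > 0,
                     rowSums(B_ref != 0) > 0)
  }
})

test_that("lambda at or above lambda_max yields the intercept-only model", {
  set.seed(8)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("g", 1:4)))
  y <- factor(sample(c("a", "b", "c"), 50, TRUE, prob = c(0.5, 0.3, 0.2)))
  lmax <- lambda_max(X, y)
  fit <- fit_multinomial_elasticnet(X, y, penalty_spec(lambda = lmax * 1.001,
                                                       tol = 1e-10))
  expect_true(all(fit$coefficients == 0))
  # intercepts reproduce the class frequencies through the softmax
  prior <- exp(fit$intercepts) / sum(exp(fit$intercepts))
  expect_equal(unname(prior), unname(table(y) / 50), tolerance = 1e-4,
               ignore_attr = TRUE)
  # binary: intercept is the log-odds of prevalence
  yb <- factor(rep(c("n", "p"), c(30, 20)))
  fb <- fit_binary_elasticnet(X, yb,
                              penalty_spec(lambda = 10, tol = 1e-12))
  expect_true(all(fb$coefficients == 0))
  expect_equal(unname(fb$intercepts[1]), log(20 / 30), tolerance = 1e-6)
  # just below lambda_max at least one gene activates
  fit2 <- fit_multinomial_elasticnet(X, y,
                                     penalty_spec(lambda = lmax * 0.9))
  expect_gt(length(selected_genes(fit2)), 0)
})

test_that("grouped penalty zeroes whole genes, never single classes", {
  set.seed(9)
  X <- matrix(rnorm(300), 60, 5, dimnames = list(NULL, paste0("g", 1:5)))
  y <- factor(sample(c("a", "b", "c"), 60, TRUE))
  for (lam in c(0.1, 0.05, 0.02)) {
    fit <- fit_multinomial_elasticnet(X, y, penalty_spec(lambda = lam))
    per_class_nz <- rowSums(fit$coefficients != 0)
    expect_true(all(per_class_nz %in% c(0L, ncol(fit$coefficients))))
  }
})

test_that("separable binary toy reaches perfect training accuracy", {
  X <- matrix(c(-2, -1.5, -1, 1, 1.5, 2), 6, 1,
              dimnames = list(NULL, "g"))
  y <- factor(c("n", "n", "n", "p", "p", "p"))
  # separable data: coefficients grow until the iteration cap, with a
  # non-convergence warning by design
  fit <- suppressWarnings(
    fit_binary_elasticnet(X, y, penalty_spec(lambda = 1e-4)))
  expect_identical(predict_class(fit, X), as.character(y))
})

test_that("nonzero-gene count is non-increasing along the default grid", {
  fx <- small_fixture()
  nz <- vapply(fx$trained$evaluations, `[[`, 0L, "n_nonzero_genes")
  lam <- vapply(fx$trained$evaluations, `[[`, 0, "lambda")
  expect_identical(lam, default_lambda_grid())
  expect_true(all(diff(nz) >= 0))  # grid is descending in lambda
})

test_that("sample permutation leaves the fit unchanged; gene permutation permutes it", {
  set.seed(10)
  X <- matrix(rnorm(160), 40, 4, dimnames = list(NULL, paste0("g", 1:4)))
  y <- factor(sample(c("a", "b"), 40, TRUE))
  spec <- penalty_spec(lambda = 0.02, tol = 1e-10, max_iter = 3000)
  base <- fit_multinomial_elasticnet(X, y, spec)
  perm <- sample(40)
  refit <- fit_multinomial_elasticnet(X[perm, ], y[perm], spec)
  expect_equal(refit$coefficients, base$coefficients, tolerance = 1e-6)
  gperm <- c(3, 1, 4, 2)
  gfit <- fit_multinomial_elasticnet(X[, gperm], y, spec)
  expect_equal(gfit$coefficients, base$coefficients[gperm, ],
               tolerance = 1e-6)
})

test_that("objective never exceeds the optimal intercept-only model", {
  for (inst in tiny_instances()[1:3]) {
    spec <- penalty_spec(lambda = 0.05, standardize = FALSE, tol = 1e-10)
    fit <- suppressWarnings(fit_multinomial_elasticnet(inst$X, inst$y, spec))
    mine <- model_objective(fit, inst$X, inst$y, 0.93, 0.05, TRUE)
    yf <- factor(inst$y)
    prior <- as.numeric(table(yf)) / length(inst$y)
    null_obj <- -sum(prior * log(prior))  # best intercept-only deviance
    expect_lte(mine, null_obj + 1e-9)
  }
})

test_that("predicted probabilities are normalized, prior-consistent, shift-invariant", {
  set.seed(12)
  X <- matrix(rnorm(120), 30, 4, dimnames = list(NULL, paste0("g", 1:4)))
  y <- factor(sample(c("a", "b", "c"), 30, TRUE))
  fit <- fit_multinomial_elasticnet(X, y, penalty_spec(lambda = 0.02))
  p <- predict_proba(fit, X)
  expect_equal(unname(rowSums(p)), rep(1, 30), tolerance = 1e-12)
  null_fit <- fit_multinomial_elasticnet(X, y, penalty_spec(lambda = 100))
  p0 <- predict_proba(null_fit, X)
  expect_equal(max(apply(p0, 2, function(c) diff(range(c)))), 0)
  shifted <- fit
  shifted$intercepts <- fit$intercepts + 5
  expect_equal(predict_proba(shifted, X), p, tolerance = 1e-9)
})

test_that("probability prediction enforces the gene-fill policy", {
  fx <- small_fixture()
  model <- fx$trained$model
  X <- encode_missing(fx$test)
  half <- X[, seq_len(ncol(X) %/% 2)]
  expect_error(predict_proba(model, half), "fill_missing")
  p <- predict_proba(model, half, fill_missing = TRUE)
  expect_equal(unname(rowSums(p)), rep(1, nrow(half)), tolerance = 1e-12)
})

test_that("cross-validation is seed-deterministic and ranks the null model worst", {
  set.seed(13)
  X <- matrix(rnorm(400), 80, 5, dimnames = list(NULL, paste0("g", 1:5)))
  X[1:40, 1] <- X[1:40, 1] + 2
  y <- factor(rep(c("a", "b"), each = 40))
  grid <- c(1, 0.1, 0.01)
  cv1 <- cross_validate(X, y, grid, nfolds = 5, seed = 99)
  cv2 <- cross_validate(X, y, grid, nfolds = 5, seed = 99)
  expect_identical(cv1, cv2)
  expect_gte(cv1$cv_deviance[1], min(cv1$cv_deviance))
  expect_gt(cv1$cv_deviance[1], cv1$cv_deviance[3])
  expect_warning(cross_validate(X, y, grid, nfolds = 50, seed = 1),
                 "fewer members")
  expect_error(cross_validate(X, y, numeric(0)), "empty")
})
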