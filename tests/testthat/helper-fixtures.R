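# Shared fixtures, built in code and cached for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

# tiny hand-built dataset for IO/type tests
tiny_dataset <- function() {
  v <- matrix(c(5, 2, 7, 0, 4, 1), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
  ExpressionDataset(v)
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# small end-to-end fixture: 4 types x 12 samples, 400 genes
small_fixture <- function() {
  if (!is.null(.fixture_cache$small)) return(.fixture_cache$small)
  cfg <- simulation_config(n_cell_types = 4L, samples_per_type = 12L,
                           n_genes = 400L, markers_per_type = 8L,
                           absent_per_type = 3L, seed = 42L)
  bulk <- simulate_bulk(cfg)
  split <- split_dataset(bulk$dataset, 0.6, seed = 5L)
  tr0 <- preprocess_pipeline(
    subset_dataset(bulk$dataset, samples = split$train_sample_ids),
    bulk$annotation)$dataset
  te0 <- preprocess_pipeline(
    subset_dataset(bulk$dataset, samples = split$test_sample_ids),
    bulk$annotation)$dataset
  common <- intersect(gene_ids(tr0), gene_ids(te0))
  fx <- list(config = cfg, bulk = bulk, split = split,
             train = subset_dataset(tr0, genes = common),
             test = subset_dataset(te0, genes = common))
  fx$trained <- suppressWarnings(train_celltype_classifier(
    fx$train, fx$test, params = augment_params(duplication_factor = 20L,
                                               seed = 3L),
    nfolds = 0L, seed = 11L))
  .fixture_cache$small <- fx
  fx
}

# the study-condition fixture: 5 types x 40 samples, 2000 genes,
# 20 markers/type, fold change 8, default augmentation (100x, 10% dropout)
full_fixture <- function() {
  if (!is.null(.fixture_cache$full)) return(.fixture_cache$full)
  cfg <- simulation_config(seed = 101L)
  bulk <- simulate_bulk(cfg)
  split <- split_dataset(bulk$dataset, 0.6, seed = 5L)
  tr0 <- preprocess_pipeline(
    subset_dataset(bulk$dataset, samples = split$train_sample_ids),
    bulk$annotation)$dataset
  te0 <- preprocess_pipeline(
    subset_dataset(bulk$dataset, samples = split$test_sample_ids),
    bulk$annotation)$dataset
  common <- intersect(gene_ids(tr0), gene_ids(te0))
  fx <- list(config = cfg, bulk = bulk,
             train = subset_dataset(tr0, genes = common),
             test = subset_dataset(te0, genes = common))
  fx$trained <- suppressWarnings(train_celltype_classifier(
    fx$train, fx$test, params = augment_params(seed = 3L), nfolds = 0L,
    seed = 11L))
  .fixture_cache$full <- fx
  fx
}

# fixed tiny problems: <= 8 samples, <= 4 genes, 2-3 classes
tiny_instances <- function() {
  list(
    list(X = matrix(c(0.5, -1.2, 0.3, 2.0, -0.7, 1.1,
                      1.0, 0.2, -0.5, -1.5, 0.8, 0.4), 6, 2,
                    dimnames = list(NULL, c("gA", "gB"))),
         y = c("a", "b", "a", "b", "a", "b")),
    list(X = matrix(c(1.2, -0.3, 0.7, -1.1, 0.2, 1.9, -0.8, 0.5,
                      0.1, 1.4, -0.6, 0.9, -1.3, 0.3, 1.0, -0.2,
                      2.1, -1.7, 0.4, 0.6, -0.9, 1.2, 0.8, -0.4), 8, 3,
                    dimnames = list(NULL, c("g1", "g2", "g3"))),
         y = c("a", "b", "c", "a", "b", "c", "a", "b")),
    list(X = matrix(c(0.0, 1.0, 2.0, 3.0, 4.0, 5.0,
                      1.5, -0.5, 0.8, -1.2, 0.3, 0.9,
                      -2.0, 0.4, 1.1, 0.2, -0.6, 1.8,
                      0.7, 0.7, -0.7, -0.7, 1.4, -1.4), 6, 4,
                    dimnames = list(NULL, paste0("x", 1:4))),
         y = c("a", "a", "b", "b", "c", "c")),
    list(X = matrix(c(3, 1, 4, 1, 5, 9, 2, 6,
                      2.6, 5.3, 5.8, 9.7, 9.3, 2.3, 8.4, 6.2), 8, 2,
                    dimnames = list(NULL, c("p", "q"))),
         y = c("a", "a", "a", "a", "b", "b", "b", "b")),
    list(X = matrix(c(-1, 1, -1, 1, -1, 1,
                      0.2, 0.1, -0.3, 0.4, -0.1, 0.0,
                      1.0, 2.0, 3.0, 1.5, 2.5, 0.5), 6, 3,
                    dimnames = list(NULL, c("u", "v", "w"))),
         y = c("a", "b", "a", "b", "a", "b")))
}

# independent generic optimizer for the penalized objective (Nelder-Mead
# with restarts; handles the nonsmooth l1/group terms acceptably at tiny
# dimension). Parameterization matches the solver: intercepts + flat beta.
oracle_enet_objective <- function(X, y, alpha, lambda, grouped, binary) {
  yf <- factor(y)
  K <- if (binary) 1L else nlevels(yf)
  N <- nrow(X); p <- ncol(X)
  Y <- if (binary) matrix(as.numeric(yf == levels(yf)[2]), ncol = 1) else {
    Z <- matrix(0, N, nlevels(yf))
    Z[cbind(seq_len(N), as.integer(yf))] <- 1
    Z
  }
  obj <- function(par) {
    b0 <- par[seq_len(ncol(Y))]
    B <- matrix(par[-seq_len(ncol(Y))], p, ncol(Y))
    eta <- sweep(X %*% B, 2, b0, "+")
    nll <- if (binary) {
      lse <- pmax(eta, 0) + log1p(exp(-abs(eta)))
      -mean(Y * eta - lse)
    } else {
      m <- apply(eta, 1, max)
      -(sum(Y * eta) - sum(m + log(rowSums(exp(eta - m))))) / N
    }
    l2sq <- rowSums(B^2)
    reg <- if (grouped && ncol(Y) > 1) sqrt(l2sq) else rowSums(abs(B))
    nll + lambda * sum((1 - alpha) / 2 * l2sq + alpha * reg)
  }
  npar <- ncol(Y) * (p + 1)
  best <- Inf
  for (start in seq_len(6)) {
    par0 <- if (start == 1) rep(0, npar) else
      with_seed_local(start, stats::rnorm(npar, sd = 0.5))
    for (rep in 1:4) {
      fit <- stats::optim(par0, obj, method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-12))
      par0 <- fit$par
    }
    if (fit$value < best) best <- fit$value
  }
  best
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# evaluate the package's objective for a fitted model on the raw scale
model_objective <- function(model, X, y, alpha, lambda, grouped) {
  binary <- model$family == "binomial"
  yf <- factor(y)
  B <- model$coefficients
  b0 <- model$intercepts
  eta <- sweep(X %*% B, 2, b0, "+")
  N <- nrow(X)
  nll <- if (binary) {
    yb <- as.numeric(yf == levels(yf)[2])
    lse <- pmax(eta[, 1], 0) + log1p(exp(-abs(eta[, 1])))
    -mean(yb * eta[, 1] - lse)
  } else {
    Y <- matrix(0, N, nlevels(yf))
    Y[cbind(seq_len(N), as.integer(yf))] <- 1
    m <- apply(eta, 1, max)
    -(sum(Y * eta) - sum(m + log(rowSums(exp(eta - m))))) / N
  }
  l2sq <- rowSums(B^2)
  reg <- if (grouped && ncol(B) > 1) sqrt(l2sq) else rowSums(abs(B))
  nll + lambda * sum((1 - alpha) / 2 * l2sq + alpha * reg)
}
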