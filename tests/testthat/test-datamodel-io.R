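test_that("read_counts parses counts, NA tokens set the missing mask", {
  path <- write_tsv_lines(c("gene\ts1\ts2", "g1\t5\t0", "g2\t2\tNA",
                            "g3\t7\t1"))
  ds <- read_counts(path)
  expect_s3_class(ds, "ExpressionDataset")
  expect_identical(gene_ids(ds), c("g1", "g2", "g3"))
  expect_identical(sample_ids(ds), c("s1", "s2"))
  expect_equal(unname(ds$values["g1", ]), c(5, 0))
  expect_true(ds$missing_mask["g2", "s2"])
  expect_identical(sum(ds$missing_mask), 1L)
  expect_equal(ds$values["g2", "s2"], 0)  # stored 0, masked
  expect_identical(ds$value_scale, "raw_counts")
})

test_that("read_counts accepts all missing tokens and both orientations", {
  path <- write_tsv_lines(c("id\tg1\tg2\tg3", "s1\t1\tNaN\t3", "s2\t\t5\t6"))
  ds <- read_counts(path, orientation = "samples_in_rows")
  expect_identical(gene_ids(ds), c("g1", "g2", "g3"))
  expect_true(ds$missing_mask["g2", "s1"])
  expect_true(ds$missing_mask["g1", "s2"])
  csv <- tempfile(fileext = ".csv")
  writeLines(c("gene,s1,s2", "g1,1,2"), csv)
  expect_equal(unname(read_counts(csv)$values[1, ]), c(1, 2))
})

test_that("read_counts rejects malformed input with informative errors", {
  expect_error(read_counts(write_tsv_lines(character(0))), "empty file")
  expect_error(
    read_counts(write_tsv_lines(c("gene\ts1", "g1\t1", "g1\t2"))),
    "duplicate gene id.*g1")
  expect_error(
    read_counts(write_tsv_lines(c("gene\ts1\ts2", "g1\t1\t2\t3"))),
    "ragged row.*line 2")
  expect_error(
    read_counts(write_tsv_lines(c("gene\ts1", "g1\t-3"))),
    "negative count.*g1.*s1")
  expect_error(
    read_counts(write_tsv_lines(c("gene\ts1", "g1\tabc"))),
    "non-numeric")
})

test_that("counts round-trip through write_counts with canonical NA", {
  fx <- tiny_dataset()
  fx$missing_mask[2, 2] <- TRUE
  path <- tempfile(fileext = ".tsv")
  write_counts(fx, path)
  expect_true(any(grepl("\tNA", readLines(path))))
  back <- read_counts(path)
  expect_equal(back$values, fx$values * !fx$missing_mask)
  expect_identical(back$missing_mask, fx$missing_mask)
})

test_that("gene annotation reader validates GC and length", {
  ok <- write_tsv_lines(c("gene_id\tgc_fraction\tlength_bp",
                          "GENE1\t0.41\t2100"))
  ann <- read_gene_annotation(ok)
  expect_equal(ann$gc_fraction, 0.41)
  bad_gc <- write_tsv_lines(c("gene_id\tgc_fraction\tlength_bp",
                              "GENE2\t1.2\t500"))
  expect_error(read_gene_annotation(bad_gc), "gc_fraction.*GENE2")
  bad_len <- write_tsv_lines(c("gene_id\tgc_fraction\tlength_bp",
                               "GENE3\t0.5\t0"))
  expect_error(read_gene_annotation(bad_len), "length_bp.*GENE3")
})

test_that("annotation missing a dataset gene defers the error to GC normalization", {
  ds <- tiny_dataset()
  ann <- data.frame(gene_id = c("g1", "g2"), gc_fraction = c(0.4, 0.5),
                    length_bp = c(1000L, 1500L))
  # reading/holding the partial annotation succeeds ...
  expect_silent(validate_expression_dataset(
    ExpressionDataset(ds$values, gene_annotation = ann)))
  # ... but the GC stage refuses, naming the uncovered gene
  expect_error(within_lane_gc_normalize(ds, ann), "g3")
})

test_that("sparse MTX reader densifies, keeps zeros unmasked, sums duplicates", {
  mtx <- write_tsv_lines(c("%%MatrixMarket matrix coordinate integer general",
                           "2 2 1", "1 1 4"))
  genes <- write_tsv_lines(c("gA", "gB"))
  cells <- write_tsv_lines(c("c1", "c2"))
  ds <- read_sparse_matrix(mtx, genes, cells)
  expect_equal(unname(ds$values),
               matrix(c(4, 0, 0, 0), 2, 2))
  expect_false(any(ds$missing_mask))  # sparse zero is a zero, not missing
  dup <- write_tsv_lines(c("%%MatrixMarket matrix coordinate integer general",
                           "2 2 2", "1 1 2", "1 1 3"))
  expect_equal(read_sparse_matrix(dup, genes, cells)$values["gA", "c1"], 5)
  oob <- write_tsv_lines(c("%%MatrixMarket matrix coordinate integer general",
                           "3 2 1", "4 1 1"))
  genes3 <- write_tsv_lines(c("gA", "gB", "gC"))
  expect_error(read_sparse_matrix(oob, genes3, cells))
})

test_that("classifier models round-trip through JSON", {
  fx <- small_fixture()
  model <- fx$trained$model
  path <- tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_identical(back$class_labels, model$class_labels)
  expect_identical(back$gene_ids, model$gene_ids)
  expect_equal(back$coefficients, model$coefficients, tolerance = 1e-12)
  expect_equal(unname(back$intercepts), unname(model$intercepts),
               tolerance = 1e-12)
  expect_equal(back$penalty$alpha, model$penalty$alpha)
})

test_that("model reader flags unknown schema versions and handles empty models", {
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(schema_version = "99.0"), path,
                       auto_unbox = TRUE)
  expect_error(read_model(path), "schema version")
  # zero-selected-gene model is degenerate but legal
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c("u", "v"), 10)
  m0 <- fit_multinomial_elasticnet(X, y, penalty_spec(lambda = 10))
  expect_length(selected_genes(m0), 0)
  p0 <- tempfile(fileext = ".json")
  write_model(m0, p0)
  expect_equal(read_model(p0)$coefficients, m0$coefficients,
               tolerance = 1e-12)
})

test_that("gene-set readers handle GMT and two-column TSV", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), gmt)
  gs <- read_gene_sets(gmt)
  expect_named(gs, c("setA", "setB"))
  expect_setequal(gs$setA, c("g1", "g2", "g3"))
  tsv <- write_tsv_lines(c("set_name\tgene", "sA\tg1", "sA\tg2", "sB\tg9"))
  gs2 <- read_gene_sets(tsv)
  expect_setequal(gs2$sA, c("g1", "g2"))
  expect_error(read_gene_sets(write_tsv_lines(character(0))), "empty")
})

test_that("split specifications enforce disjointness and label coverage", {
  fx <- small_fixture()
  ds <- fx$bulk$dataset
  ids <- sample_ids(ds)
  expect_error(SplitSpec(ds, ids[1:10], ids[10:20]), "overlap")
  expect_error(SplitSpec(ds, ids[1:3], ids[40:48]), "absent from the training")
  sp <- split_dataset(ds, 0.6, seed = 1)
  expect_length(intersect(sp$train_sample_ids, sp$test_sample_ids), 0)
  ct <- cell_types(ds)
  expect_setequal(unique(ct[match(sp$train_sample_ids, ids)]), unique(ct))
})

test_that("dataset invariants reject duplicates and stray negatives", {
  v <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g1"), c("s1", "s2")))
  expect_error(ExpressionDataset(v), "duplicate gene")
  v2 <- matrix(c(1, -2, 3, 4), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(ExpressionDataset(v2), "negative")
})
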