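#' Run the full workflow from a configuration
#'
#' Executes the requested stages in order, each reading its inputs from and
#' writing its outputs (plus a provenance stanza: parameters, derived seed,
#' input file hashes) into `outdir`. Every stochastic stage receives a seed
#' derived deterministically from the global seed and the stage name, so
#' re-running an identical configuration reproduces the outputs bitwise.
#' No stage mutates its inputs on disk.
#'
#' Recognized top-level keys: `outdir`, `seed`, `stages`, and one optional
#' parameter block per stage (`simulate`, `preprocess`, `train_classifier`,
#' `build_signatures`, `annotate`, `compose`, `pca_control`, `cluster`,
#' `benchmark`). Unknown keys are an error, not silently ignored.
#'
#' @param config a YAML file path or an equivalent named list.
#' @return the artifact directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("outdir", "seed", "stages", PIPELINE_STAGES)
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stopf("unknown configuration key(s): %s (known: %s)",
          paste(unknown, collapse = ", "), paste(known, collapse = ", "))
  outdir <- config$outdir %||% stop("config needs an `outdir`")
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% PIPELINE_STAGES
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad))
    stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (stage in stages) {
    fn <- get(paste0("stage_", stage), mode = "function")
    fn(outdir, config[[stage]] %||% list(), derive_seed(seed, stage))
  }
  invisible(outdir)
}

PIPELINE_STAGES <- c("simulate", "preprocess", "train_classifier",
                     "build_signatures", "annotate", "compose",
                     "pca_control", "cluster", "benchmark")

write_provenance <- function(outdir, stage, params, seed, inputs) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(
    list(stage = stage, parameters = params, seed = seed,
         input_md5 = hashes),
    file.path(outdir, paste0("provenance_", stage, ".json")),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

need_artifact <- function(outdir, file, producer) {
  path <- file.path(outdir, file)
  if (!file.exists(path))
    stopf("missing artifact '%s'; run the '%s' stage first", file, producer)
  path
}

stage_simulate <- function(outdir, params, seed) {
  cfg <- do.call(simulation_config,
                 modifyList(list(seed = seed),
                            params[setdiff(names(params),
                                           c("cells_per_specimen",
                                             "n_specimens"))]))
  bulk <- simulate_bulk(cfg)
  write_counts(bulk$dataset, file.path(outdir, "counts.tsv"))
  write.table(bulk$annotation, file.path(outdir, "annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bulk$dataset$sample_meta, file.path(outdir, "labels.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bulk$truth[c("markers", "absent")],
                       file.path(outdir, "truth.json"), auto_unbox = FALSE,
                       pretty = TRUE)
  sc <- simulate_single_cells(
    cfg, cells_per_specimen = params$cells_per_specimen %||% 200L,
    n_specimens = params$n_specimens %||% 4L)
  write_counts(sc$dataset, file.path(outdir, "sc_counts.tsv"))
  write.table(sc$specimen_map, file.path(outdir, "sc_specimens.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(cell_id = names(sc$labels),
                         true_type = unname(sc$labels)),
              file.path(outdir, "sc_true_labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_provenance(outdir, "simulate", unclass(cfg), seed, character(0))
}

stage_preprocess <- function(outdir, params, seed) {
  counts_path <- params$counts %||% need_artifact(outdir, "counts.tsv",
                                                  "simulate")
  labels_path <- params$labels %||% need_artifact(outdir, "labels.tsv",
                                                  "simulate")
  ann_path <- params$annotation %||% need_artifact(outdir, "annotation.tsv",
                                                   "simulate")
  ds <- read_counts(counts_path)
  ds$sample_meta <- read_sample_labels(labels_path)
  ann <- read_gene_annotation(ann_path)
  split <- split_dataset(ds, train_fraction = params$train_fraction %||% 0.6,
                         seed = seed)
  for (grp in c("train", "test")) {
    ids <- if (grp == "train") split$train_sample_ids else
      split$test_sample_ids
    pp <- preprocess_pipeline(subset_dataset(ds, samples = ids),
                              annotation = ann,
                              min_count = params$min_count %||% 5,
                              min_samples = params$min_samples %||% 5L,
                              span = params$gc_span %||% 0.3,
                              skip_gc = isTRUE(params$skip_gc))
    write_counts(pp$dataset, file.path(outdir, paste0(grp, "_log2.tsv")))
    jsonlite::write_json(
      list(stages = pp$report$stage_order,
           genes = as.list(pp$report$genes), params = pp$report$params),
      file.path(outdir, paste0("normalization_report_", grp, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  write_provenance(outdir, "preprocess", params, seed,
                   c(counts_path, labels_path, ann_path))
}

read_split <- function(outdir, labels_path = NULL) {
  tr_p <- need_artifact(outdir, "train_log2.tsv", "preprocess")
  te_p <- need_artifact(outdir, "test_log2.tsv", "preprocess")
  lb_p <- labels_path %||% need_artifact(outdir, "labels.tsv", "simulate")
  labels <- read_sample_labels(lb_p)
  tr <- read_counts(tr_p, value_scale = "log2")
  te <- read_counts(te_p, value_scale = "log2")
  # restrict both splits to the genes surviving preprocessing in both
  common <- intersect(gene_ids(tr), gene_ids(te))
  tr <- subset_dataset(tr, genes = common)
  te <- subset_dataset(te, genes = common)
  tr$sample_meta <- labels[labels$sample_id %in% sample_ids(tr), ]
  te$sample_meta <- labels[labels$sample_id %in% sample_ids(te), ]
  list(train = tr, test = te, inputs = c(tr_p, te_p, lb_p))
}

stage_train_classifier <- function(outdir, params, seed) {
  sp <- read_split(outdir, params$labels)
  spec <- penalty_spec(alpha = params$alpha %||% 0.93,
                       max_iter = params$max_iter %||% 500L)
  aug <- augment_params(
    duplication_factor = params$dup_factor %||% 100L,
    dropout_fraction = params$dropout %||% 0.10,
    seed = derive_seed(seed, "augment"))
  grid <- params$lambda_grid %||% default_lambda_grid()
  res <- train_celltype_classifier(
    sp$train, sp$test, lambda_grid = grid, spec = spec, params = aug,
    rule = params$rule %||% "max_auc_smallest_lambda",
    nfolds = params$nfolds %||% 0L, seed = seed)
  write_model(res$model, file.path(outdir, "model.json"))
  write.table(as.data.frame(res$evaluations),
              file.path(outdir, "lambda_evaluations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  roc_tab <- do.call(rbind, lapply(res$evaluations, function(e)
    cbind(lambda = e$lambda, e$roc)))
  write.table(roc_tab, file.path(outdir, "roc_points.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(res$cv))
    write.table(res$cv, file.path(outdir, "cv_deviance.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  write_provenance(outdir, "train_classifier", params, seed, sp$inputs)
}

stage_build_signatures <- function(outdir, params, seed) {
  sp <- read_split(outdir, params$labels)
  model <- read_model(need_artifact(outdir, "model.json",
                                    "train_classifier"))
  spec <- penalty_spec(alpha = params$alpha %||% 0.93,
                       max_iter = params$max_iter %||% 500L)
  aug <- augment_params(
    duplication_factor = params$dup_factor %||% 100L,
    dropout_fraction = params$dropout %||% 0.10,
    seed = derive_seed(seed, "augment"))
  sigs <- build_all_signatures(
    sp$train, sp$test, model,
    lambda_grid = params$lambda_grid %||% default_lambda_grid(),
    spec = spec, params = aug,
    rule = params$rule %||% "max_auc_smallest_lambda", seed = seed)
  export_signatures(sigs, file.path(outdir, "signatures.tsv"))
  write.table(signature_summary(sigs),
              file.path(outdir, "signature_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_provenance(outdir, "build_signatures", params, seed,
                   c(sp$inputs, file.path(outdir, "model.json")))
}

stage_annotate <- function(outdir, params, seed) {
  model <- read_model(need_artifact(outdir, "model.json",
                                    "train_classifier"))
  sc_path <- params$sc_counts %||% need_artifact(outdir, "sc_counts.tsv",
                                                 "simulate")
  sc <- read_counts(sc_path)
  ann <- annotate_cells(model, sc,
                        preprocess_like_training =
                          isTRUE(params$preprocess_like_training),
                        min_overlap = params$min_overlap %||% 0.5,
                        min_confidence = params$min_confidence %||% 0)
  write.table(ann, file.path(outdir, "annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_provenance(outdir, "annotate", params, seed,
                   c(sc_path, file.path(outdir, "model.json")))
}

stage_compose <- function(outdir, params, seed) {
  ann_path <- need_artifact(outdir, "annotations.tsv", "annotate")
  map_path <- params$specimens %||% need_artifact(outdir,
                                                  "sc_specimens.tsv",
                                                  "simulate")
  ann <- read.delim(ann_path, stringsAsFactors = FALSE)
  comp <- compose_by_specimen(ann, read.delim(map_path,
                                              stringsAsFactors = FALSE))
  write.table(data.frame(specimen_id = rownames(comp),
                         unclass(comp), check.names = FALSE),
              file.path(outdir, "composition.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_provenance(outdir, "compose", params, seed, c(ann_path, map_path))
}

read_composition <- function(outdir) {
  path <- need_artifact(outdir, "composition.tsv", "compose")
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  list(m = m, path = path)
}

stage_pca_control <- function(outdir, params, seed) {
  comp <- read_composition(outdir)
  res <- pca_with_scrambled_control(comp$m,
                                    n_scrambles = params$n_scrambles %||%
                                      50L, seed = seed)
  jsonlite::write_json(
    list(n_retained = res$n_retained, threshold = res$threshold,
         explained_variance = res$explained_variance),
    file.path(outdir, "pca_control.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write_provenance(outdir, "pca_control", params, seed, comp$path)
}

stage_cluster <- function(outdir, params, seed) {
  comp <- read_composition(outdir)
  cl <- cluster_specimens(comp$m, k = params$k %||% 2L,
                          linkage = params$linkage %||% "complete")
  write.table(data.frame(specimen_id = names(cl), cluster = unname(cl)),
              file.path(outdir, "clusters.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_provenance(outdir, "cluster", params, seed, comp$path)
}

stage_benchmark <- function(outdir, params, seed) {
  tr_p <- need_artifact(outdir, "train_log2.tsv", "preprocess")
  ds <- read_counts(tr_p, value_scale = "log2")
  gene_sets <- if (!is.null(params$gene_sets)) {
    read_gene_sets(params$gene_sets)
  } else {
    sig_p <- need_artifact(outdir, "signatures.tsv", "build_signatures")
    sigs <- read_signatures(sig_p)
    lapply(sigs, function(s) s$entries$gene_id)
  }
  cfg <- benchmark_config(
    binarize_threshold = params$binarize_threshold %||% 2.48,
    n_boot = params$n_boot %||% 1000L,
    ci_level = params$ci_level %||% 0.95, seed = seed)
  res <- suppressWarnings(benchmark_gene_sets(ds, gene_sets, cfg))
  summ <- data.frame(
    gene_set = vapply(res, `[[`, "", "name"),
    n_genes_used = vapply(res, `[[`, 0L, "n_genes_used"),
    mean_auc = vapply(res, `[[`, 0, "mean_auc"),
    auc_lo = vapply(res, function(r) r$auc_ci[1], 0),
    auc_hi = vapply(res, function(r) r$auc_ci[2], 0),
    flagged = vapply(res, `[[`, TRUE, "flagged"))
  write.table(summ, file.path(outdir, "benchmark_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  curves <- do.call(rbind, lapply(res, function(r)
    data.frame(gene_set = r$name, fpr = r$fpr_grid, mean_tpr = r$mean_tpr,
               lower = r$lower, upper = r$upper)))
  write.table(curves, file.path(outdir, "benchmark_curves.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_provenance(outdir, "benchmark", params, seed, tr_p)
}
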