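#' Simulation configuration for synthetic multi-study count data
#'
#' The generator emulates the structure the workflow assumes: several cell
#' types profiled across heterogeneous studies, negative-binomial counts,
#' planted cell-type marker genes of two styles (over-expressed in their
#' type; suppressed to near zero in one type, which should attract negative
#' coefficients), per-study GC-content bias, and missing values at random.
#'
#' @param n_cell_types number of cell types (default 5).
#' @param samples_per_type samples per type (default 40).
#' @param n_genes total genes (default 2000).
#' @param markers_per_type over-expressed markers planted per type
#'   (default 20).
#' @param absent_per_type genes suppressed to near zero in exactly one
#'   type (default 5).
#' @param marker_fold_change multiplicative marker effect, > 1 (default 8).
#' @param nb_dispersion negative-binomial size parameter (default 2;
#'   smaller = more overdispersed).
#' @param baseline_mean_log_range range of log-uniform baseline means
#'   (default `c(log(2), log(500))`, spanning background-level to highly
#'   expressed genes so that expression binarization has both classes).
#' @param marker_baseline_log_range range of log-uniform baseline means
#'   for the planted markers (default `c(log(2), log(6))`): markers sit
#'   near the background level outside their own type, so the fold-change
#'   in their type switches them from "background" to "expressed".
#' @param n_studies simulated studies (default 3).
#' @param gc_bias_strength per-study GC bias slopes (recycled/generated to
#'   `n_studies`; default evenly spaced in \[-1, 1\]).
#' @param missing_rate MCAR missing fraction in \[0,1) (default 0.05).
#' @param single_cell_dropout_rate extra dropout applied by
#'   [simulate_single_cells()] (default 0.3).
#' @param seed integer seed.
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(n_cell_types = 5L, samples_per_type = 40L,
                              n_genes = 2000L, markers_per_type = 20L,
                              absent_per_type = 5L, marker_fold_change = 8,
                              nb_dispersion = 2,
                              baseline_mean_log_range = c(log(2), log(500)),
                              marker_baseline_log_range = c(log(2), log(6)),
                              n_studies = 3L, gc_bias_strength = NULL,
                              missing_rate = 0.05,
                              single_cell_dropout_rate = 0.3, seed = 1L) {
  if (marker_fold_change < 1)
    stop("marker_fold_change must be >= 1", call. = FALSE)
  if ((markers_per_type + absent_per_type) * n_cell_types > n_genes)
    stop("more planted genes than n_genes", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  if (single_cell_dropout_rate < 0 || single_cell_dropout_rate >= 1)
    stop("single_cell_dropout_rate must be in [0, 1)", call. = FALSE)
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive",
                               call. = FALSE)
  gc_bias_strength <- gc_bias_strength %||%
    seq(-1, 1, length.out = n_studies)
  structure(list(n_cell_types = as.integer(n_cell_types),
                 samples_per_type = as.integer(samples_per_type),
                 n_genes = as.integer(n_genes),
                 markers_per_type = as.integer(markers_per_type),
                 absent_per_type = as.integer(absent_per_type),
                 marker_fold_change = marker_fold_change,
                 nb_dispersion = nb_dispersion,
                 baseline_mean_log_range = baseline_mean_log_range,
                 marker_baseline_log_range = marker_baseline_log_range,
                 n_studies = as.integer(n_studies),
                 gc_bias_strength = rep_len(gc_bias_strength, n_studies),
                 missing_rate = missing_rate,
                 single_cell_dropout_rate = single_cell_dropout_rate,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

# gene-by-sample matrix of expected counts before noise/bias
sim_mean_matrix <- function(config, types_of_samples, base_mean, truth) {
  mu <- matrix(base_mean, config$n_genes, length(types_of_samples))
  for (t in seq_len(config$n_cell_types)) {
    cols <- types_of_samples == t
    mu[truth$marker_gene_idx[[t]], cols] <-
      mu[truth$marker_gene_idx[[t]], cols] * config$marker_fold_change
    mu[truth$absent_gene_idx[[t]], cols] <-
      mu[truth$absent_gene_idx[[t]], cols] * 0.01
  }
  mu
}

#' Simulate labeled multi-study bulk count data with planted markers
#'
#' Baseline per-gene means are log-uniform over
#' `baseline_mean_log_range`. Each cell type receives `markers_per_type`
#' over-expressed markers (multiplied by `marker_fold_change` in their
#' type) and `absent_per_type` "absent-in-type" genes (suppressed to 1% of
#' baseline in that type only). Counts are negative binomial with size
#' `nb_dispersion`; a per-study multiplicative GC bias
#' `exp(b_s * (gc - 0.5))` is applied; entries go missing completely at
#' random at `missing_rate`. Gene annotations (GC fraction, length) and
#' per-sample metadata (cell type, study) are emitted.
#'
#' @param config a [simulation_config()].
#' @return list with `dataset` (an [ExpressionDataset] of raw counts),
#'   `truth` (per-type marker and absent-gene ids), `annotation`.
#' @export
simulate_bulk <- function(config = simulation_config()) {
  with_seed(config$seed, {
    n_g <- config$n_genes
    n_type <- config$n_cell_types
    n_s <- n_type * config$samples_per_type
    gene_ids <- sprintf("GENE%04d", seq_len(n_g))
    planted <- sample.int(n_g, (config$markers_per_type +
                                  config$absent_per_type) * n_type)
    mk <- config$markers_per_type; ab <- config$absent_per_type
    truth <- list(
      marker_gene_idx = lapply(seq_len(n_type), function(t)
        if (mk == 0) integer(0)
        else planted[((t - 1) * mk + 1):(t * mk)]),
      absent_gene_idx = lapply(seq_len(n_type), function(t) {
        off <- n_type * mk
        if (ab == 0) integer(0)
        else planted[(off + (t - 1) * ab + 1):(off + t * ab)]
      }))
    base_mean <- exp(runif(n_g, config$baseline_mean_log_range[1],
                           config$baseline_mean_log_range[2]))
    all_markers <- unlist(truth$marker_gene_idx)
    base_mean[all_markers] <- exp(runif(length(all_markers),
                                        config$marker_baseline_log_range[1],
                                        config$marker_baseline_log_range[2]))
    types_of_samples <- rep(seq_len(n_type), each = config$samples_per_type)
    studies <- sample(rep_len(seq_len(config$n_studies), n_s))
    gc <- pmin(pmax(rnorm(n_g, 0.45, 0.1), 0.2), 0.8)
    len <- pmax(200L, as.integer(round(exp(rnorm(n_g, 7.5, 0.6)))))
    mu <- sim_mean_matrix(config, types_of_samples, base_mean, truth)
    bias <- exp(outer(gc - 0.5, config$gc_bias_strength[studies]))
    counts <- matrix(rnbinom(n_g * n_s, size = config$nb_dispersion,
                             mu = as.vector(mu * bias)), n_g, n_s)
    miss <- matrix(runif(n_g * n_s) < config$missing_rate, n_g, n_s)
    counts[miss] <- 0
    sample_ids <- sprintf("S%03d_type%d", seq_len(n_s), types_of_samples)
    dimnames(counts) <- list(gene_ids, sample_ids)
    dimnames(miss) <- dimnames(counts)
    annotation <- data.frame(gene_id = gene_ids, gc_fraction = gc,
                             length_bp = len)
    meta <- data.frame(sample_id = sample_ids,
                       cell_type = paste0("type", types_of_samples),
                       study_id = paste0("study", studies))
    truth_named <- list(
      markers = setNames(lapply(truth$marker_gene_idx,
                                function(i) gene_ids[i]),
                         paste0("type", seq_len(n_type))),
      absent = setNames(lapply(truth$absent_gene_idx,
                               function(i) gene_ids[i]),
                        paste0("type", seq_len(n_type))),
      base_mean = setNames(base_mean, gene_ids))
    list(dataset = ExpressionDataset(counts, miss,
                                     gene_annotation = annotation,
                                     sample_meta = meta,
                                     value_scale = "raw_counts"),
         truth = truth_named, annotation = annotation)
  })
}

#' Simulate single cells from the bulk generative model
#'
#' Cells are drawn per specimen according to the requested composition,
#' from the same negative-binomial model (no study GC bias: one platform),
#' with extra dropout: each entry is zeroed with probability
#' `single_cell_dropout_rate`, emulating scRNA-seq technical zeros.
#'
#' @param config a [simulation_config()] (types, markers, dispersion are
#'   shared with the bulk model).
#' @param cells_per_specimen cells per specimen (default 200).
#' @param n_specimens specimens (default 4).
#' @param composition per-specimen type proportions: either one numeric
#'   vector of length `n_cell_types` reused for all specimens, or a
#'   `n_specimens` x `n_cell_types` matrix; rows need not be normalized.
#' @param seed integer seed (default `config$seed + 1`).
#' @return list with `dataset` (cells as samples, raw counts), `labels`
#'   (true type per cell), `specimen_map` (data.frame `cell_id`,
#'   `specimen_id`), `true_composition` (percent matrix).
#' @export
simulate_single_cells <- function(config = simulation_config(),
                                  cells_per_specimen = 200L,
                                  n_specimens = 4L, composition = NULL,
                                  seed = NULL) {
  seed <- seed %||% (config$seed + 1L)
  n_type <- config$n_cell_types
  comp <- composition %||% rep(1 / n_type, n_type)
  if (is.null(dim(comp))) comp <- matrix(comp, n_specimens, n_type,
                                         byrow = TRUE)
  comp <- comp / rowSums(comp)
  # regenerate the bulk ground truth (same seed => same genes/means)
  bulk <- simulate_bulk(config)
  gene_ids <- gene_ids(bulk$dataset)
  truth_idx <- list(
    marker_gene_idx = lapply(bulk$truth$markers, function(g)
      match(g, gene_ids)),
    absent_gene_idx = lapply(bulk$truth$absent, function(g)
      match(g, gene_ids)))
  base_mean <- unname(bulk$truth$base_mean)
  with_seed(seed, {
    types <- integer(0); spec <- character(0)
    for (s in seq_len(n_specimens)) {
      t_s <- sample.int(n_type, cells_per_specimen, replace = TRUE,
                        prob = comp[s, ])
      types <- c(types, t_s)
      spec <- c(spec, rep(sprintf("specimen%d", s), cells_per_specimen))
    }
    mu <- sim_mean_matrix(config, types, base_mean, truth_idx)
    counts <- matrix(rnbinom(length(mu), size = config$nb_dispersion,
                             mu = as.vector(mu)), nrow(mu), ncol(mu))
    if (config$single_cell_dropout_rate > 0) {
      drop <- matrix(runif(length(counts)) <
                       config$single_cell_dropout_rate,
                     nrow(counts), ncol(counts))
      counts[drop] <- 0
    }
    cell_ids <- sprintf("cell%05d", seq_len(ncol(counts)))
    dimnames(counts) <- list(gene_ids, cell_ids)
    labels <- paste0("type", types)
    true_comp <- 100 * t(vapply(seq_len(n_specimens), function(s)
      tabulate(types[spec == sprintf("specimen%d", s)], n_type) /
        cells_per_specimen, numeric(n_type)))
    dimnames(true_comp) <- list(sprintf("specimen%d", seq_len(n_specimens)),
                                paste0("type", seq_len(n_type)))
    list(dataset = ExpressionDataset(counts,
                                     gene_annotation = bulk$annotation,
                                     sample_meta = data.frame(
                                       sample_id = cell_ids,
                                       cell_type = NA_character_,
                                       study_id = "sc"),
                                     value_scale = "raw_counts"),
         labels = setNames(labels, cell_ids),
         specimen_map = data.frame(cell_id = cell_ids, specimen_id = spec),
         true_composition = true_comp)
  })
}
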