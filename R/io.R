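#' Read a delimited count matrix
#'
#' Reads a TSV/CSV count matrix (delimiter autodetected from the file
#' extension, `.csv` = comma, anything else = tab) into an
#' [ExpressionDataset] with `value_scale = "raw_counts"`. The tokens `NA`,
#' `NaN` and the empty string mark missing values: they are stored as 0 with
#' the missing mask set, never silently coerced.
#'
#' @param path path to the delimited file; first column (or row) holds
#'   identifiers.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @param value_scale scale to stamp on the result (default
#'   `"raw_counts"`; use `"log2"` to reload a matrix written after the
#'   log2 transform).
#' @return an [ExpressionDataset] of raw counts.
#' @export
read_counts <- function(path, orientation = c("genes_in_rows",
                                              "samples_in_rows"),
                        value_scale = "raw_counts") {
  orientation <- match.arg(orientation)
  tab <- read_delim_checked(path)
  m <- as.matrix(tab$body)
  if (!is.numeric(m))
    stopf("non-numeric cell in %s (first offending column: %s)", path,
          names(tab$body)[which(!vapply(tab$body, is.numeric, TRUE))[1]])
  rownames(m) <- tab$row_ids
  if (orientation == "samples_in_rows") m <- t(m)
  dup <- rownames(m)[duplicated(rownames(m))]
  if (length(dup))
    stopf("duplicate gene id(s) in %s: %s", path,
          paste(unique(dup), collapse = ", "))
  dup <- colnames(m)[duplicated(colnames(m))]
  if (length(dup))
    stopf("duplicate sample id(s) in %s: %s", path,
          paste(unique(dup), collapse = ", "))
  miss <- is.na(m)
  neg <- which(!miss & m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stopf("negative count at gene '%s', sample '%s' in %s",
          rownames(m)[neg[1, 1]], colnames(m)[neg[1, 2]], path)
  m[miss] <- 0
  ExpressionDataset(m, miss, value_scale = value_scale)
}

# Shared delimited reader: autodetects separator, enforces rectangular
# shape, reports the line number of ragged rows, maps NA tokens.
read_delim_checked <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("empty file: %s", path)
  cells <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) > 1) {
    bad <- which(widths != widths[1])[1]
    stopf("ragged row in %s at line %d: %d fields, expected %d",
          path, bad, widths[bad], widths[1])
  }
  header <- cells[[1]]
  if (length(header) < 2) stopf("%s has no data columns", path)
  if (length(cells) < 2) stopf("%s has a header but no data rows", path)
  body_cells <- cells[-1]
  row_ids <- vapply(body_cells, `[`, "", 1)
  # header may or may not carry a leading cell for the id column
  col_ids <- if (length(header) == length(body_cells[[1]])) header[-1] else header
  vals <- lapply(body_cells, function(r) {
    x <- r[-1]
    x[x %in% c("NA", "NaN", "")] <- NA
    suppressWarnings(as.numeric(x))
  })
  nonnum <- vapply(seq_along(vals), function(i) {
    raw <- body_cells[[i]][-1]
    any(is.na(vals[[i]]) & !(raw %in% c("NA", "NaN", "")))
  }, TRUE)
  if (any(nonnum))
    stopf("non-numeric cell in %s at line %d", path, which(nonnum)[1] + 1L)
  body <- as.data.frame(do.call(rbind, vals))
  names(body) <- col_ids
  list(row_ids = row_ids, body = body)
}

#' Write an ExpressionDataset to delimited text
#'
#' Missing values are written as the canonical token `NA`.
#'
#' @param ds an [ExpressionDataset].
#' @param path output path (`.csv` writes comma-separated, else tab).
#' @return `path`, invisibly.
#' @export
write_counts <- function(ds, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  m <- ds$values
  m[ds$missing_mask] <- NA
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read per-gene annotation (GC fraction, length)
#'
#' @param path delimited file with columns `gene_id`, `gc_fraction`,
#'   `length_bp`.
#' @return a data.frame with validated columns.
#' @export
read_gene_annotation <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("gene_id", "gc_fraction", "length_bp")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("annotation file %s lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$gc_fraction) | df$gc_fraction < 0 |
                 df$gc_fraction > 1)
  if (length(bad))
    stopf("gc_fraction outside [0,1] for gene '%s'", df$gene_id[bad[1]])
  bad <- which(!is.finite(df$length_bp) | df$length_bp <= 0 |
                 df$length_bp != round(df$length_bp))
  if (length(bad))
    stopf("length_bp not a positive integer for gene '%s'", df$gene_id[bad[1]])
  df[need]
}

#' Read per-sample labels
#'
#' @param path delimited file with columns `sample_id`, `cell_type` and
#'   optionally `study_id`; `cell_type` may be `NA` for unlabeled cells.
#' @return a data.frame usable as `sample_meta`.
#' @export
read_sample_labels <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "cell_type") %in% names(df)))
    stopf("label file %s needs columns sample_id, cell_type", path)
  if (!"study_id" %in% names(df)) df$study_id <- NA_character_
  df[c("sample_id", "cell_type", "study_id")]
}

#' Read a sparse single-cell matrix (MTX coordinate triplets)
#'
#' Reads MatrixMarket coordinate triplets with companion one-column gene and
#' barcode files. Entries absent from the triplet list are structural zeros,
#' not missing values. Duplicate coordinates are summed (the common dialect
#' for coordinate files).
#'
#' @param matrix_path MTX file; @param genes_path,barcodes_path one
#'   identifier per line, genes ordered as MTX rows, barcodes as columns.
#' @return a dense [ExpressionDataset] of raw counts.
#' @export
read_sparse_matrix <- function(matrix_path, genes_path, barcodes_path) {
  sm <- tryCatch(Matrix::readMM(matrix_path),
                 error = function(e) stopf("malformed MTX file %s: %s",
                                           matrix_path, conditionMessage(e)))
  genes <- readLines(genes_path)
  genes <- sub("\t.*$", "", genes[nzchar(genes)])
  cells <- readLines(barcodes_path)
  cells <- cells[nzchar(cells)]
  if (length(genes) != nrow(sm))
    stopf("gene list (%d) does not match MTX rows (%d)", length(genes),
          nrow(sm))
  if (length(cells) != ncol(sm))
    stopf("barcode list (%d) does not match MTX columns (%d)", length(cells),
          ncol(sm))
  m <- as.matrix(sm)
  if (min(m) < 0) stopf("negative count in %s", matrix_path)
  dimnames(m) <- list(genes, cells)
  ExpressionDataset(m, value_scale = "raw_counts")
}

#' Read gene sets (GMT or two-column TSV)
#'
#' GMT: one set per line, `name <tab> description <tab> gene...`. TSV: two
#' columns `set_name`, `gene` (header optional).
#'
#' @param path gene-set file; format chosen by `.gmt` extension.
#' @return named list of character vectors (each a `GeneSet`).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("empty gene-set file: %s", path)
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
      if (length(f) < 3) stopf("GMT line with fewer than 3 fields in %s", path)
      list(name = f[1], genes = unique(f[-(1:2)]))
    })
    out <- setNames(lapply(sets, `[[`, "genes"),
                    vapply(sets, `[[`, "", "name"))
  } else {
    cells <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(cells) != 2))
      stopf("two-column TSV expected in %s", path)
    df <- do.call(rbind.data.frame, cells)
    names(df) <- c("set_name", "gene")
    if (identical(tolower(df$set_name[1]), "set_name")) df <- df[-1, ]
    out <- lapply(split(df$gene, df$set_name), unique)
  }
  if (any(lengths(out) == 0)) stopf("empty gene set in %s", path)
  out
}

MODEL_SCHEMA_VERSION <- "1.0"

#' Serialize / deserialize a fitted classifier model
#'
#' Models round-trip through self-describing JSON preserving gene order,
#' class order, every coefficient, the penalty parameters and the training
#' provenance. Reading a file with an unknown schema version is an explicit
#' error, never a silent downgrade.
#'
#' @param model a `ClassifierModel` as returned by
#'   [fit_multinomial_elasticnet()] or [fit_binary_elasticnet()].
#' @param path JSON path.
#' @return `write_model()` returns `path` invisibly; `read_model()` the
#'   reconstructed `ClassifierModel`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "ClassifierModel"))
  payload <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    family = model$family,
    class_labels = model$class_labels,
    gene_ids = model$gene_ids,
    intercepts = model$intercepts,
    coefficients = asplit_cols(model$coefficients),
    penalty = model$penalty,
    converged = model$converged,
    training_provenance = model$training_provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

asplit_cols <- function(m) setNames(lapply(seq_len(ncol(m)),
                                           function(j) unname(m[, j])),
                                    colnames(m))

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$schema_version) ||
      !identical(as.character(p$schema_version), MODEL_SCHEMA_VERSION))
    stopf("unknown model schema version '%s' in %s (expected %s)",
          p$schema_version %||% "<absent>", path, MODEL_SCHEMA_VERSION)
  coef_cols <- names(p$coefficients)
  coef <- if (length(p$gene_ids) == 0) {
    matrix(0, 0, length(coef_cols), dimnames = list(NULL, coef_cols))
  } else {
    co <- do.call(cbind, p$coefficients)
    rownames(co) <- p$gene_ids
    colnames(co) <- coef_cols
    co
  }
  new_classifier_model(
    family = p$family, class_labels = p$class_labels,
    gene_ids = p$gene_ids %||% character(0),
    intercepts = setNames(as.numeric(p$intercepts), p$class_labels),
    coefficients = coef, penalty = p$penalty,
    converged = isTRUE(p$converged),
    training_provenance = p$training_provenance)
}
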