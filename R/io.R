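# Readers and writers for the package's plain-text interchange formats:
# TSV for dense expression and result tables, MatrixMarket for sparse
# counts, CSV for panel metadata and growth studies, YAML for signatures
# and scenario configuration.

#' Write / read a TPM expression matrix as TSV
#'
#' Genes in rows (first column `gene_id`), one column per sample. On read,
#' column sums are checked against 1e6 within 1%; off-scale columns
#' trigger a warning, or are rescaled when `renormalize = TRUE`.
#'
#' @param expression Genes x samples numeric matrix.
#' @param path File path.
#' @param renormalize Rescale every column to 1e6 on read.
#' @return `read_expression_tsv`: the matrix; `write_expression_tsv`: the
#'   path, invisibly.
#' @export
write_expression_tsv <- function(expression, path) {
  if (is.null(rownames(expression)) || is.null(colnames(expression))) {
    stop("`expression` must have gene rownames and sample colnames",
         call. = FALSE)
  }
  df <- data.frame(gene_id = rownames(expression), expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, renormalize = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c(gene_id = "character"),
                          stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(df)) {
    stop("expression TSV must have a `gene_id` first column", call. = FALSE)
  }
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup)) {
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  body <- df[setdiff(names(df), "gene_id")]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric value at gene '%s', sample '%s'",
                   df$gene_id[bad], names(body)[j]), call. = FALSE)
    }
  }
  mat <- as.matrix(body)
  rownames(mat) <- df$gene_id
  cs <- colSums(mat)
  off <- abs(cs / 1e6 - 1) > 0.01
  if (any(off)) {
    if (renormalize) {
      mat <- sweep(mat, 2L, cs / 1e6, "/")
    } else {
      warning(sprintf(
        "%d column(s) deviate from a 1e6 TPM sum by more than 1%% (e.g. %s: %.4g); set renormalize = TRUE to rescale",
        sum(off), colnames(mat)[which(off)[1]], cs[which(off)[1]]))
    }
  }
  mat
}

#' Write / read sparse single-cell counts (MatrixMarket + label files)
#'
#' The 10x-style trio: a MatrixMarket coordinate file of genes x cells
#' counts, a one-id-per-line gene file, and a TSV of cell ids with their
#' cluster labels (columns `cell_id`, `cluster`).
#'
#' @param dataset An `sc_dataset` (see [simulate_scrnaseq()]).
#' @param path_mtx,path_genes,path_cells File paths.
#' @return `read_sparse_counts`: an `sc_dataset`; the writer returns
#'   `path_mtx` invisibly.
#' @export
write_sparse_counts <- function(dataset, path_mtx, path_genes, path_cells) {
  stopifnot(inherits(dataset, "sc_dataset"))
  Matrix::writeMM(Matrix::Matrix(dataset$counts, sparse = TRUE), path_mtx)
  writeLines(dataset$gene_ids, path_genes)
  utils::write.table(
    data.frame(cell_id = dataset$cell_ids,
               cluster = as.character(dataset$cell_cluster),
               stringsAsFactors = FALSE),
    path_cells, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path_mtx)
}

#' @rdname write_sparse_counts
#' @export
read_sparse_counts <- function(path_mtx, path_genes, path_cells) {
  counts <- Matrix::readMM(path_mtx)
  # an all-zero matrix round-trips as a pattern matrix; coerce to numeric
  counts <- methods::as(methods::as(counts, "dMatrix"), "CsparseMatrix")
  genes <- readLines(path_genes)
  cells <- utils::read.delim(path_cells, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "cluster") %in% names(cells))) {
    stop("cell label file must have columns cell_id and cluster",
         call. = FALSE)
  }
  if (length(genes) != nrow(counts)) {
    stop(sprintf("gene label file does not match the matrix: expected %d ids, found %d",
                 nrow(counts), length(genes)), call. = FALSE)
  }
  if (nrow(cells) != ncol(counts)) {
    stop(sprintf("cell label file does not match the matrix: expected %d cells, found %d",
                 ncol(counts), nrow(cells)), call. = FALSE)
  }
  if (Matrix::nnzero(counts) == 0L) {
    warning("count matrix has no nonzero entries")
  }
  dimnames(counts) <- list(genes, cells$cell_id)
  structure(list(
    counts = counts,
    cell_cluster = factor(cells$cluster, levels = unique(cells$cluster)),
    gene_ids = genes,
    cell_ids = cells$cell_id
  ), class = "sc_dataset")
}

#' Write / read panel sample metadata as CSV
#'
#' Sample-level metadata of a model panel: `sample_id`, `model`,
#' `replicate`, `mvd_ihc`, plus (when present) the planted per-model truth
#' columns merged in.
#'
#' @param panel A `model_panel`.
#' @param path File path.
#' @return `read_panel_metadata_csv`: a data.frame; writer returns the
#'   path invisibly.
#' @export
write_panel_metadata_csv <- function(panel, path) {
  stopifnot(inherits(panel, "model_panel"))
  meta <- merge(panel$samples, panel$models, by = "model", sort = FALSE)
  meta <- meta[order(meta$model, meta$replicate), , drop = FALSE]
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_panel_metadata_csv
#' @export
read_panel_metadata_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a growth study as long-format CSV
#'
#' Columns `model`, `arm`, `animal`, `day`, `volume_mm3`; alternatively a
#' caliper table with `length_mm` and `width_mm` instead of `volume_mm3`,
#' from which volumes are computed via [tumor_volume()].
#'
#' @param growth Growth study data.frame.
#' @param path File path.
#' @return `read_growth_csv`: a `growth_study` data.frame with volumes;
#'   writer returns the path invisibly.
#' @export
write_growth_csv <- function(growth, path) {
  utils::write.csv(growth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_growth_csv
#' @export
read_growth_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  base <- c("model", "arm", "animal", "day")
  if (!all(base %in% names(df))) {
    stop("growth CSV must contain columns ", paste(base, collapse = ", "),
         call. = FALSE)
  }
  if (!"volume_mm3" %in% names(df)) {
    if (!all(c("length_mm", "width_mm") %in% names(df))) {
      stop("growth CSV needs either volume_mm3 or length_mm + width_mm",
           call. = FALSE)
    }
    df$volume_mm3 <- tumor_volume(df$length_mm, df$width_mm)
  }
  if (any(df$volume_mm3 <= 0)) {
    stop("tumor volumes must be positive", call. = FALSE)
  }
  key <- paste(df$model, df$arm, df$animal, df$day)
  if (anyDuplicated(key)) {
    stop("duplicate (model, arm, animal, day) record(s)", call. = FALSE)
  }
  class(df) <- c("growth_study", "data.frame")
  df
}

#' Write / read a signature definition as YAML
#'
#' Serializes the gene list together with its transform convention (and
#' weights, when defined) so a score computed elsewhere means the same
#' thing.
#'
#' @param signature A `signature_def`.
#' @param path File path.
#' @return `read_signature_yaml`: a `signature_def`; writer returns the
#'   path invisibly.
#' @export
write_signature_yaml <- function(signature, path) {
  stopifnot(inherits(signature, "signature_def"))
  obj <- list(name = signature$name, genes = as.list(signature$genes),
              transform = signature$transform)
  if (!is.null(signature$weights)) obj$weights <- as.list(signature$weights)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_signature_yaml
#' @export
read_signature_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$genes) || is.null(obj$transform)) {
    stop("signature YAML must define `genes` and `transform`", call. = FALSE)
  }
  mvd_signature(unlist(obj$genes), name = obj$name %||% "signature",
                log_base = obj$transform$log_base %||% 2,
                pseudocount = obj$transform$pseudocount %||% 1,
                unit = obj$transform$unit %||% "TPM",
                weights = if (!is.null(obj$weights)) unlist(obj$weights))
}

#' Read a scenario configuration YAML
#'
#' A scenario file carries every simulation and analysis parameter of a
#' pipeline run plus the master seed (see [panel12_scenario()] for the
#' reference values). Missing fields fall back to the panel12 defaults.
#'
#' @param path YAML file path.
#' @return Named parameter list for [run_pipeline()].
#' @export
read_scenario_yaml <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- panel12_scenario()
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  if (!is.null(user$effect_map)) {
    cfg$effect_map <- lapply(user$effect_map, function(e) {
      if (is.list(e)) unlist(e) else e
    })
  }
  if (!is.null(user$days)) cfg$days <- as.integer(unlist(user$days))
  cfg
}
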