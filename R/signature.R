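#' Construct a gene-signature definition
#'
#' A signature is an ordered, unique gene list together with the transform
#' convention under which its score is computed; a score is meaningless
#' without the transform, so it travels with the definition. The default —
#' mean of `log2(TPM + 1)` over the signature genes — is the convention
#' used throughout the package. Optional per-gene weights turn the score
#' into a weighted mean, for fidelity to externally published signatures
#' that define one.
#'
#' @param genes Non-empty character vector of unique gene ids (ordered).
#' @param name Signature name.
#' @param log_base Logarithm base (default 2).
#' @param pseudocount Added to expression before the log (default 1).
#' @param unit Expression unit the transform assumes (default "TPM").
#' @param weights Optional numeric weights, one per gene (named or
#'   positional).
#' @return An object of class `signature_def`.
#' @export
#' @examples
#' sig <- mvd_signature(c("Kdr", "Cdh5", "Tek"), name = "ec3")
#' sig
mvd_signature <- function(genes, name = "signature", log_base = 2,
                          pseudocount = 1, unit = "TPM", weights = NULL) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("`genes` must be non-empty", call. = FALSE)
  if (anyDuplicated(genes)) {
    stop("duplicate gene ids in signature: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  check_scalar(log_base, "log_base", lower = 1, strict_lower = TRUE)
  check_scalar(pseudocount, "pseudocount", lower = 0, strict_lower = TRUE)
  if (!is.null(weights)) {
    if (length(weights) != length(genes)) {
      stop("`weights` must have one value per gene", call. = FALSE)
    }
    if (!is.null(names(weights))) weights <- weights[genes]
    weights <- unname(as.numeric(weights))
    if (any(!is.finite(weights))) {
      stop("`weights` must be finite (and cover every signature gene when named)",
           call. = FALSE)
    }
  }
  structure(list(
    name = name,
    genes = genes,
    transform = list(log_base = log_base, pseudocount = pseudocount,
                     unit = unit),
    weights = weights
  ), class = "signature_def")
}

#' @export
print.signature_def <- function(x, ...) {
  cat(sprintf("signature_def '%s': %d genes, score = %smean of log%g(%s + %g)\n",
              x$name, length(x$genes),
              if (is.null(x$weights)) "" else "weighted ",
              x$transform$log_base, x$transform$unit,
              x$transform$pseudocount))
  cat("  genes: ", paste(utils::head(x$genes, 10), collapse = ", "),
      if (length(x$genes) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Per-model mean log expression across replicates
#'
#' For each model, the mean over its replicate samples of
#' `log2(TPM + 1)` — the aggregation level at which candidate genes are
#' correlated against MVD(IHC), so the correlation's n is the number of
#' models.
#'
#' @param panel A `model_panel` (see [simulate_panel()]), or a list with
#'   `expression` (genes x samples TPM) and `samples` (data.frame with
#'   `sample_id`, `model`).
#' @param genes Genes to extract; all must be present.
#' @return Matrix genes x models of mean log2(TPM + 1).
#' @export
model_mean_log_expression <- function(panel, genes) {
  expr <- panel$expression
  samples <- panel$samples
  genes <- as.character(genes)
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    stop("gene(s) absent from panel expression: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lg <- log2(expr[genes, , drop = FALSE] + 1)
  models <- unique(samples$model)
  out <- vapply(models, function(m) {
    rowMeans(lg[, samples$model == m, drop = FALSE])
  }, numeric(length(genes)))
  out <- matrix(out, nrow = length(genes),
                dimnames = list(genes, models))
  out
}

#' Correlate per-gene expression with MVD(IHC) across models
#'
#' Sample Pearson correlation of each gene's per-model mean log expression
#' against the per-model MVD(IHC) value, with a two-sided t-distribution
#' p-value on n - 2 degrees of freedom. Genes with zero expression variance
#' (r undefined) are reported as `NA` with a warning and are skipped by
#' [top_correlated()].
#'
#' @param model_means Genes x models matrix from
#'   [model_mean_log_expression()].
#' @param model_mvd Numeric MVD(IHC) per model (named by model or aligned
#'   with the matrix columns); typically the mean over replicate
#'   measurements.
#' @return A `data.frame`: `gene`, `pearson_r`, `p_value`, `n_models`.
#' @export
correlate_with_mvd <- function(model_means, model_mvd) {
  if (is.null(dim(model_means))) {
    stop("`model_means` must be a genes x models matrix", call. = FALSE)
  }
  n <- ncol(model_means)
  if (n < 3L) stop("need >= 3 models to report correlations", call. = FALSE)
  if (!is.null(names(model_mvd))) {
    missing <- setdiff(colnames(model_means), names(model_mvd))
    if (length(missing)) {
      stop("MVD value missing for model(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    model_mvd <- model_mvd[colnames(model_means)]
  }
  if (length(model_mvd) != n) {
    stop("`model_mvd` must supply one value per model", call. = FALSE)
  }
  mvd <- as.numeric(model_mvd)
  if (stats::sd(mvd) == 0) {
    warning("MVD values have zero variance; all correlations undefined")
    return(data.frame(gene = rownames(model_means), pearson_r = NA_real_,
                      p_value = NA_real_, n_models = n,
                      stringsAsFactors = FALSE))
  }
  r <- suppressWarnings(as.numeric(stats::cor(t(model_means), mvd)))
  flat <- apply(model_means, 1L, stats::sd) == 0
  r[flat] <- NA_real_
  if (any(flat)) {
    warning(sprintf(
      "%d gene(s) with zero expression variance; correlation undefined and excluded from ranking",
      sum(flat)))
  }
  # two-sided p from the t transform of r; exactly what cor.test reports
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[is.nan(p)] <- 0  # |r| = 1 exactly
  data.frame(gene = rownames(model_means) %||% seq_len(nrow(model_means)),
             pearson_r = r, p_value = p, n_models = n,
             stringsAsFactors = FALSE)
}

#' Top genes by signed correlation with MVD(IHC)
#'
#' The top `k` genes by descending Pearson r (signed, not absolute: the
#' signature seeks genes whose abundance tracks vessel density positively),
#' ties broken lexicographically by gene id. Genes with undefined r are
#' excluded.
#'
#' @param correlation_table Output of [correlate_with_mvd()].
#' @param k Number of genes to keep (default 20). If fewer valid genes
#'   exist, all are returned with a warning.
#' @return The top-k slice of the table (columns `gene`, `pearson_r`, ...),
#'   ordered.
#' @export
top_correlated <- function(correlation_table, k = 20) {
  if (!is.data.frame(correlation_table) ||
      !all(c("gene", "pearson_r") %in% names(correlation_table))) {
    stop("`correlation_table` must contain columns gene and pearson_r",
         call. = FALSE)
  }
  check_scalar(k, "k", lower = 1)
  tab <- correlation_table[!is.na(correlation_table$pearson_r), , drop = FALSE]
  tab <- tab[order(-tab$pearson_r, tab$gene), , drop = FALSE]
  if (nrow(tab) < k) {
    warning(sprintf("only %d gene(s) with defined correlation; k = %d requested",
                    nrow(tab), k))
    k <- nrow(tab)
  }
  out <- utils::head(tab, k)
  rownames(out) <- NULL
  out
}

#' Expression specificity of a gene for one cluster
#'
#' The fraction of a gene's total normalized expression that falls in the
#' target cluster's cells: 1 for a gene expressed exclusively there, 1/K
#' for a gene uniform across K equally sized clusters. This index is the
#' numeric replacement for manual inspection of embedding plots when
#' deciding whether a candidate is genuinely endothelial. A gene with zero
#' total expression gets 0 by convention (flagged via attribute
#' `all_zero`).
#'
#' @param dataset An `sc_dataset` (see [simulate_scrnaseq()]).
#' @param genes Gene id(s) to evaluate.
#' @param target_cluster Cluster of interest.
#' @return Named numeric vector in \[0, 1\], one value per gene.
#' @export
specificity_index <- function(dataset, genes, target_cluster) {
  stopifnot(inherits(dataset, "sc_dataset"))
  genes <- as.character(genes)
  missing <- setdiff(genes, dataset$gene_ids)
  if (length(missing)) {
    stop("gene(s) absent from the single-cell dataset: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  labels <- as.character(dataset$cell_cluster)
  if (!target_cluster %in% labels) {
    stop(sprintf("cluster '%s' not found; available clusters: %s",
                 target_cluster,
                 paste(sort(unique(labels)), collapse = ", ")), call. = FALSE)
  }
  nm <- normalize_cells(dataset$counts, drop_empty = TRUE)
  kept <- setdiff(colnames(dataset$counts), attr(nm, "dropped_cells"))
  labels <- labels[match(kept, colnames(dataset$counts))]
  in_t <- labels == target_cluster
  tot <- Matrix::rowSums(nm[genes, , drop = FALSE])
  in_target <- Matrix::rowSums(nm[genes, in_t, drop = FALSE])
  idx <- ifelse(tot > 0, in_target / tot, 0)
  out <- stats::setNames(as.numeric(idx), genes)
  attr(out, "all_zero") <- genes[tot == 0]
  out
}

#' Build an MVD gene signature from correlated candidates
#'
#' Pools the top MVD-correlated genes with any externally supplied,
#' well-known endothelial markers, drops genes whose single-cell expression
#' specificity for the target cluster falls below `specificity_threshold`,
#' ranks survivors by descending correlation (extra markers without a
#' correlation rank after correlated genes, in their given order), and
#' truncates to `size` genes. If fewer survivors than `size` remain, all
#' are returned with a warning.
#'
#' @param candidates Output of [top_correlated()] (data.frame with `gene`
#'   and `pearson_r`), or a character vector of genes in rank order.
#' @param extra_markers Character vector of canonical EC markers to add to
#'   the pool (e.g. Kdr/Cdh5/Tek orthologs); default none.
#' @param dataset `sc_dataset` used for the specificity filter.
#' @param target_cluster Cluster the signature should be specific to.
#' @param specificity_threshold Minimum [specificity_index()] (default 0.5).
#' @param size Signature size (default 6).
#' @param name Name recorded in the definition.
#' @return A `signature_def` whose attribute `provenance` is a data.frame
#'   with each pool gene's correlation, specificity and whether it was kept.
#' @export
build_signature <- function(candidates, extra_markers = character(),
                            dataset, target_cluster,
                            specificity_threshold = 0.5, size = 6,
                            name = "MVD") {
  if (is.character(candidates)) {
    candidates <- data.frame(gene = candidates,
                             pearson_r = rev(seq_along(candidates)),
                             stringsAsFactors = FALSE)
  }
  if (!is.data.frame(candidates) ||
      !all(c("gene", "pearson_r") %in% names(candidates))) {
    stop("`candidates` must be a data.frame with columns gene and pearson_r",
         call. = FALSE)
  }
  check_scalar(specificity_threshold, "specificity_threshold",
               lower = 0, upper = 1)
  check_scalar(size, "size", lower = 1)
  extra_markers <- setdiff(as.character(extra_markers), candidates$gene)
  pool <- data.frame(
    gene = c(candidates$gene, extra_markers),
    pearson_r = c(candidates$pearson_r, rep(NA_real_, length(extra_markers))),
    stringsAsFactors = FALSE)
  if (nrow(pool) == 0L) stop("candidate pool is empty", call. = FALSE)

  spec <- specificity_index(dataset, pool$gene, target_cluster)
  pool$specificity = as.numeric(spec)
  pool$kept <- pool$specificity >= specificity_threshold

  surv <- pool[pool$kept, , drop = FALSE]
  # correlated genes first by descending r; extras keep their given order after
  surv <- surv[order(is.na(surv$pearson_r), -xtfrm(surv$pearson_r)), ,
               drop = FALSE]
  if (nrow(surv) < size) {
    warning(sprintf(
      "only %d gene(s) survive the specificity filter; signature smaller than requested size %d",
      nrow(surv), size))
  }
  final <- utils::head(surv$gene, size)
  if (length(final) == 0L) {
    warning("no gene survives the specificity filter; returning an empty signature shell")
    sig <- structure(list(
      name = name, genes = character(0),
      transform = list(log_base = 2, pseudocount = 1, unit = "TPM"),
      weights = NULL), class = "signature_def")
  } else {
    sig <- mvd_signature(final, name = name)
  }
  attr(sig, "provenance") <- pool
  sig
}

#' Translate a signature's gene identifiers through an ortholog map
#'
#' Signatures store gene identifiers verbatim; applying a mouse-derived
#' signature to human expression (or vice versa) requires an explicit
#' ortholog map supplied by the caller. Genes without a mapping are
#' dropped with a warning.
#'
#' @param signature A `signature_def`.
#' @param map Two-column data.frame (from, to), or the path of a
#'   two-column TSV without header.
#' @return A new `signature_def` with translated, deduplicated gene ids;
#'   weights (if any) follow their genes.
#' @export
map_signature_genes <- function(signature, map) {
  stopifnot(inherits(signature, "signature_def"))
  if (is.character(map) && length(map) == 1L) {
    map <- utils::read.delim(map, header = FALSE, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(map) || ncol(map) < 2L) {
    stop("`map` must be a two-column data.frame or TSV path", call. = FALSE)
  }
  idx <- match(signature$genes, map[[1L]])
  unmapped <- signature$genes[is.na(idx)]
  if (length(unmapped) == length(signature$genes)) {
    stop("no signature gene has an ortholog mapping", call. = FALSE)
  }
  if (length(unmapped)) {
    warning("dropping unmapped gene(s): ", paste(unmapped, collapse = ", "))
  }
  keep <- !is.na(idx)
  new_genes <- map[[2L]][idx[keep]]
  dup <- duplicated(new_genes)
  mvd_signature(new_genes[!dup],
                name = signature$name,
                log_base = signature$transform$log_base,
                pseudocount = signature$transform$pseudocount,
                unit = signature$transform$unit,
                weights = if (!is.null(signature$weights))
                  signature$weights[keep][!dup])
}
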