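#' Library-size normalize a single-cell count matrix
#'
#' Scales every cell to a common library size of `target` (default 10,000):
#' `counts * target / cell_total`. This is the normalization convention the
#' marker test and specificity index operate on.
#'
#' @param counts Genes x cells matrix (dense or `Matrix` sparse), or an
#'   `sc_dataset`.
#' @param target Common library size (default 1e4).
#' @param drop_empty Drop all-zero cells instead of erroring (the number
#'   dropped is reported via a message).
#' @return Normalized matrix of the same class family as the input; for an
#'   `sc_dataset` input, the matrix only. Dropped cells are recorded in
#'   attribute `dropped_cells`.
#' @export
#' @examples
#' m <- matrix(c(5, 0, 5000 - 5, 0, 2, 8), nrow = 3,
#'             dimnames = list(c("a", "b", "c"), c("s1", "s2")))
#' normalize_cells(m)["a", "s1"]  # 5 * 10000 / 5000 = 10
normalize_cells <- function(counts, target = 1e4, drop_empty = FALSE) {
  if (inherits(counts, "sc_dataset")) counts <- counts$counts
  if (is.null(dim(counts))) stop("`counts` must be a matrix", call. = FALSE)
  if (min(counts) < 0) stop("`counts` must be non-negative", call. = FALSE)
  check_scalar(target, "target", lower = 0, strict_lower = TRUE)
  totals <- Matrix::colSums(counts)
  empty <- totals == 0
  dropped <- character(0)
  if (any(empty)) {
    if (!drop_empty) {
      stop(sprintf(
        "%d all-zero cell(s) found (e.g. %s); set drop_empty = TRUE to drop them",
        sum(empty), colnames(counts)[which(empty)[1]] %||% "unnamed"),
        call. = FALSE)
    }
    dropped <- colnames(counts)[empty] %||% as.character(which(empty))
    message(sprintf("normalize_cells: dropped %d all-zero cell(s)", sum(empty)))
    counts <- counts[, !empty, drop = FALSE]
    totals <- totals[!empty]
  }
  out <- counts %*% Matrix::Diagonal(x = target / totals)
  dimnames(out) <- dimnames(counts)
  attr(out, "dropped_cells") <- dropped
  out
}

#' Per-gene log2 fold change of one cluster versus the rest
#'
#' `log2((mean_in_target + pseudocount) / (mean_in_rest + pseudocount))`,
#' with means taken over normalized expression.
#'
#' @param normalized Genes x cells normalized matrix
#'   (see [normalize_cells()]).
#' @param labels Cluster label per cell.
#' @param target_cluster Cluster whose enrichment is measured.
#' @param pseudocount Positive stabilizer added to both means (default 1).
#' @return Named numeric vector of log2 fold changes, one per gene.
#' @export
cluster_log2fc <- function(normalized, labels, target_cluster,
                           pseudocount = 1) {
  labels <- as.character(labels)
  if (ncol(normalized) != length(labels)) {
    stop("`labels` must have one entry per cell", call. = FALSE)
  }
  if (!target_cluster %in% labels) {
    stop(sprintf("cluster '%s' not found; available clusters: %s",
                 target_cluster,
                 paste(sort(unique(labels)), collapse = ", ")), call. = FALSE)
  }
  check_scalar(pseudocount, "pseudocount", lower = 0, strict_lower = TRUE)
  in_t <- labels == target_cluster
  mt <- Matrix::rowMeans(normalized[, in_t, drop = FALSE])
  mr <- Matrix::rowMeans(normalized[, !in_t, drop = FALSE])
  stats::setNames(log2((mt + pseudocount) / (mr + pseudocount)),
                  rownames(normalized))
}

#' Rank-sum marker test of one cluster versus all other cells
#'
#' For every gene, a two-sided Mann-Whitney U test comparing normalized
#' expression in the target cluster against all remaining cells. Ties are
#' handled by midranks with the tie-corrected normal approximation and a
#' continuity correction; a gene whose values are fully tied (zero rank
#' variance) gets p = 1. P-values are returned unadjusted and unfiltered —
#' multiple-testing correction and thresholding happen in
#' [select_ec_genes()].
#'
#' @inheritParams cluster_log2fc
#' @param pseudocount Pseudocount for the accompanying log2 fold change.
#' @return A `data.frame` (one row per gene): `gene`, `mean_target`,
#'   `mean_rest`, `log2fc`, `p_value`.
#' @export
#' @examples
#' pr <- make_cluster_profiles(60, 3, 10, 2, seed = 1)
#' sc <- simulate_scrnaseq(pr, 50, dispersion = 2, seed = 2)
#' nm <- normalize_cells(sc$counts)
#' mt <- ec_marker_test(nm, sc$cell_cluster, "EC")
#' head(mt)
ec_marker_test <- function(normalized, labels, target_cluster,
                           pseudocount = 1) {
  labels <- as.character(labels)
  if (ncol(normalized) != length(labels)) {
    stop("`labels` must have one entry per cell", call. = FALSE)
  }
  if (!target_cluster %in% labels) {
    stop(sprintf("cluster '%s' not found; available clusters: %s",
                 target_cluster,
                 paste(sort(unique(labels)), collapse = ", ")), call. = FALSE)
  }
  in_t <- labels == target_cluster
  n1 <- sum(in_t)
  n2 <- sum(!in_t)
  if (n1 < 2L || n2 < 2L) {
    stop(sprintf(
      "need >= 2 cells in the target cluster and in the rest (got %d vs %d)",
      n1, n2), call. = FALSE)
  }
  x <- as.matrix(normalized)
  n <- n1 + n2

  p <- apply(x, 1L, function(v) {
    r <- rank(v)
    u <- sum(r[in_t]) - n1 * (n1 + 1) / 2
    tied <- tabulate(match(v, unique(v)))
    sigma2 <- (n1 * n2 / 12) *
      ((n + 1) - sum(tied^3 - tied) / (n * (n - 1)))
    if (sigma2 <= 0) return(1)
    z <- u - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    min(1, 2 * stats::pnorm(-abs(z)))
  })

  mt <- rowMeans(x[, in_t, drop = FALSE])
  mr <- rowMeans(x[, !in_t, drop = FALSE])
  genes <- rownames(x) %||% sprintf("gene%d", seq_len(nrow(x)))
  data.frame(
    gene = genes,
    mean_target = unname(mt),
    mean_rest = unname(mr),
    log2fc = log2((unname(mt) + pseudocount) / (unname(mr) + pseudocount)),
    p_value = unname(p),
    stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment across the whole input vector:
#' `adj_p(i) = min over rank >= rank(i) of m * p / rank`, capped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order as the input.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop("`p_values` must be numeric", call. = FALSE)
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("all p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Select endothelial-cell marker genes from a marker table
#'
#' Applies Benjamini-Hochberg correction across all tested genes, then
#' retains genes with `adj_p < alpha` and `log2fc > lfc_threshold` (both
#' strict), sorted by descending log2 fold change with lexicographic gene-id
#' tie-breaking.
#'
#' @param marker_table Output of [ec_marker_test()].
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param lfc_threshold log2 fold-change cutoff (default 1).
#' @return Character vector of selected gene ids, ordered. The full
#'   augmented table (columns `adj_p`, `passes` added) is attached as
#'   attribute `marker_table`.
#' @export
select_ec_genes <- function(marker_table, alpha = 0.05, lfc_threshold = 1) {
  need <- c("gene", "log2fc", "p_value")
  if (!is.data.frame(marker_table) || !all(need %in% names(marker_table))) {
    stop("`marker_table` must contain columns gene, log2fc, p_value",
         call. = FALSE)
  }
  check_scalar(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  if (alpha >= 1) stop("`alpha` must be < 1", call. = FALSE)
  tab <- marker_table
  tab$adj_p <- bh_adjust(tab$p_value)
  tab$passes <- tab$adj_p < alpha & tab$log2fc > lfc_threshold
  sel <- tab[tab$passes, , drop = FALSE]
  sel <- sel[order(-sel$log2fc, sel$gene), , drop = FALSE]
  structure(sel$gene, marker_table = tab)
}
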