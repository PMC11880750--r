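#' Build a set of cluster expression profiles with planted markers
#'
#' Constructs per-cluster mean expression profiles for a simulated tumor
#' single-cell experiment. Every gene starts at a common baseline mean;
#' each cluster receives a disjoint block of marker genes whose mean is
#' raised by a planted log2 fold change. The first cluster is the
#' endothelial-cell (EC) cluster and the second (when present) an immune
#' cluster, so downstream marker selection and T cell-inflamed scoring can
#' both be validated against known truth.
#'
#' @param n_genes Number of genes (positive integer).
#' @param n_clusters Number of clusters (positive integer).
#' @param markers_per_cluster Markers planted per cluster; may be 0.
#' @param marker_log2fc Planted log2 fold change of marker genes over
#'   baseline; must be > 0.
#' @param baseline_mean Expected counts per gene per cell at baseline
#'   (default 0.5, a typical droplet-scRNA-seq depth).
#' @param seed Integer seed; marker gene positions are drawn from it.
#'   Identical arguments give identical profiles.
#' @return An object of class `cluster_profiles`: a list with `profiles`
#'   (genes x clusters matrix of mean expression), `marker_sets` (named list
#'   of marker gene ids per cluster), `ec_cluster`, `immune_cluster`,
#'   `gene_ids`, `baseline_mean`, `marker_log2fc`.
#' @export
#' @examples
#' pr <- make_cluster_profiles(100, 4, markers_per_cluster = 5,
#'                             marker_log2fc = 2, seed = 1)
#' pr$profiles[pr$marker_sets$EC[1], "EC"] / pr$baseline_mean  # 2^2 = 4
make_cluster_profiles <- function(n_genes, n_clusters, markers_per_cluster,
                                  marker_log2fc, baseline_mean = 0.5,
                                  seed = NULL) {
  check_scalar(n_genes, "n_genes", lower = 1)
  check_scalar(n_clusters, "n_clusters", lower = 1)
  check_scalar(markers_per_cluster, "markers_per_cluster", lower = 0)
  check_scalar(marker_log2fc, "marker_log2fc", lower = 0, strict_lower = TRUE)
  check_scalar(baseline_mean, "baseline_mean", lower = 0, strict_lower = TRUE)
  n_genes <- as.integer(n_genes)
  n_clusters <- as.integer(n_clusters)
  markers_per_cluster <- as.integer(markers_per_cluster)
  if (markers_per_cluster * n_clusters > n_genes) {
    stop(sprintf(
      "cannot allocate %d disjoint markers across %d clusters with only %d genes",
      markers_per_cluster, n_clusters, n_genes), call. = FALSE)
  }

  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  cluster_ids <- cluster_names(n_clusters)

  marker_idx <- with_seed(seed, {
    picked <- sample.int(n_genes, markers_per_cluster * n_clusters)
    if (markers_per_cluster == 0L) {
      rep(list(integer(0)), n_clusters)
    } else {
      split(picked, rep(seq_len(n_clusters), each = markers_per_cluster))
    }
  })
  names(marker_idx) <- cluster_ids

  profiles <- matrix(baseline_mean, nrow = n_genes, ncol = n_clusters,
                     dimnames = list(gene_ids, cluster_ids))
  for (k in seq_len(n_clusters)) {
    profiles[marker_idx[[k]], k] <- baseline_mean * 2^marker_log2fc
  }

  structure(list(
    profiles = profiles,
    marker_sets = lapply(marker_idx, function(i) gene_ids[sort(i)]),
    ec_cluster = cluster_ids[[1L]],
    immune_cluster = if (n_clusters >= 2L) cluster_ids[[2L]] else NA_character_,
    gene_ids = gene_ids,
    baseline_mean = baseline_mean,
    marker_log2fc = marker_log2fc
  ), class = "cluster_profiles")
}

cluster_names <- function(n_clusters) {
  ids <- sprintf("C%02d", seq_len(n_clusters))
  ids[1L] <- "EC"
  if (n_clusters >= 2L) ids[2L] <- "Timm"
  ids
}

#' @export
print.cluster_profiles <- function(x, ...) {
  cat(sprintf(
    "cluster_profiles: %d genes x %d clusters (EC cluster '%s', %d markers/cluster, planted log2FC %.3g)\n",
    nrow(x$profiles), ncol(x$profiles), x$ec_cluster,
    length(x$marker_sets[[x$ec_cluster]]), x$marker_log2fc))
  invisible(x)
}
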