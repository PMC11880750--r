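#' Score bulk samples with a gene signature
#'
#' The per-sample score is the mean (or weighted mean, if the signature
#' defines weights) over the signature's present genes of
#' `log_base(TPM + pseudocount)` under the signature's recorded transform.
#' Missing genes are tolerated up to `max_missing` of the signature
#' (default 1/3) and reported; beyond that the score is refused.
#'
#' @param expression_tpm Genes x samples TPM matrix.
#' @param signature A `signature_def` (see [mvd_signature()]) or a plain
#'   character vector of genes (scored under the default transform).
#' @param max_missing Maximum tolerated fraction of missing signature genes.
#' @return Named numeric vector of scores (one per sample) with attributes
#'   `signature`, `n_genes_used`, `missing_genes`.
#' @export
#' @examples
#' tpm <- matrix(3, nrow = 6, ncol = 2,
#'               dimnames = list(paste0("g", 1:6), c("s1", "s2")))
#' signature_score(tpm, paste0("g", 1:6))  # log2(3 + 1) = 2 for both samples
signature_score <- function(expression_tpm, signature, max_missing = 1 / 3) {
  if (is.character(signature)) signature <- mvd_signature(signature)
  stopifnot(inherits(signature, "signature_def"))
  check_scalar(max_missing, "max_missing", lower = 0, upper = 1)
  if (is.null(rownames(expression_tpm))) {
    stop("`expression_tpm` must have gene ids as rownames", call. = FALSE)
  }
  genes <- signature$genes
  present <- genes %in% rownames(expression_tpm)
  if (!any(present)) {
    stop(sprintf("none of the %d genes of signature '%s' are present",
                 length(genes), signature$name), call. = FALSE)
  }
  if (mean(!present) > max_missing) {
    stop(sprintf(
      "%d of %d genes of signature '%s' are missing (more than the allowed fraction %.2f)",
      sum(!present), length(genes), signature$name, max_missing),
      call. = FALSE)
  }
  if (any(!present)) {
    message(sprintf("signature_score: %d of %d '%s' gene(s) missing, scored on the rest",
                    sum(!present), length(genes), signature$name))
  }
  tr <- signature$transform
  lg <- log(expression_tpm[genes[present], , drop = FALSE] + tr$pseudocount,
            base = tr$log_base)
  if (is.null(signature$weights)) {
    scores <- colMeans(lg)
  } else {
    w <- signature$weights[present]
    scores <- as.numeric(crossprod(lg, w) / sum(w))
    names(scores) <- colnames(expression_tpm)
  }
  attr(scores, "signature") <- signature$name
  attr(scores, "n_genes_used") <- sum(present)
  attr(scores, "missing_genes") <- genes[!present]
  scores
}

#' Median classification threshold
#'
#' The sample median (midpoint of the central pair for even n) — the
#' cohort-wide threshold used to split each signature axis into high/low.
#'
#' @param scores Numeric vector (non-empty, finite).
#' @return The median.
#' @export
threshold_median <- function(scores) {
  scores <- as.numeric(scores)
  if (length(scores) == 0L || any(!is.finite(scores))) {
    stop("`scores` must be a non-empty finite numeric vector", call. = FALSE)
  }
  stats::median(scores)
}

#' Top-quartile classification threshold
#'
#' The 75th percentile under the inclusive linear-interpolation convention
#' (`stats::quantile` type 7); "high" means value >= threshold, so a panel
#' of 12 models yields exactly 3 high models. If all values are equal,
#' every value is labeled high and a warning is emitted.
#'
#' @param model_means Numeric vector of per-model means (n >= 4).
#' @return The threshold, with attribute `high` (logical per value).
#' @export
#' @examples
#' th <- threshold_top_quartile(1:12)
#' sum(attr(th, "high"))  # 3
threshold_top_quartile <- function(model_means) {
  x <- as.numeric(model_means)
  if (length(x) < 4L) {
    stop("need >= 4 values for a top-quartile split", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("values must be finite", call. = FALSE)
  th <- unname(stats::quantile(x, 0.75, type = 7))
  if (max(x) == min(x)) {
    warning("all values equal; every model labeled high")
  }
  structure(th, high = stats::setNames(x >= th, names(model_means)))
}

#' Classify samples into MVD x Tcell_inf_GEP quadrant subgroups
#'
#' A sample is "high" on an axis iff its score is strictly greater than the
#' axis threshold; samples exactly at a threshold are low (reported via a
#' message). Every sample receives exactly one of the four labels.
#'
#' @param mvd_scores Named numeric vector of MVD gene scores.
#' @param tgep_scores Named numeric vector of Tcell_inf_GEP scores over the
#'   same samples.
#' @param mvd_threshold,tgep_threshold Axis thresholds (e.g.
#'   [threshold_median()] of a reference cohort).
#' @return A `data.frame`: `sample`, `mvd_score`, `tgep_score`, `quadrant`
#'   (factor with the four subgroup levels), with attribute `thresholds`.
#' @export
#' @examples
#' q <- classify_quadrants(c(a = 2, b = 0), c(a = 1, b = 3),
#'                         mvd_threshold = 1, tgep_threshold = 2)
#' q$quadrant
classify_quadrants <- function(mvd_scores, tgep_scores,
                               mvd_threshold, tgep_threshold) {
  check_scalar(mvd_threshold, "mvd_threshold")
  check_scalar(tgep_threshold, "tgep_threshold")
  if (!is.null(names(mvd_scores)) && !is.null(names(tgep_scores))) {
    if (!setequal(names(mvd_scores), names(tgep_scores))) {
      stop("`mvd_scores` and `tgep_scores` cover different sample sets",
           call. = FALSE)
    }
    tgep_scores <- tgep_scores[names(mvd_scores)]
  } else if (length(mvd_scores) != length(tgep_scores)) {
    stop("`mvd_scores` and `tgep_scores` cover different sample sets",
         call. = FALSE)
  }
  ids <- names(mvd_scores) %||% as.character(seq_along(mvd_scores))
  mh <- as.numeric(mvd_scores) > mvd_threshold
  th <- as.numeric(tgep_scores) > tgep_threshold
  at <- sum(as.numeric(mvd_scores) == mvd_threshold |
              as.numeric(tgep_scores) == tgep_threshold)
  if (at > 0) {
    message(sprintf(
      "classify_quadrants: %d sample(s) exactly at a threshold classified low on that axis",
      at))
  }
  out <- data.frame(
    sample = ids,
    mvd_score = as.numeric(mvd_scores),
    tgep_score = as.numeric(tgep_scores),
    quadrant = factor(
      paste0("MVD-", ifelse(mh, "high", "low"),
             "/Tcell_inf_GEP-", ifelse(th, "high", "low")),
      levels = quadrant_levels()),
    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- c(mvd = mvd_threshold, tgep = tgep_threshold)
  out
}

#' Quadrant proportions per group
#'
#' For each group (e.g. tumor type), the fraction of its samples in each of
#' the four quadrant subgroups. Rows sum to 1; empty groups are omitted
#' with a warning.
#'
#' @param labels Quadrant labels (factor/character, or the data.frame from
#'   [classify_quadrants()], whose `quadrant` column is used).
#' @param group_by Group per sample.
#' @return Matrix groups x quadrants of proportions with attribute
#'   `counts` (the underlying contingency table).
#' @export
subgroup_proportions <- function(labels, group_by) {
  if (is.data.frame(labels)) labels <- labels$quadrant
  labels <- factor(as.character(labels), levels = quadrant_levels())
  if (anyNA(labels)) stop("unknown quadrant label(s) present", call. = FALSE)
  if (length(group_by) != length(labels)) {
    stop("`group_by` must supply one group per sample", call. = FALSE)
  }
  if (!is.factor(group_by)) group_by <- factor(group_by)
  counts <- table(group = group_by, quadrant = labels)
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    warning("omitting empty group(s): ",
            paste(rownames(counts)[empty], collapse = ", "))
    counts <- counts[!empty, , drop = FALSE]
  }
  props <- counts / rowSums(counts)
  out <- matrix(as.numeric(props), nrow = nrow(counts),
                dimnames = dimnames(counts))
  attr(out, "counts") <- counts
  out
}

#' Compare gene signatures by correlation with a reference measurement
#'
#' Scores each signature on the same expression matrix and reports the
#' Pearson correlation (and p-value) of each score vector against a
#' reference measurement such as MVD(IHC), ranked by descending r — the
#' head-to-head benchmark of competing angiogenesis signatures.
#'
#' @param expression_tpm Genes x samples TPM matrix.
#' @param signatures Named list of `signature_def` objects or gene-id
#'   vectors.
#' @param reference_values Numeric reference per sample (named or aligned
#'   with columns); >= 3 samples.
#' @return A `data.frame`: `signature`, `pearson_r`, `p_value`, `n`,
#'   ordered by descending r.
#' @export
compare_signatures <- function(expression_tpm, signatures, reference_values) {
  if (!is.list(signatures) || is.null(names(signatures))) {
    stop("`signatures` must be a named list", call. = FALSE)
  }
  if (!is.null(names(reference_values))) {
    missing <- setdiff(colnames(expression_tpm), names(reference_values))
    if (length(missing)) {
      stop("reference value missing for sample(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    reference_values <- reference_values[colnames(expression_tpm)]
  }
  n <- length(reference_values)
  if (n != ncol(expression_tpm)) {
    stop("`reference_values` must supply one value per sample", call. = FALSE)
  }
  if (n < 3L) stop("need >= 3 samples with reference values", call. = FALSE)
  ref <- as.numeric(reference_values)
  if (stats::sd(ref) == 0) {
    stop("reference values have zero variance; correlation undefined",
         call. = FALSE)
  }
  scores <- vapply(signatures, function(s) {
    as.numeric(signature_score(expression_tpm, s))
  }, numeric(n))
  r <- as.numeric(stats::cor(scores, ref))
  flat <- apply(scores, 2L, stats::sd) == 0
  r[flat] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[is.nan(p)] <- 0
  out <- data.frame(signature = names(signatures), pearson_r = r,
                    p_value = p, n = n, stringsAsFactors = FALSE)
  out <- out[order(-xtfrm(out$pearson_r)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Quadrant subgroup labels
#'
#' The four MVD x Tcell_inf_GEP subgroup labels in their canonical factor
#' order.
#'
#' @return Character vector of length 4.
#' @export
#' @examples
#' quadrants()
quadrants <- function() quadrant_levels()
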