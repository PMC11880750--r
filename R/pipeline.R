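#' Run the full signature-derivation and efficacy pipeline
#'
#' Executes the five analysis stages on a simulated scenario and writes
#' every intermediate table plus a machine-readable run manifest to
#' `outdir`:
#'
#' 1. **simulate** — cluster profiles, single-cell counts, bulk panel with
#'    paired MVD(IHC), growth study (all from per-stage seeds derived from
#'    the one master seed);
#' 2. **markers** — library-size normalization, rank-sum EC-marker test,
#'    BH correction and log2FC filter;
#' 3. **signature** — per-model mean log expression, correlation with
#'    MVD(IHC), top-k ranking, specificity filter, final MVD signature;
#'    a T cell-inflamed analogue is built from the immune cluster's
#'    markers by the same filters;
#' 4. **scoring** — MVD and Tcell_inf_GEP scores on the panel, model-level
#'    means, median thresholds, quadrant classification;
#' 5. **efficacy** — per-model delta T/C at the evaluation day, Welch
#'    comparison of high vs low MVD-score models (top-quartile split).
#'
#' All randomness flows from `config$seed`; a rerun with the same config
#' writes byte-identical result tables.
#'
#' @param config Named parameter list — see [panel12_scenario()] for all
#'   fields — or a YAML path readable by [read_scenario_yaml()].
#' @param outdir Output directory (created if absent).
#' @return Invisibly, a list with the in-memory stage results: `profiles`,
#'   `sc`, `panel`, `markers`, `signature`, `tgep_signature`, `scores`,
#'   `quadrants`, `growth`, `delta_t_c`, `high_low_test`, `manifest`.
#' @export
#' @examples
#' \donttest{
#' cfg <- panel12_scenario(seed = 1)
#' cfg$n_genes <- 200; cfg$cells_per_cluster <- 40; cfg$n_clusters <- 4
#' cfg$markers_per_cluster <- 15
#' res <- run_pipeline(cfg, outdir = tempfile("run"))
#' res$signature
#' }
run_pipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_scenario_yaml(config)
  }
  required <- c("seed", "n_genes", "n_clusters", "markers_per_cluster",
                "marker_log2fc", "cells_per_cluster", "dispersion",
                "n_models", "replicates_per_model", "alpha",
                "lfc_threshold", "k", "signature_size",
                "specificity_threshold", "day", "effect_map")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop("config is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (missing(outdir) || !is.character(outdir) || length(outdir) != 1L) {
    stop("`outdir` must be a single path", call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 4L)
  stages_done <- character(0)
  paths <- character(0)
  save <- function(writer, obj, file) {
    p <- file.path(outdir, file)
    writer(obj, p)
    paths[[file]] <<- p
  }
  save_table <- function(obj, file, sep = "\t") {
    p <- file.path(outdir, file)
    utils::write.table(obj, p, sep = sep, quote = FALSE, row.names = FALSE)
    paths[[file]] <<- p
  }

  ## stage 1: simulate -------------------------------------------------
  profiles <- make_cluster_profiles(
    n_genes = config$n_genes, n_clusters = config$n_clusters,
    markers_per_cluster = config$markers_per_cluster,
    marker_log2fc = config$marker_log2fc,
    baseline_mean = config$baseline_mean %||% 0.5,
    seed = seeds[1])
  sc <- simulate_scrnaseq(profiles, config$cells_per_cluster,
                          dispersion = config$dispersion, seed = seeds[2])
  panel <- simulate_panel(
    profiles, n_models = config$n_models,
    ec_fraction_range = config$ec_fraction_range %||% c(0.02, 0.25),
    immune_fraction_range = config$immune_fraction_range %||% c(0.02, 0.25),
    mvd_slope = config$mvd_slope %||% 1000,
    mvd_noise_sd = config$mvd_noise_sd %||% 55,
    bulk_noise_sd = config$bulk_noise_sd %||% 0.6,
    replicates_per_model = config$replicates_per_model, seed = seeds[3])
  growth <- simulate_growth(
    panel, effect_map = config$effect_map,
    growth_rate = config$growth_rate %||% 0.18,
    days = config$days %||% seq(1, 15, by = 2),
    n_animals = config$n_animals %||% 8,
    noise_sd = config$growth_noise_sd %||% 0.1, seed = seeds[4])
  save(write_sparse_counts_bundle, sc, "sc_counts.mtx")
  save(write_expression_tsv, panel$expression, "panel_tpm.tsv")
  save(write_panel_metadata_csv, panel, "panel_metadata.csv")
  save(write_growth_csv, growth, "growth.csv")
  stages_done <- c(stages_done, "simulate")

  ## stage 2: markers ---------------------------------------------------
  normalized <- normalize_cells(sc$counts, drop_empty = TRUE)
  kept <- setdiff(sc$cell_ids, attr(normalized, "dropped_cells"))
  labels <- as.character(sc$cell_cluster)[match(kept, sc$cell_ids)]
  marker_tab <- ec_marker_test(normalized, labels, profiles$ec_cluster)
  ec_genes <- select_ec_genes(marker_tab, alpha = config$alpha,
                              lfc_threshold = config$lfc_threshold)
  save_table(attr(ec_genes, "marker_table"), "marker_table.tsv")
  stages_done <- c(stages_done, "markers")

  ## stage 3: signature -------------------------------------------------
  mvd_by_model <- tapply(panel$samples$mvd_ihc, panel$samples$model, mean)
  means <- model_mean_log_expression(panel, as.character(ec_genes))
  corr <- correlate_with_mvd(means, mvd_by_model)
  top <- top_correlated(corr, k = config$k)
  sig <- build_signature(
    top, extra_markers = config$extra_markers %||% character(),
    dataset = sc, target_cluster = profiles$ec_cluster,
    specificity_threshold = config$specificity_threshold,
    size = config$signature_size, name = "MVD")
  # immune-axis analogue, derived by the same filters on the immune cluster
  tgep_tab <- ec_marker_test(normalized, labels, profiles$immune_cluster)
  tgep_genes <- select_ec_genes(tgep_tab, alpha = config$alpha,
                                lfc_threshold = config$lfc_threshold)
  tgep_size <- min(config$tgep_size %||% 18, length(tgep_genes))
  if (tgep_size == 0L) {
    stop("pipeline stage 'signature': no immune-cluster markers found to build the Tcell_inf_GEP analogue",
         call. = FALSE)
  }
  tgep_sig <- mvd_signature(utils::head(as.character(tgep_genes), tgep_size),
                            name = "Tcell_inf_GEP")
  save_table(corr, "correlations.tsv")
  save(write_signature_yaml, sig, "signature_mvd.yaml")
  save(write_signature_yaml, tgep_sig, "signature_tgep.yaml")
  stages_done <- c(stages_done, "signature")

  ## stage 4: scoring ---------------------------------------------------
  mvd_scores <- signature_score(panel$expression, sig)
  tgep_scores <- signature_score(panel$expression, tgep_sig)
  model_mvd_score <- tapply(mvd_scores, panel$samples$model, mean)
  model_tgep_score <- tapply(tgep_scores, panel$samples$model, mean)
  model_order <- panel$models$model
  model_mvd_score <- model_mvd_score[model_order]
  model_tgep_score <- model_tgep_score[model_order]
  quad <- classify_quadrants(
    model_mvd_score, model_tgep_score,
    mvd_threshold = threshold_median(model_mvd_score),
    tgep_threshold = threshold_median(model_tgep_score))
  scores_tab <- data.frame(
    sample = names(mvd_scores),
    model = panel$samples$model,
    mvd_score = as.numeric(mvd_scores),
    tgep_score = as.numeric(tgep_scores),
    stringsAsFactors = FALSE)
  save_table(scores_tab, "scores.tsv")
  quad_tab <- quad
  quad_tab$mvd_threshold <- attr(quad, "thresholds")[["mvd"]]
  quad_tab$tgep_threshold <- attr(quad, "thresholds")[["tgep"]]
  save_table(quad_tab, "quadrants.tsv")
  stages_done <- c(stages_done, "scoring")

  ## stage 5: efficacy --------------------------------------------------
  dtc <- delta_t_c_table(growth, day = config$day)
  dtc_a <- dtc[dtc$arm == "drugA", , drop = FALSE]
  dtc_a <- dtc_a[match(model_order, dtc_a$model), , drop = FALSE]
  qt <- threshold_top_quartile(model_mvd_score)
  high <- attr(qt, "high")
  hl <- compare_high_low(dtc_a$delta_t_c, high)
  save_table(dtc, "delta_t_c.tsv")
  hl_tab <- data.frame(
    statistic = hl$statistic, df = hl$df, p_value = hl$p_value,
    mean_high = hl$mean_x, mean_low = hl$mean_y,
    n_high = hl$n_x, n_low = hl$n_y, stronger_in = hl$stronger_in,
    mvd_score_threshold = as.numeric(qt))
  save_table(hl_tab, "high_low_test.tsv")
  stages_done <- c(stages_done, "efficacy")

  ## manifest -----------------------------------------------------------
  manifest <- list(
    package = "mvdsig",
    version = as.character(utils::packageVersion("mvdsig")),
    seed = config$seed,
    stage_seeds = as.numeric(seeds),
    stages_completed = stages_done,
    parameters = config[order(names(config))],
    outputs = lapply(paths, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    }))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(
    profiles = profiles, sc = sc, panel = panel,
    markers = attr(ec_genes, "marker_table"), ec_genes = as.character(ec_genes),
    signature = sig, tgep_signature = tgep_sig,
    scores = scores_tab, quadrants = quad,
    growth = growth, delta_t_c = dtc, high_low_test = hl,
    manifest = manifest, outdir = outdir))
}

# write_sparse_counts with a one-argument surface for the pipeline writer
# table: companion gene/cell label files sit next to the MTX file.
write_sparse_counts_bundle <- function(dataset, path_mtx) {
  stem <- sub("\\.mtx$", "", path_mtx)
  write_sparse_counts(dataset, path_mtx,
                      paste0(stem, "_genes.txt"),
                      paste0(stem, "_cells.tsv"))
}
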