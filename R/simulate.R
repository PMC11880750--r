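#' Simulate a clustered single-cell RNA-seq count matrix
#'
#' Draws per-gene, per-cell counts from a negative binomial whose mean is
#' the cell's cluster profile and whose variance is
#' `mu + mu^2 / dispersion`. Large `dispersion` approaches the Poisson
#' limit; small values give strong overdispersion.
#'
#' @param profiles A [make_cluster_profiles()] object.
#' @param cells_per_cluster Cells per cluster: a single number or a vector
#'   with one entry per cluster (each >= 1).
#' @param dispersion Negative-binomial size parameter (> 0).
#' @param seed Integer seed; identical arguments give identical counts.
#' @return An object of class `sc_dataset`: list with `counts` (sparse
#'   genes x cells integer matrix), `cell_cluster` (factor per cell),
#'   `gene_ids`, `cell_ids`.
#' @export
#' @examples
#' pr <- make_cluster_profiles(50, 3, 5, 2, seed = 1)
#' sc <- simulate_scrnaseq(pr, cells_per_cluster = 20, dispersion = 2, seed = 2)
#' table(sc$cell_cluster)
simulate_scrnaseq <- function(profiles, cells_per_cluster, dispersion = 2,
                              seed = NULL) {
  stopifnot(inherits(profiles, "cluster_profiles"))
  check_scalar(dispersion, "dispersion", lower = 0, strict_lower = TRUE)
  n_clusters <- ncol(profiles$profiles)
  if (length(cells_per_cluster) == 1L) {
    cells_per_cluster <- rep(cells_per_cluster, n_clusters)
  }
  if (length(cells_per_cluster) != n_clusters || any(cells_per_cluster < 1)) {
    stop("`cells_per_cluster` must give >= 1 cells for each cluster",
         call. = FALSE)
  }
  cells_per_cluster <- as.integer(cells_per_cluster)

  cluster_ids <- colnames(profiles$profiles)
  labels <- factor(rep(cluster_ids, times = cells_per_cluster),
                   levels = cluster_ids)
  n_cells <- length(labels)
  mu <- profiles$profiles[, as.integer(labels), drop = FALSE]

  counts <- with_seed(seed, {
    matrix(stats::rnbinom(length(mu), mu = as.numeric(mu), size = dispersion),
           nrow = nrow(mu), ncol = ncol(mu))
  })
  dimnames(counts) <- list(profiles$gene_ids,
                           sprintf("cell%05d", seq_len(n_cells)))

  structure(list(
    counts = Matrix::Matrix(counts, sparse = TRUE),
    cell_cluster = labels,
    gene_ids = profiles$gene_ids,
    cell_ids = colnames(counts)
  ), class = "sc_dataset")
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat(sprintf("sc_dataset: %d genes x %d cells, %d clusters\n",
              nrow(x$counts), ncol(x$counts), nlevels(x$cell_cluster)))
  invisible(x)
}

#' Simulate a bulk expression panel with paired MVD(IHC)
#'
#' Emulates a panel of syngeneic tumor models, each profiled by bulk RNA-seq
#' (replicate samples, TPM) and by immunohistochemical microvessel counting.
#' Each model's bulk profile is a convex mixture of the cluster mean
#' profiles: the endothelial-cell (EC) weight is the model's vascular
#' fraction `f`, the immune-cluster weight `g` is an independent planted
#' axis, and the remaining mass is split equally over the other clusters.
#' Per-gene, per-sample lognormal noise is applied and columns are
#' renormalized to TPM. MVD(IHC) is drawn per replicate as
#' `mvd_slope * f + N(0, mvd_noise_sd)`, truncated at 0, so bulk EC-gene
#' expression tracks vessel density by construction — the structural
#' assumption the signature-building pipeline must exploit.
#'
#' @param profiles A [make_cluster_profiles()] object (>= 2 clusters).
#' @param n_models Number of tumor models (>= 2).
#' @param ec_fraction_range Length-2 range in \[0, 1\] for the per-model EC
#'   fraction `f`.
#' @param immune_fraction_range Range for the planted immune fraction `g`.
#' @param mvd_slope Vessels per mm2 per unit EC fraction.
#' @param mvd_noise_sd SD of per-replicate Gaussian noise on MVD(IHC).
#' @param bulk_noise_sd SD (natural-log scale) of multiplicative lognormal
#'   noise per gene per sample.
#' @param replicates_per_model Replicate samples per model.
#' @param seed Integer seed.
#' @return An object of class `model_panel`: list with `expression`
#'   (genes x samples TPM matrix), `samples` (data.frame: sample_id, model,
#'   replicate, mvd_ihc), `models` (data.frame of planted truth: model,
#'   ec_fraction, immune_fraction, mvd_ihc_mean, mvd_high, tgep_high,
#'   quadrant_truth), `gene_ids`.
#' @export
#' @examples
#' pr <- make_cluster_profiles(100, 4, 10, 2, seed = 1)
#' pan <- simulate_panel(pr, n_models = 6, replicates_per_model = 3, seed = 2)
#' colSums(pan$expression)[1:3]  # each 1e6
simulate_panel <- function(profiles, n_models = 12,
                           ec_fraction_range = c(0.02, 0.25),
                           immune_fraction_range = c(0.02, 0.25),
                           mvd_slope = 1000, mvd_noise_sd = 35,
                           bulk_noise_sd = 0.55,
                           replicates_per_model = 5, seed = NULL) {
  stopifnot(inherits(profiles, "cluster_profiles"))
  check_scalar(n_models, "n_models", lower = 2)
  check_scalar(replicates_per_model, "replicates_per_model", lower = 1)
  check_scalar(mvd_slope, "mvd_slope", lower = 0, strict_lower = TRUE)
  check_scalar(mvd_noise_sd, "mvd_noise_sd", lower = 0)
  check_scalar(bulk_noise_sd, "bulk_noise_sd", lower = 0)
  check_range <- function(r, name) {
    if (!is.numeric(r) || length(r) != 2L || any(!is.finite(r)) ||
        r[1] > r[2] || r[1] < 0 || r[2] > 1) {
      stop(sprintf("`%s` must be an increasing range within [0, 1]", name),
           call. = FALSE)
    }
  }
  check_range(ec_fraction_range, "ec_fraction_range")
  check_range(immune_fraction_range, "immune_fraction_range")
  n_clusters <- ncol(profiles$profiles)
  if (n_clusters < 2L) {
    stop("panel simulation needs >= 2 clusters (an EC and a non-EC compartment)",
         call. = FALSE)
  }
  if (ec_fraction_range[2] + immune_fraction_range[2] >= 1) {
    stop("EC and immune fraction ranges must leave mass for the other clusters",
         call. = FALSE)
  }
  n_models <- as.integer(n_models)
  replicates_per_model <- as.integer(replicates_per_model)

  P <- profiles$profiles
  gene_ids <- profiles$gene_ids
  model_ids <- sprintf("M%02d", seq_len(n_models))

  res <- with_seed(seed, {
    f <- stats::runif(n_models, ec_fraction_range[1], ec_fraction_range[2])
    g <- stats::runif(n_models, immune_fraction_range[1], immune_fraction_range[2])
    n_samples <- n_models * replicates_per_model
    expr <- matrix(NA_real_, nrow = nrow(P), ncol = n_samples)
    mvd <- numeric(n_samples)
    sample_model <- character(n_samples)
    sample_rep <- integer(n_samples)
    col <- 0L
    for (m in seq_len(n_models)) {
      w <- numeric(n_clusters)
      w[1L] <- f[m]                       # EC cluster
      w[2L] <- g[m]                       # immune cluster
      if (n_clusters > 2L) w[3:n_clusters] <- (1 - f[m] - g[m]) / (n_clusters - 2L)
      base <- as.numeric(P %*% w)
      for (r in seq_len(replicates_per_model)) {
        col <- col + 1L
        x <- base * exp(stats::rnorm(nrow(P), 0, bulk_noise_sd))
        expr[, col] <- x / sum(x) * 1e6
        mvd[col] <- max(0, mvd_slope * f[m] + stats::rnorm(1, 0, mvd_noise_sd))
        sample_model[col] <- model_ids[m]
        sample_rep[col] <- r
      }
    }
    list(f = f, g = g, expr = expr, mvd = mvd,
         sample_model = sample_model, sample_rep = sample_rep)
  })

  sample_ids <- paste0(res$sample_model, "_r", res$sample_rep)
  dimnames(res$expr) <- list(gene_ids, sample_ids)
  samples <- data.frame(
    sample_id = sample_ids, model = res$sample_model,
    replicate = res$sample_rep, mvd_ihc = res$mvd,
    stringsAsFactors = FALSE)
  mvd_mean <- tapply(samples$mvd_ihc, samples$model, mean)[model_ids]
  mvd_high <- res$f > stats::median(res$f)
  tgep_high <- res$g > stats::median(res$g)
  models <- data.frame(
    model = model_ids,
    ec_fraction = res$f,
    immune_fraction = res$g,
    mvd_ihc_mean = as.numeric(mvd_mean),
    mvd_high = mvd_high,
    tgep_high = tgep_high,
    quadrant_truth = factor(
      paste0("MVD-", ifelse(mvd_high, "high", "low"),
             "/Tcell_inf_GEP-", ifelse(tgep_high, "high", "low")),
      levels = quadrant_levels()),
    stringsAsFactors = FALSE)

  structure(list(
    expression = res$expr,
    samples = samples,
    models = models,
    gene_ids = gene_ids,
    replicates_per_model = replicates_per_model
  ), class = "model_panel")
}

#' @export
print.model_panel <- function(x, ...) {
  cat(sprintf("model_panel: %d genes x %d samples (%d models x %d replicates)\n",
              nrow(x$expression), ncol(x$expression), nrow(x$models),
              x$replicates_per_model))
  invisible(x)
}

#' Simulate per-animal tumor growth curves across treatment arms
#'
#' Each animal's tumor volume follows
#' `V(t) = V1 * exp(r_eff * (t - 1)) * lognormal noise` with
#' `r_eff = growth_rate * (1 - effect)`; the per-arm effect is looked up in
#' `effect_map` by the model's quadrant subgroup, so treatment response can
#' be confined to planted subgroups. Animals whose volume exceeds
#' `max_volume` are censored: later measurements are dropped (humane
#' endpoint), and arm means downstream use the animals still on study.
#'
#' @param models Character vector of model ids, or a [simulate_panel()]
#'   object (its `models$quadrant_truth` supplies `quadrant` when omitted).
#' @param quadrant Factor/character of quadrant subgroup labels, one per
#'   model (see [quadrants()] levels).
#' @param effect_map Named list with one entry per arm
#'   (`NT`, `drugA`, `drugB`, `combo`). Each entry is a single effect in
#'   `(-Inf, Inf)` applied to every model, or a named vector keyed by
#'   quadrant label. Effect 0 = no growth inhibition, 1 = growth arrest,
#'   > 1 = regression.
#' @param growth_rate Control exponential growth rate per day.
#' @param days Integer vector of measurement days; must start at 1.
#' @param n_animals Animals per arm (default 8).
#' @param noise_sd SD (natural-log scale) of multiplicative measurement noise.
#' @param v1 Starting volume in mm3 (default 100).
#' @param max_volume Humane-endpoint volume in mm3 (default 2000).
#' @param seed Integer seed.
#' @return A `data.frame` (class `growth_study`) with columns
#'   `model`, `arm`, `animal`, `day`, `volume_mm3`.
#' @export
#' @examples
#' gs <- simulate_growth("M01", "MVD-low/Tcell_inf_GEP-low",
#'                       effect_map = list(NT = 0, drugA = 0.5, drugB = 0,
#'                                         combo = 0.8),
#'                       seed = 1)
#' head(gs)
simulate_growth <- function(models, quadrant = NULL,
                            effect_map = list(NT = 0, drugA = 0, drugB = 0,
                                              combo = 0),
                            growth_rate = 0.18, days = seq(1, 15, by = 2),
                            n_animals = 8, noise_sd = 0.1, v1 = 100,
                            max_volume = 2000, seed = NULL) {
  if (inherits(models, "model_panel")) {
    if (is.null(quadrant)) quadrant <- models$models$quadrant_truth
    models <- models$models$model
  }
  models <- as.character(models)
  if (is.null(quadrant)) {
    stop("`quadrant` labels are required when `models` is not a model_panel",
         call. = FALSE)
  }
  quadrant <- as.character(quadrant)
  if (length(quadrant) != length(models)) {
    stop("`quadrant` must supply one label per model", call. = FALSE)
  }
  bad <- setdiff(unique(quadrant), quadrant_levels())
  if (length(bad)) {
    stop("unknown quadrant label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  arms <- c("NT", "drugA", "drugB", "combo")
  if (!is.list(effect_map) || !setequal(names(effect_map), arms)) {
    stop("`effect_map` must be a named list with entries NT, drugA, drugB, combo",
         call. = FALSE)
  }
  days <- as.integer(days)
  if (length(days) < 2L || days[1] != 1L || is.unsorted(days, strictly = TRUE)) {
    stop("`days` must be a strictly increasing integer vector starting at day 1",
         call. = FALSE)
  }
  check_scalar(growth_rate, "growth_rate", lower = 0, strict_lower = TRUE)
  check_scalar(n_animals, "n_animals", lower = 1)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(v1, "v1", lower = 0, strict_lower = TRUE)
  n_animals <- as.integer(n_animals)

  arm_effect <- function(arm, quad) {
    e <- effect_map[[arm]]
    if (!is.numeric(e)) {
      stop(sprintf("effect_map$%s must be numeric", arm), call. = FALSE)
    }
    if (length(e) == 1L && is.null(names(e))) return(rep(e, length(quad)))
    if (is.null(names(e)) || !all(quad %in% names(e))) {
      stop(sprintf(
        "effect_map$%s must be a scalar or a vector named by quadrant label",
        arm), call. = FALSE)
    }
    unname(e[quad])
  }

  out <- with_seed(seed, {
    rows <- vector("list", length(models) * length(arms))
    i <- 0L
    for (m in seq_along(models)) {
      for (arm in arms) {
        eff <- arm_effect(arm, quadrant[m])
        r_eff <- growth_rate * (1 - eff)
        for (a in seq_len(n_animals)) {
          noise <- if (noise_sd > 0) {
            exp(stats::rnorm(length(days), 0, noise_sd))
          } else {
            rep(1, length(days))
          }
          vol <- v1 * exp(r_eff * (days - 1)) * noise
          # humane endpoint: keep the crossing measurement, drop later ones
          over <- which(vol > max_volume)
          keep <- if (length(over)) seq_len(min(over)) else seq_along(days)
          i <- i + 1L
          rows[[i]] <- data.frame(
            model = models[m], arm = arm,
            animal = sprintf("%s_%s_a%02d", models[m], arm, a),
            day = days[keep], volume_mm3 = vol[keep],
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
  rownames(out) <- NULL
  out$arm <- factor(out$arm, levels = arms)
  class(out) <- c("growth_study", "data.frame")
  out
}

#' Default calibrated simulation scenario ("panel12")
#'
#' Returns the full parameter list of the package's reference scenario:
#' 14 single-cell clusters with 40 planted EC markers at log2 fold change 2
#' over a baseline of 0.5 counts/cell, roughly 5,600 cells, a 12-model bulk
#' panel with 5 replicates per model, and noise calibrated so the
#' population correlation between the recovered signature score and
#' MVD(IHC) is about 0.8. Used by [run_pipeline()] and throughout the test
#' suite.
#'
#' @param seed Master seed for the scenario.
#' @return A named list of parameters understood by [run_pipeline()].
#' @export
#' @examples
#' sc <- panel12_scenario(seed = 1)
#' names(sc)
panel12_scenario <- function(seed = 1) {
  list(
    seed = seed,
    n_genes = 1000,
    n_clusters = 14,
    markers_per_cluster = 40,
    marker_log2fc = 2,
    baseline_mean = 0.5,
    cells_per_cluster = 400,
    dispersion = 2,
    n_models = 12,
    ec_fraction_range = c(0.02, 0.25),
    immune_fraction_range = c(0.02, 0.25),
    mvd_slope = 1000,
    mvd_noise_sd = 35,
    bulk_noise_sd = 0.55,
    replicates_per_model = 5,
    alpha = 0.05,
    lfc_threshold = 1,
    k = 20,
    signature_size = 6,
    # a marker planted at log2FC 2 over 13 other clusters has an expression
    # share of at most 2^2 / (2^2 + 13) ~= 0.24 in EC cells; 0.15 (about
    # twice the uniform share 1/14) separates markers from background here
    specificity_threshold = 0.15,
    tgep_size = 18,
    growth_rate = 0.18,
    days = seq(1, 15, by = 2),
    n_animals = 8,
    growth_noise_sd = 0.1,
    day = 15,
    effect_map = list(
      NT = 0,
      drugA = c("MVD-high/Tcell_inf_GEP-high" = 0.8,
                "MVD-high/Tcell_inf_GEP-low" = 0.8,
                "MVD-low/Tcell_inf_GEP-high" = 0.2,
                "MVD-low/Tcell_inf_GEP-low" = 0.2),
      drugB = c("MVD-high/Tcell_inf_GEP-high" = 0.6,
                "MVD-high/Tcell_inf_GEP-low" = 0.1,
                "MVD-low/Tcell_inf_GEP-high" = 0.6,
                "MVD-low/Tcell_inf_GEP-low" = 0.1),
      combo = c("MVD-high/Tcell_inf_GEP-high" = 1.1,
                "MVD-high/Tcell_inf_GEP-low" = 0.9,
                "MVD-low/Tcell_inf_GEP-high" = 1.0,
                "MVD-low/Tcell_inf_GEP-low" = 0.3)
    )
  )
}
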