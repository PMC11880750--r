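#' Tumor volume from caliper measurements
#'
#' `TV (mm3) = 0.5 x length (mm) x width^2 (mm2)`. Length is the longer
#' axis by convention: pairs with width > length are swapped with a
#' warning.
#'
#' @param length_mm,width_mm Positive caliper measurements (vectorized).
#' @return Tumor volume(s) in mm3.
#' @export
#' @examples
#' tumor_volume(10, 10)  # 500
#' tumor_volume(12, 5)   # 150
tumor_volume <- function(length_mm, width_mm) {
  if (length(length_mm) != length(width_mm)) {
    stop("`length_mm` and `width_mm` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(length_mm)) || any(!is.finite(width_mm)) ||
      any(length_mm <= 0) || any(width_mm <= 0)) {
    stop("tumor dimensions must be positive and finite", call. = FALSE)
  }
  swap <- width_mm > length_mm
  if (any(swap)) {
    warning(sprintf(
      "%d measurement(s) with width > length; axes swapped so length is the longer axis",
      sum(swap)))
    tmp <- length_mm[swap]
    length_mm[swap] <- width_mm[swap]
    width_mm[swap] <- tmp
  }
  0.5 * length_mm * width_mm^2
}

#' Antitumor activity as delta T/C
#'
#' `dT/C = (T_t - T_1) / (C_t - C_1) x 100`, where `T` and `C` are the mean
#' tumor volumes of the treated and control arms on the evaluation day `t`
#' and on day 1. When the treated arm's mean volume on day `t` has fallen
#' below its day-1 mean (tumor regression), the statistic switches to
#' `(T_t - T_1) / T_1 x 100`, which is negative; the branch used is
#' recorded. Lower values indicate stronger antitumor activity; 100 means
#' no effect.
#'
#' @param treated_means,control_means Named numeric vectors of arm mean
#'   volumes indexed by day (names); day 1 and the evaluation day must be
#'   present in both.
#' @param day Evaluation day.
#' @return An object of class `efficacy_result`: list with `delta_t_c`,
#'   `branch_used` ("ratio" or "regression"), `day`, and the four means
#'   used.
#' @export
#' @examples
#' delta_t_c(c("1" = 100, "15" = 200), c("1" = 100, "15" = 600), day = 15)
delta_t_c <- function(treated_means, control_means, day) {
  day_key <- as.character(as.integer(day))
  get_day <- function(v, key, arm) {
    if (is.null(names(v)) || !key %in% names(v)) {
      stop(sprintf("day %s missing from the %s arm means", key, arm),
           call. = FALSE)
    }
    unname(v[[key]])
  }
  t1 <- get_day(treated_means, "1", "treated")
  tt <- get_day(treated_means, day_key, "treated")
  c1 <- get_day(control_means, "1", "control")
  ct <- get_day(control_means, day_key, "control")
  if (any(!is.finite(c(t1, tt, c1, ct))) || any(c(t1, tt, c1, ct) <= 0)) {
    stop("arm mean volumes must be positive and finite", call. = FALSE)
  }
  if (tt < t1) {
    value <- (tt - t1) / t1 * 100
    branch <- "regression"
  } else {
    dc <- ct - c1
    if (dc == 0) {
      stop("control arm volume change is zero; ratio-branch delta T/C undefined",
           call. = FALSE)
    }
    value <- (tt - t1) / dc * 100
    branch <- "ratio"
  }
  structure(list(
    delta_t_c = value, branch_used = branch, day = as.integer(day),
    treated_day = tt, treated_baseline = t1,
    control_day = ct, control_baseline = c1
  ), class = "efficacy_result")
}

#' @export
print.efficacy_result <- function(x, ...) {
  cat(sprintf("delta T/C at day %d: %.2f (%s branch)\n",
              x$day, x$delta_t_c, x$branch_used))
  invisible(x)
}

#' Per-model, per-arm delta T/C from a growth study
#'
#' Computes arm mean volumes per day (over the animals still on study that
#' day) and applies [delta_t_c()] for every treated arm of every model
#' against the control arm.
#'
#' @param growth A growth study `data.frame` with columns `model`, `arm`,
#'   `animal`, `day`, `volume_mm3` (see [simulate_growth()] and
#'   [read_growth_csv()]).
#' @param day Evaluation day.
#' @param control_arm Name of the untreated arm (default "NT").
#' @return A `data.frame`: `model`, `arm`, `day`, `delta_t_c`,
#'   `branch_used`, `n_treated`, `n_control` (animals contributing on the
#'   evaluation day). Model/arm pairs lacking day 1 or the evaluation day
#'   are skipped with a warning.
#' @export
delta_t_c_table <- function(growth, day, control_arm = "NT") {
  need <- c("model", "arm", "animal", "day", "volume_mm3")
  if (!is.data.frame(growth) || !all(need %in% names(growth))) {
    stop("`growth` must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  growth$arm <- as.character(growth$arm)
  if (!control_arm %in% growth$arm) {
    stop(sprintf("control arm '%s' absent from the growth study", control_arm),
         call. = FALSE)
  }
  arm_means <- function(df) {
    m <- tapply(df$volume_mm3, df$day, mean)
    stats::setNames(as.numeric(m), names(m))
  }
  arm_n <- function(df, d) sum(df$day == d)
  out <- list()
  skipped <- character(0)
  for (mod in unique(growth$model)) {
    gm <- growth[growth$model == mod, , drop = FALSE]
    ctrl <- gm[gm$arm == control_arm, , drop = FALSE]
    cm <- if (nrow(ctrl)) arm_means(ctrl) else numeric(0)
    for (arm in setdiff(unique(gm$arm), control_arm)) {
      ga <- gm[gm$arm == arm, , drop = FALSE]
      tm <- arm_means(ga)
      keys <- c("1", as.character(as.integer(day)))
      if (!all(keys %in% names(tm)) || !all(keys %in% names(cm))) {
        skipped <- c(skipped, sprintf("%s/%s", mod, arm))
        next
      }
      res <- delta_t_c(tm, cm, day)
      out[[length(out) + 1L]] <- data.frame(
        model = mod, arm = arm, day = as.integer(day),
        delta_t_c = res$delta_t_c, branch_used = res$branch_used,
        n_treated = arm_n(ga, day), n_control = arm_n(ctrl, day),
        stringsAsFactors = FALSE)
    }
  }
  if (length(skipped)) {
    warning("skipped model/arm pair(s) lacking day 1 or day ", day, ": ",
            paste(skipped, collapse = ", "))
  }
  if (!length(out)) stop("no evaluable model/arm pairs", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Welch two-sample t test
#'
#' Two-sided Welch test (unequal variances, Welch-Satterthwaite degrees of
#' freedom) — the package's two-group comparison throughout. Degenerate
#' input where both groups are constant with equal means returns t = 0,
#' p = 1 by convention (with a message); constant groups with unequal means
#' are refused.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return An object of class `group_comparison`: list with `statistic`,
#'   `df`, `p_value`, `mean_x`, `mean_y`, `n_x`, `n_y`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(11, 12, 13))$p_value
welch_t <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs >= 2 observations", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("observations must be finite", call. = FALSE)
  }
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) {
      message("welch_t: both groups constant with equal means; t = 0, p = 1 by convention")
      return(structure(list(
        statistic = 0, df = length(x) + length(y) - 2, p_value = 1,
        mean_x = mean(x), mean_y = mean(y),
        n_x = length(x), n_y = length(y)), class = "group_comparison"))
    }
    stop("both groups have zero variance with unequal means; Welch test undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  structure(list(
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, mean_x = mean(x), mean_y = mean(y),
    n_x = length(x), n_y = length(y)), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Welch t test: t = %.4g, df = %.3g, p = %.4g (means %.4g vs %.4g, n = %d vs %d)\n",
              x$statistic, x$df, x$p_value, x$mean_x, x$mean_y, x$n_x, x$n_y))
  invisible(x)
}

#' Compare antitumor activity between high and low subgroups
#'
#' Welch t test of per-model delta T/C values between models labeled high
#' and low (e.g. by MVD); reports which group shows stronger activity
#' (lower delta T/C = stronger).
#'
#' @param delta_t_c_values Numeric delta T/C per model.
#' @param high Logical per model: `TRUE` for the high group.
#' @return A `group_comparison` (high group is `x`) with an extra field
#'   `stronger_in` ("high", "low" or "tie").
#' @export
compare_high_low <- function(delta_t_c_values, high) {
  if (length(delta_t_c_values) != length(high)) {
    stop("`high` must supply one label per model", call. = FALSE)
  }
  high <- as.logical(high)
  if (anyNA(high)) stop("`high` labels must be TRUE/FALSE", call. = FALSE)
  if (sum(high) < 2L || sum(!high) < 2L) {
    stop(sprintf(
      "need >= 2 models per group (got %d high, %d low); consider a different threshold",
      sum(high), sum(!high)), call. = FALSE)
  }
  cmp <- welch_t(delta_t_c_values[high], delta_t_c_values[!high])
  cmp$stronger_in <- if (cmp$mean_x < cmp$mean_y) "high"
    else if (cmp$mean_x > cmp$mean_y) "low" else "tie"
  cmp
}

#' Per-model score change tests with BH correction
#'
#' For each model, a Welch t test of signature scores between the control
#' and treated arms, Benjamini-Hochberg-corrected across models; the
#' direction of change is reported. Models lacking >= 2 samples in either
#' arm are skipped with a warning.
#'
#' @param score Numeric score per sample.
#' @param model Model id per sample.
#' @param arm Arm per sample.
#' @param control,treated Arm names to compare (defaults "NT", "drugA").
#' @return A `data.frame`: `model`, `mean_control`, `mean_treated`,
#'   `direction` ("decrease"/"increase"/"none"), `statistic`, `df`, `p_value`,
#'   `adj_p`.
#' @export
score_change_tests <- function(score, model, arm, control = "NT",
                               treated = "drugA") {
  if (length(score) != length(model) || length(score) != length(arm)) {
    stop("`score`, `model` and `arm` must be aligned per sample", call. = FALSE)
  }
  model <- as.character(model); arm <- as.character(arm)
  out <- list()
  skipped <- character(0)
  for (mod in unique(model)) {
    sc_c <- score[model == mod & arm == control]
    sc_t <- score[model == mod & arm == treated]
    if (length(sc_c) < 2L || length(sc_t) < 2L) {
      skipped <- c(skipped, mod)
      next
    }
    cmp <- welch_t(sc_c, sc_t)
    out[[length(out) + 1L]] <- data.frame(
      model = mod, mean_control = cmp$mean_x, mean_treated = cmp$mean_y,
      direction = if (cmp$mean_y < cmp$mean_x) "decrease"
        else if (cmp$mean_y > cmp$mean_x) "increase" else "none",
      statistic = cmp$statistic, df = cmp$df, p_value = cmp$p_value,
      stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    warning("skipped model(s) lacking >= 2 samples per arm: ",
            paste(skipped, collapse = ", "))
  }
  if (!length(out)) stop("no model with enough samples in both arms",
                         call. = FALSE)
  res <- do.call(rbind, out)
  res$adj_p <- bh_adjust(res$p_value)
  rownames(res) <- NULL
  res
}
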