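# Independent reference implementations used as oracles. These are kept
# deliberately naive and separate from the package code paths they check.

# Benjamini-Hochberg step-up rule, written directly from its definition:
# sort p ascending, q_i = m * p_(i) / i, then enforce monotonicity by
# taking the running minimum from the largest rank down.
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- m * p[o] / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    q[i] <- min(q[i], q[i + 1])
  }
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Welch's t statistic, Welch-Satterthwaite df and two-sided p, from the
# textbook formulas.
welch_reference <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(statistic = tstat, df = df,
       p_value = 2 * pt(-abs(tstat), df = df))
}

# A small cluster-profile/single-cell fixture shared across tests.
tiny_profiles <- function(seed = 1, n_genes = 120, n_clusters = 4,
                          markers = 10, lfc = 2) {
  make_cluster_profiles(n_genes, n_clusters, markers, lfc, seed = seed)
}

tiny_sc <- function(seed = 2, cells = 60, ...) {
  simulate_scrnaseq(tiny_profiles(...), cells_per_cluster = cells,
                    dispersion = 2, seed = seed)
}

# Normalized matrix plus aligned labels for a dataset that may have had
# empty cells dropped.
normalized_with_labels <- function(sc) {
  nm <- normalize_cells(sc$counts, drop_empty = TRUE)
  kept <- setdiff(sc$cell_ids, attr(nm, "dropped_cells"))
  list(norm = nm, labels = as.character(sc$cell_cluster)[match(kept, sc$cell_ids)])
}
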