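test_that("cluster profiles plant disjoint markers at the stated fold change", {
  pr <- make_cluster_profiles(1000, 14, 40, marker_log2fc = 2, seed = 1)
  sets <- pr$marker_sets
  expect_length(sets, 14)
  expect_true(all(lengths(sets) == 40))
  expect_equal(anyDuplicated(unlist(sets)), 0L)
  # EC markers sit at exactly 2^2 x baseline in the EC profile column
  ec <- sets[[pr$ec_cluster]]
  expect_equal(unname(pr$profiles[ec, pr$ec_cluster]),
               rep(pr$baseline_mean * 4, 40))
  expect_equal(unname(pr$profiles[ec, "C03"]),
               rep(pr$baseline_mean, 40))
})

test_that("profile construction handles no markers and rejects infeasible sizing", {
  pr0 <- make_cluster_profiles(50, 3, 0, marker_log2fc = 1, seed = 1)
  expect_true(all(lengths(pr0$marker_sets) == 0))
  expect_true(all(pr0$profiles == pr0$baseline_mean))
  expect_error(make_cluster_profiles(10, 3, 5, 1, seed = 1),
               "cannot allocate")
  expect_error(make_cluster_profiles(10, 3, 2, marker_log2fc = 0, seed = 1),
               "marker_log2fc")
})

test_that("all four generators are deterministic given a seed", {
  pr <- tiny_profiles()
  expect_identical(tiny_profiles(), pr)
  expect_identical(simulate_scrnaseq(pr, 10, seed = 5),
                   simulate_scrnaseq(pr, 10, seed = 5))
  expect_identical(simulate_panel(pr, n_models = 4, seed = 5),
                   simulate_panel(pr, n_models = 4, seed = 5))
  em <- list(NT = 0, drugA = 0.5, drugB = 0, combo = 1)
  expect_identical(
    simulate_growth("M1", quadrants()[1], em, n_animals = 3, seed = 5),
    simulate_growth("M1", quadrants()[1], em, n_animals = 3, seed = 5))
  # different seeds: different counts, identical shape and labels
  a <- simulate_scrnaseq(pr, 10, seed = 1)
  b <- simulate_scrnaseq(pr, 10, seed = 2)
  expect_false(identical(a$counts, b$counts))
  expect_identical(dim(a$counts), dim(b$counts))
  expect_identical(a$cell_cluster, b$cell_cluster)
})

test_that("near the Poisson limit the planted marker fold change is recovered", {
  pr <- make_cluster_profiles(200, 3, 20, marker_log2fc = 2, seed = 3)
  sc <- simulate_scrnaseq(pr, cells_per_cluster = 500, dispersion = 1e8,
                          seed = 4)
  counts <- as.matrix(sc$counts)
  ec_cells <- sc$cell_cluster == "EC"
  markers <- pr$marker_sets$EC
  ratio <- mean(counts[markers, ec_cells]) / mean(counts[markers, !ec_cells])
  expect_lt(abs(ratio / 4 - 1), 0.10)
})

test_that("a single-cell cluster of size one is representable", {
  pr <- tiny_profiles()
  sc <- simulate_scrnaseq(pr, cells_per_cluster = c(1, 20, 20, 20), seed = 1)
  expect_equal(sum(sc$cell_cluster == "EC"), 1)
  expect_equal(ncol(sc$counts), 61)
  expect_error(simulate_scrnaseq(pr, 10, dispersion = 0), "dispersion")
})

test_that("simulated panel columns are TPM and invariants hold", {
  pr <- tiny_profiles()
  pan <- simulate_panel(pr, n_models = 6, replicates_per_model = 3, seed = 7)
  expect_equal(unname(colSums(pan$expression)), rep(1e6, 18),
               tolerance = 1e-6)
  expect_true(all(pan$samples$mvd_ihc >= 0))
  expect_equal(nrow(pan$samples), 18)
  expect_true(all(table(pan$samples$model) == 3))
  # quadrant truth consistency: MVD-high truth means EC fraction above median
  med <- median(pan$models$ec_fraction)
  expect_identical(pan$models$mvd_high, pan$models$ec_fraction > med)
  expect_error(simulate_panel(pr, n_models = 1), "n_models")
  expect_error(simulate_panel(pr, ec_fraction_range = c(0.5, 0.2)),
               "range")
})

test_that("noiseless panel: EC-marker expression is monotone in EC fraction and r = 1", {
  pr <- tiny_profiles()
  pan <- simulate_panel(pr, n_models = 8, mvd_noise_sd = 0, bulk_noise_sd = 0,
                        replicates_per_model = 2, seed = 11)
  marker <- pr$marker_sets$EC[1]
  per_model <- tapply(log2(pan$expression[marker, ] + 1),
                      pan$samples$model, mean)
  ord <- order(pan$models$ec_fraction)
  expect_true(all(diff(per_model[pan$models$model[ord]]) > 0))
  mvd <- tapply(pan$samples$mvd_ihc, pan$samples$model, mean)
  expect_equal(cor(mvd[pan$models$model], pan$models$ec_fraction), 1)
})

test_that("growth simulator reproduces the null, arrest and regression regimes", {
  em0 <- list(NT = 0, drugA = 0, drugB = 0, combo = 0)
  g0 <- simulate_growth("M1", quadrants()[4], em0, noise_sd = 0,
                        n_animals = 2, seed = 1)
  dtc <- delta_t_c_table(g0, day = 15)
  expect_equal(dtc$delta_t_c, rep(100, 3))

  em1 <- list(NT = 0, drugA = 1, drugB = 0, combo = 2)
  g1 <- simulate_growth("M1", quadrants()[4], em1, noise_sd = 0,
                        n_animals = 2, seed = 1)
  d1 <- delta_t_c_table(g1, day = 15)
  expect_equal(d1$delta_t_c[d1$arm == "drugA"], 0)  # growth arrest
  expect_lt(d1$delta_t_c[d1$arm == "combo"], 0)     # regression branch
  expect_equal(d1$branch_used[d1$arm == "combo"], "regression")

  expect_error(simulate_growth("M1", "not-a-quadrant", em0),
               "quadrant")
  expect_error(simulate_growth("M1", quadrants()[1],
                               list(NT = 0, drugA = 0)),
               "effect_map")
})

test_that("animals exceeding the humane-endpoint volume are censored", {
  em <- list(NT = 0, drugA = 0, drugB = 0, combo = 0)
  g <- simulate_growth("M1", quadrants()[4], em, growth_rate = 0.4,
                       noise_sd = 0, n_animals = 1, days = seq(1, 15, 2),
                       seed = 1)
  # 100 * exp(0.4 * (day - 1)) crosses 2000 between day 8 and 9: the day-9
  # measurement is kept (the animal is then removed), later days dropped
  nt <- g[g$arm == "NT", ]
  expect_equal(max(nt$day), 9)
  expect_gt(max(nt$volume_mm3), 2000)
  expect_equal(sum(nt$day > 9), 0)
})
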