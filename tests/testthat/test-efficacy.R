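test_that("tumor volume formula and the axis-swap convention", {
  expect_equal(tumor_volume(10, 10), 500)
  expect_equal(tumor_volume(12, 5), 150)
  expect_warning(v <- tumor_volume(5, 12), "swapped")
  expect_equal(v, 150)
  expect_error(tumor_volume(0, 5), "positive")
  expect_error(tumor_volume(c(1, 2), 1), "same length")
})

test_that("delta T/C ratio and regression branches follow their formulas", {
  r <- delta_t_c(c("1" = 100, "15" = 200), c("1" = 100, "15" = 600), 15)
  expect_equal(r$delta_t_c, 20)  # 100/500 x 100
  expect_equal(r$branch_used, "ratio")

  reg <- delta_t_c(c("1" = 100, "15" = 70), c("1" = 100, "15" = 600), 15)
  expect_equal(reg$delta_t_c, -30)  # (70 - 100)/100 x 100
  expect_equal(reg$branch_used, "regression")

  # treated identical to control -> 100 (null effect)
  same <- c("1" = 100, "15" = 480)
  expect_equal(delta_t_c(same, same, 15)$delta_t_c, 100)

  expect_error(delta_t_c(c("1" = 100, "15" = 150),
                         c("1" = 100, "15" = 100), 15),
               "control arm volume change is zero")
  expect_error(delta_t_c(c("1" = 100), c("1" = 100, "15" = 200), 15),
               "day 15 missing")
})

test_that("ratio-branch delta T/C is scale invariant; regression branch signs", {
  tr <- c("1" = 120, "8" = 300)
  ct <- c("1" = 110, "8" = 700)
  a <- delta_t_c(tr, ct, 8)$delta_t_c
  b <- delta_t_c(tr * 7.5, ct * 7.5, 8)$delta_t_c
  expect_equal(a, b, tolerance = 1e-12)
  # regression branch iff treated day mean below day-1 mean, and then < 0
  reg <- delta_t_c(c("1" = 200, "8" = 199), ct, 8)
  expect_equal(reg$branch_used, "regression")
  expect_lt(reg$delta_t_c, 0)
})

test_that("welch_t matches the reference formulas and handles degeneracy", {
  set.seed(13)
  for (i in 1:25) {
    x <- rnorm(sample(2:12, 1)); y <- rnorm(sample(2:12, 1), sd = 2)
    got <- welch_t(x, y)
    ref <- welch_reference(x, y)
    expect_equal(got$statistic, ref$statistic, tolerance = 1e-12)
    expect_equal(got$df, ref$df, tolerance = 1e-12)
    expect_equal(got$p_value, ref$p_value, tolerance = 1e-12)
  }
  # identical groups with variance: t = 0, p = 1
  z <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  # clearly separated groups
  expect_lt(welch_t(c(1, 2, 3), c(11, 12, 13))$p_value, 0.01)
  # degenerate conventions
  expect_message(flat <- welch_t(c(2, 2), c(2, 2)), "convention")
  expect_equal(flat$p_value, 1)
  expect_error(welch_t(c(2, 2), c(3, 3)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), ">= 2")
})

test_that("high/low comparison detects constructed separation and direction", {
  dtc <- c(10, 15, 20, 80, 85, 90)
  high <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  cmp <- compare_high_low(dtc, high)
  expect_lt(cmp$p_value, 0.05)
  expect_equal(cmp$stronger_in, "high")  # lower delta T/C = stronger activity
  same <- compare_high_low(c(1, 2, 3, 1, 2, 3),
                           c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(same$statistic, 0)
  expect_error(compare_high_low(dtc, c(TRUE, rep(FALSE, 5))),
               ">= 2 models per group")
})

test_that("null high/low labels give roughly uniform p-values", {
  set.seed(17)
  ps <- replicate(200, {
    dtc <- rnorm(12, 100, 15)
    high <- sample(rep(c(TRUE, FALSE), 6))
    compare_high_low(dtc, high)$p_value
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  halfw <- 1.96 * sqrt(0.05 * 0.95 / 200)
  expect_lt(mean(ps < 0.05), 0.05 + halfw)
})

test_that("per-model score change tests apply BH across models", {
  set.seed(19)
  # 3 models x 2 arms x 4 samples; planted decrease in M1 only
  model <- rep(c("M1", "M2", "M3"), each = 8)
  arm <- rep(rep(c("NT", "drugA"), each = 4), 3)
  score <- rnorm(24, 5, 0.2)
  score[model == "M1" & arm == "drugA"] <- score[model == "M1" & arm == "drugA"] - 3
  res <- score_change_tests(score, model, arm)
  expect_equal(res$adj_p, bh_reference(res$p_value))
  expect_equal(res$direction[res$model == "M1"], "decrease")
  expect_lt(res$adj_p[res$model == "M1"], 0.05)
  # single model: BH is the identity
  one <- score_change_tests(score[1:8], model[1:8], arm[1:8])
  expect_equal(one$adj_p, one$p_value)
  # model lacking the treated arm is skipped with a warning
  expect_warning(
    two <- score_change_tests(score[1:12], model[1:12],
                              c(arm[1:8], rep("NT", 4))),
    "skipped model")
  expect_equal(two$model, "M1")
})

test_that("delta_t_c_table aggregates arm means per day and flags gaps", {
  em <- list(NT = 0, drugA = 0.5, drugB = 0, combo = 0)
  g <- simulate_growth(c("M1", "M2"), rep(quadrants()[4], 2), em,
                       noise_sd = 0.05, n_animals = 4, seed = 23)
  tab <- delta_t_c_table(g, day = 15)
  expect_equal(nrow(tab), 6)  # 2 models x 3 treated arms
  expect_true(all(tab$delta_t_c[tab$arm == "drugA"] <
                    tab$delta_t_c[tab$arm == "drugB"]))
  # hand-check one cell against arm means
  m1 <- g[g$model == "M1" & g$arm == "drugA", ]
  nt <- g[g$model == "M1" & g$arm == "NT", ]
  tm <- tapply(m1$volume_mm3, m1$day, mean)
  cm <- tapply(nt$volume_mm3, nt$day, mean)
  expect_equal(tab$delta_t_c[tab$model == "M1" & tab$arm == "drugA"],
               (tm[["15"]] - tm[["1"]]) / (cm[["15"]] - cm[["1"]]) * 100)
  expect_error(delta_t_c_table(g, day = 15, control_arm = "placebo"),
               "absent")
  expect_warning(delta_t_c_table(g[g$day < 15 | g$arm != "drugB", ], 15),
                 "skipped")
})
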