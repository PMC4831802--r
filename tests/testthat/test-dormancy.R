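test_that("dormancy is the absence of any EdU-positive cell", {
  cells <- data.frame(cell_id = sprintf("c%d", 1:260),
                      dna_content = runif(260, 1, 2),
                      edu = 0L, ph3 = 0L)
  g <- gonad_sample("w1", "L", assay = "continuous", label_h = 1,
                    cells = cells)
  expect_true(classify_dormant(g))
  cells$edu[17] <- 1L
  g2 <- gonad_sample("w1", "R", assay = "continuous", label_h = 1,
                     cells = cells)
  expect_false(classify_dormant(g2))
  empty <- gonad_sample("w2", "L", assay = "continuous", label_h = 1,
                        cells = cells[0, ])
  expect_error(classify_dormant(empty), "empty")
})

test_that("observed dormant fraction follows the switching model", {
  pre <- builtin_presets()$fog2_day1
  g <- generate_continuous(pre, durations = 1, n_per_duration = 200,
                           seed = 61, cells = TRUE)
  dorm <- mean(vapply(g$samples, classify_dormant, logical(1)))
  expected <- pre$pi_d * exp(-pre$k_da * 1)
  se <- sqrt(expected * (1 - expected) / 200)
  expect_lt(abs(dorm - expected), 3 * se)
})

test_that("expected M-phase count is n * f_m", {
  expect_equal(expected_mphase_count(260, 0.10), 26)
  expect_equal(expected_mphase_count(100, 0), 0)
  expect_equal(expected_mphase_count(50, 0.2), 10)
  expect_error(expected_mphase_count(100, 1.5), "f_m")
})

test_that("labeling curves report unlabeled fractions with binomial CIs", {
  df <- data.frame(label_h = rep(c(1, 4), c(20, 40)),
                   labeled = c(rep(c(0, 1), c(11, 9)), rep(1, 40)))
  curve <- labeling_curve(df)
  expect_equal(curve$fraction_unlabeled, c(0.55, 0))
  expect_equal(curve$n, c(20, 40))
  expect_true(all(curve$ci_low <= curve$fraction_unlabeled &
                    curve$fraction_unlabeled <= curve$ci_high))
  expect_error(labeling_curve(df[0, ]), "no observations")
})

test_that("a slow-switching preset stays partly unlabeled past 6 h", {
  pre <- condition_preset("fog1_like", pi_d = 0.55, k_da = 0.25)
  g <- generate_continuous(pre, durations = c(1, 2, 4, 6, 8),
                           n_per_duration = 120, seed = 62)
  curve <- labeling_curve(g$summary)
  expect_gt(curve$fraction_unlabeled[curve$label_h == 6], 0)
  # decreasing overall trend
  expect_lt(curve$fraction_unlabeled[curve$label_h == 8],
            curve$fraction_unlabeled[curve$label_h == 1])
})

test_that("switching-model boundary cases are flagged", {
  all_lab <- data.frame(label_h = rep(c(1, 2, 4), each = 20), labeled = 1L)
  f1 <- fit_switching(all_lab)
  expect_lte(f1$pi_d, 0.02)
  expect_identical(f1$boundary, "all_labeled")
  none <- data.frame(label_h = rep(c(1, 2, 4), each = 20), labeled = 0L)
  f2 <- fit_switching(none)
  expect_equal(f2$pi_d, 1)
  expect_equal(f2$k_da, 0)
  expect_identical(f2$boundary, "none_labeled")
})

test_that("switching fit recovers generative parameters", {
  pre <- condition_preset("x", pi_d = 0.5, k_da = 0.3)
  g <- generate_continuous(pre, durations = c(1, 2, 4, 6, 8),
                           n_per_duration = 500, seed = 42)
  fit <- fit_switching(g$summary)
  expect_lt(abs(fit$pi_d - 0.5) / 0.5, 0.15)
  expect_lt(abs(fit$k_da - 0.3) / 0.3, 0.15)
  # fitted curve is a valid, non-increasing survival-type function
  tt <- seq(0.1, 10, by = 0.1)
  u <- predict(fit, tt)
  expect_true(all(diff(u) <= 0))
  expect_true(all(u >= 0 & u <= 1))
})

test_that("mitotic index is the PH3-positive fraction", {
  cells <- data.frame(cell_id = sprintf("c%d", 1:260),
                      dna_content = 1.5, edu = 0L,
                      ph3 = rep(c(1L, 0L), c(3, 257)))
  expect_equal(mitotic_index(cells), 3 / 260)
  cells$ph3 <- 0L
  expect_equal(mitotic_index(cells), 0)
  expect_error(mitotic_index(cells[0, ]), "empty")
})

test_that("CV and its bootstrap CI behave on known inputs", {
  r <- cv_with_bootstrap(c(1, 2, 3), reps = 500, seed = 63)
  expect_equal(r$cv, 0.5)
  expect_true(r$ci_low <= r$cv && r$cv <= r$ci_high)
  const <- cv_with_bootstrap(rep(2, 10), reps = 200, seed = 64)
  expect_equal(const$cv, 0)
  expect_equal(c(const$ci_low, const$ci_high), c(0, 0))
  expect_error(cv_with_bootstrap(c(-1, 1)), "zero mean")
  r2 <- cv_with_bootstrap(c(1, 2, 3), reps = 500, seed = 63)
  expect_equal(c(r$ci_low, r$ci_high), c(r2$ci_low, r2$ci_high))
})

test_that("dormancy inflates the mitotic-index CV of a mixture", {
  mi_cohort <- function(p, seed) {
    pre <- condition_preset("m", pi_d = p, k_da = 0.3)
    vapply(generate_pulse_chase(pre, chase_times = 0, n_per_time = 120,
                                seed = seed),
           mitotic_index, numeric(1))
  }
  lo <- mi_cohort(0.05, 65)
  hi <- mi_cohort(0.55, 66)
  cv <- function(x) sd(x) / mean(x)
  expect_gt(cv(hi) / cv(lo), 1)
  d <- cv_diff_bootstrap(hi, lo, reps = 1000, seed = 67)
  expect_gt(d$ci_low, 0)
})

test_that("the Gehan-score test is null on identical groups and extreme on separated ones", {
  a <- interval_obs(c(1, 2, 4, 6), c(1, 1, 0, 0))
  r <- ic_rank_test(a, a, n_perm = 999, seed = 68)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  late <- data.frame(left = 10 + (1:10), right = 20 + (1:10))
  early <- data.frame(left = rep(0, 10), right = 1 + (1:10) / 10)
  r2 <- ic_rank_test(late, early, n_perm = 999, seed = 69)
  expect_equal(r2$statistic, 100)  # |A| * |B|, all pairs strictly ordered
  expect_lte(r2$p_value, 3 / 1000)
})

test_that("the Gehan test agrees with the rank-sum test on point data", {
  set.seed(70)
  for (i in 1:8) {
    shift <- sample(c(0, 3), 1)
    x <- round(rnorm(15, 10, 1), 3)
    y <- round(rnorm(15, 10 + shift, 1), 3)
    a <- data.frame(left = x, right = x + 1e-9)
    b <- data.frame(left = y, right = y + 1e-9)
    p_gehan <- ic_rank_test(a, b, n_perm = 1999)$p_value
    p_wilcox <- stats::wilcox.test(x, y, exact = FALSE)$p.value
    if (p_wilcox < 0.01) expect_lt(p_gehan, 0.05)
    if (p_wilcox > 0.2) expect_gt(p_gehan, 0.05)
  }
})

test_that("Bonferroni adjustment caps at one and scales by m", {
  expect_equal(bonferroni(0.001, m = 15), 0.015)
  expect_equal(bonferroni(0.5, m = 15), 1)
  expect_equal(bonferroni(0, m = 15), 0)
  expect_error(bonferroni(1.5), "p_values")
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "m")
})

test_that("sister-arm agreement and its permutation null", {
  pairs <- cbind(rep(TRUE, 36), c(rep(TRUE, 33), rep(FALSE, 3)))
  r <- sister_arm_agreement(pairs, n_perm = 999, seed = 71)
  expect_equal(r$agreement, 33 / 36)
  expect_equal(round(100 * r$agreement), 92)
  r_all <- sister_arm_agreement(cbind(c(TRUE, FALSE), c(TRUE, FALSE)),
                                n_perm = 999, seed = 72)
  expect_equal(r_all$agreement, 1)
  # independent arms: agreement near 0.5 and mostly non-significant
  pre <- condition_preset("ind", pi_d = 0.5, k_da = 0.3)
  set.seed(73)
  ps <- replicate(30, {
    arms <- generate_sister_arms(pre, n_worms = 60, rho = 0)
    sister_arm_agreement(arms[, c("active_l", "active_r")],
                         n_perm = 999)$p_value
  })
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("Fisher's exact test on dormancy tables", {
  expect_equal(dormancy_proportion_test(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(dormancy_proportion_test(matrix(c(10, 0, 0, 10), 2)),
               2 / choose(20, 10))
  # contrast like 23% vs 46% dormant at n = 100 per group
  expect_lt(dormancy_proportion_test(matrix(c(23, 77, 46, 54), 2)), 0.05)
  expect_error(dormancy_proportion_test(matrix(c(0, 0, 5, 5), 2)), "margin")
})
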