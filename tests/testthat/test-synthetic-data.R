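test_that("built-in presets anchor dormancy and cycle length", {
  pr <- builtin_presets()
  expect_gte(length(pr), 5L)
  expect_lte(pr$wt_day1$pi_d, 0.05)
  expect_equal(pr$wt_day1$cycle$t_c, 5.5)
  expect_equal(pr$fog1_day1$pi_d, 0.55)
  expect_equal(pr$fog2_day1$pi_d, 0.17)
  for (p in pr) {
    expect_s3_class(p, "condition_preset")
    # stationarity ties the switching rates to the dormant fraction
    expect_lt(abs(p$pi_d - p$k_ad / (p$k_ad + p$k_da)), 1e-9)
  }
})

test_that("presets roundtrip through the config format unchanged", {
  for (p in builtin_presets()) {
    path <- withr::local_tempfile(fileext = ".cfg")
    write_preset(p, path)
    expect_equal(read_preset(path), p)
  }
})

test_that("preset constructor rejects inconsistent switching rates", {
  expect_error(condition_preset("bad", pi_d = 0.5, k_da = 0.3, k_ad = 0.1),
               "inconsistent")
  expect_error(condition_preset("bad", pi_d = 1.2, k_da = 0.3), "pi_d")
})

test_that("pulse-chase cohorts are periodic over one full cycle", {
  cp <- cycle_params()
  pre <- condition_preset("act", cycle = cp, pi_d = 0, k_da = 1,
                          noise_cv = 0)
  a <- generate_pulse_chase(pre, chase_times = 0, n_per_time = 5, seed = 101)
  b <- generate_pulse_chase(pre, chase_times = cp$t_c, n_per_time = 5,
                            seed = 101)
  edges <- default_bin_edges()
  for (i in seq_along(a)) {
    ha <- bin_contents(a[[i]]$cells$dna_content, edges)
    hb <- bin_contents(b[[i]]$cells$dna_content, edges)
    expect_equal(ha, hb)
    expect_equal(a[[i]]$cells$edu, b[[i]]$cells$edu)
  }
})

test_that("generators are byte-identical under a repeated seed", {
  pre <- builtin_presets()$fog2_day1
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cell_tables(generate_pulse_chase(pre, c(0, 2), 4, seed = 102), f1)
  write_cell_tables(generate_pulse_chase(pre, c(0, 2), 4, seed = 102), f2)
  expect_identical(readLines(f1), readLines(f2))
  g1 <- generate_continuous(pre, c(1, 4), 20, seed = 103)
  g2 <- generate_continuous(pre, c(1, 4), 20, seed = 103)
  expect_identical(g1, g2)
})

test_that("an always-active preset labels every zone at every duration", {
  pre <- condition_preset("act", pi_d = 0, k_da = 1)
  g <- generate_continuous(pre, durations = c(0.5, 2, 6),
                           n_per_duration = 30, seed = 104)
  expect_true(all(g$summary$labeled == 1))
})

test_that("unlabeled fractions decline with labeling duration", {
  pre <- condition_preset("fog", pi_d = 0.5, k_da = 0.3)
  g <- generate_continuous(pre, durations = c(1, 2, 4, 6, 8),
                           n_per_duration = 500, seed = 105)
  curve <- labeling_curve(g$summary)
  # monotone in expectation; allow one CI-width of sampling wiggle
  slack <- diff(range(curve$ci_high - curve$ci_low)) + 0.03
  expect_true(all(diff(curve$fraction_unlabeled) < slack))
  expect_lt(curve$fraction_unlabeled[5L], curve$fraction_unlabeled[1L])
})

test_that("sister arms interpolate between independence and identity", {
  pre <- condition_preset("s", pi_d = 0.5, k_da = 0.3)
  arms1 <- generate_sister_arms(pre, n_worms = 200, rho = 1, seed = 106)
  expect_equal(mean(arms1$active_l == arms1$active_r), 1)
  arms0 <- generate_sister_arms(pre, n_worms = 2000, rho = 0, seed = 107)
  agree0 <- mean(arms0$active_l == arms0$active_r)
  expect_lt(abs(agree0 - 0.5), 3 * sqrt(0.25 / 2000))
  expect_error(generate_sister_arms(pre, 10, rho = 1.5), "rho")
})

test_that("rho can be calibrated to the observed 92% sister-arm agreement", {
  # fog-1-like marginal activity p = 0.45: agreement(rho) =
  # rho + (1 - rho) * (p^2 + (1-p)^2); solve for 0.92
  pre <- builtin_presets()$fog1_day1
  p <- 1 - pre$pi_d
  base <- p^2 + (1 - p)^2
  rho <- (0.92 - base) / (1 - base)
  arms <- generate_sister_arms(pre, n_worms = 600, rho = rho, seed = 108)
  r <- sister_arm_agreement(arms[, c("active_l", "active_r")],
                            n_perm = 999, seed = 109)
  expect_lt(abs(r$agreement - 0.92), 3 * sqrt(0.92 * 0.08 / 600))
  expect_lt(r$p_value, 0.05)
})

test_that("generated samples satisfy downstream type invariants", {
  pre <- builtin_presets()$wt_day1
  samp <- generate_pulse_chase(pre, chase_times = c(0, 2), n_per_time = 6,
                               seed = 110)
  for (g in samp) {
    expect_s3_class(g, "gonad_sample")
    expect_true(all(g$cells$dna_content >= 1 & g$cells$dna_content <= 2))
    expect_true(all(g$cells$edu %in% 0:1))
    expect_true(all(g$cells$ph3 %in% 0:1))
  }
  cont <- generate_continuous(pre, durations = 1, n_per_duration = 5,
                              seed = 111, cells = TRUE)
  expect_equal(nrow(cont$summary), 5L)
  expect_length(cont$samples, 5L)
})
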