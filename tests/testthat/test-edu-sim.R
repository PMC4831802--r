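test_that("activity schedules validate intervals and accumulate overlap", {
  expect_error(activity_schedule(c(0, 1), c(2, 3), horizon = 4), "disjoint")
  expect_error(activity_schedule(1, 1, horizon = 4), "start < end")
  expect_error(activity_schedule(0, 5, horizon = 4), "within")
  s <- activity_schedule(c(0, 3), c(1, 4), horizon = 6)
  tt <- seq(0, 6, by = 0.25)
  at <- active_time(s, tt)
  expect_true(all(diff(at) >= 0))
  expect_equal(active_time(s, 6), 2)
  expect_equal(active_time(s, 0.5), 0.5)
  expect_equal(active_time(s, 2), 1)
})

test_that("pulse labeling marks exactly the cells traversing S", {
  cp <- cycle_params()
  # all cells parked in G2/M, short pulse: none reaches S
  pop <- zone_population(seq(0.72, 0.9, length.out = 10))
  expect_false(any(pulse_label(pop, 0.2, cp)$edu))
  # instantaneous pulse labels cells in S at that instant
  pop2 <- zone_population(c(0.1, 0.45, 0.75))
  lab <- pulse_label(pop2, 0, cp)
  expect_identical(lab$edu, phase_label(pop2$age, cp) == "S")
  expect_error(pulse_label(pop2, cp$t_c, cp), "single-pass")
})

test_that("pulse-labeled fraction approaches f_s + pulse / t_c", {
  cp <- cycle_params()
  n <- 1e4
  pop <- sample_steady_state(n, cp, seed = 21)
  pulse <- 0.5
  frac <- mean(pulse_label(pop, pulse, cp)$edu)
  expected <- cp$f_s + pulse / cp$t_c
  expect_lt(abs(frac - expected), 3 * sqrt(expected * (1 - expected) / n))
})

test_that("chase advances only by active time", {
  cp <- cycle_params()
  pop <- sample_steady_state(200, cp, seed = 22)
  expect_identical(chase(pop, activity_schedule(horizon = 4), 4, cp)$age,
                   pop$age)
  full <- activity_schedule(0, 4, horizon = 4)
  expect_equal(chase(pop, full, 4, cp)$age, advance(pop, 4, cp)$age)
  half <- activity_schedule(c(0, 2), c(1, 3), horizon = 4)
  expect_equal(chase(pop, half, 4, cp)$age, advance(pop, 2, cp)$age)
  expect_error(chase(pop, full, 3, cp), "exceeds")
})

test_that("continuous labeling requires activity and saturates in one cycle", {
  cp <- cycle_params()
  pop <- sample_steady_state(500, cp, seed = 23)
  # fully dormant: nothing labels
  expect_false(any(continuous_label(pop, activity_schedule(horizon = 6), 6,
                                    cp)$edu))
  # fully active for >= t_c: everything labels
  full <- activity_schedule(0, 6, horizon = 6)
  expect_true(all(continuous_label(pop, full, 6, cp)$edu))
  # short active window: fraction f_s + t / t_c
  n <- 1e4
  big <- sample_steady_state(n, cp, seed = 24)
  t <- 1.5  # < t_c * (1 - f_s)
  frac <- mean(continuous_label(big, activity_schedule(0, t, horizon = t),
                                t, cp)$edu)
  expected <- cp$f_s + t / cp$t_c
  expect_lt(abs(frac - expected), 3 * sqrt(expected * (1 - expected) / n))
})

test_that("labels never shrink under chase or continuous labeling", {
  cp <- cycle_params()
  pop <- pulse_label(sample_steady_state(300, cp, seed = 25), 0.5, cp)
  before <- which(pop$edu)
  sched <- simulate_activity(0.4, 0.4, 6, TRUE, seed = 26)
  after_chase <- chase(pop, sched, 6, cp)
  expect_true(all(after_chase$edu[before]))
  after_cont <- continuous_label(pop, sched, 6, cp)
  expect_true(all(after_cont$edu[before]))
  expect_gte(sum(after_cont$edu), length(before))
})

test_that("an active 260-cell zone labels essentially immediately", {
  # P(no cell in S) = (1 - f_s)^260 ~ 4e-41: every active zone should
  # contain a labeled cell after any positive active window.
  cp <- cycle_params()
  short <- activity_schedule(0, 0.05, horizon = 0.05)
  set.seed(31)
  labeled <- vapply(1:200, function(i) {
    pop <- sample_steady_state(260, cp)
    any(continuous_label(pop, short, 0.05, cp)$edu)
  }, logical(1))
  expect_true(all(labeled))
})

test_that("histogram pairs conserve cells and flag empties", {
  cp <- cycle_params()
  pop <- zone_population(rep(0.1, 50), edu = FALSE)  # all G1
  hp <- make_histogram_pair(pop, params = cp, noise_cv = 0)
  expect_equal(sum(hp$counts_neg), 50)
  expect_equal(sum(hp$counts_pos), 0)
  expect_equal(hp$counts_neg[1L], 50)  # all mass in the bin containing 1.0
  mixed <- pulse_label(sample_steady_state(1234, cp, seed = 27), 0.5, cp)
  hp2 <- make_histogram_pair(mixed, params = cp, noise_cv = 0.06, seed = 28)
  expect_equal(sum(hp2$counts_pos) + sum(hp2$counts_neg), 1234)
  empty <- make_histogram_pair(zone_population(), params = cp)
  expect_true(empty$empty)
  expect_true(is.na(empty$frac_pos))
  expect_equal(sum(empty$counts_pos) + sum(empty$counts_neg), 0)
})

test_that("measured content is unbiased at small noise", {
  cp <- cycle_params()
  n <- 1e4
  pop <- zone_population(rep(0.1, n))  # G1, true content 1.0
  hp <- make_histogram_pair(pop, params = cp, noise_cv = 0.05, seed = 29)
  mids <- (hp$bin_edges[-1] + hp$bin_edges[-length(hp$bin_edges)]) / 2
  m <- sum(mids * hp$counts_neg) / n
  # clamping at 1.0 biases the binned mean upward by about half the lower
  # tail; allow 3 SE around the clamped-normal expectation
  expect_lt(abs(m - 1.02), 3 * 0.05 / sqrt(n) + 0.02)
})

test_that("the template library is anchored at the pulse and periodic", {
  cp <- cycle_params()
  lib <- build_template_library(cp, k = 10, n_sim = 2e4, noise_cv = 0,
                                seed = 30)
  expect_equal(lib$phases, (0:9) / 10)
  # phase 0 equals the freshly pulsed population's histograms
  pop <- sample_steady_state(2e4, cp, seed = 30)
  pop <- pulse_label(pop, 0.5, cp)
  hp0 <- make_histogram_pair(pop, params = cp, noise_cv = 0)
  expect_equal(lib$templates[[1L]]$counts_pos, hp0$counts_pos)
  expect_equal(lib$templates[[1L]]$counts_neg, hp0$counts_neg)
  # advancing the same population a full cycle reproduces phase 0 exactly
  hp1 <- make_histogram_pair(advance(pop, cp$t_c, cp), params = cp,
                             noise_cv = 0)
  expect_equal(hp1$counts_pos, hp0$counts_pos)
  expect_equal(hp1$counts_neg, hp0$counts_neg)
})
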