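# Seeded generators of synthetic experiment tables with the statistical
# structure the downstream analysis assumes.

# Draw a zone size from the preset's truncated normal (>= 1 cell).
draw_zone_size <- function(preset) {
  max(1L, as.integer(round(stats::rnorm(1L, preset$zone_size_mean,
                                        preset$zone_size_sd))))
}

# Is the zone active at the end of its observation window?
active_at <- function(sched, t) {
  nrow(sched) > 0L && any(sched$start < t & sched$end >= t - 1e-9)
}

# Measure one zone: noisy DNA content, EdU misclassification, PH3 emission.
measure_cells <- function(age, labeled, preset, active_end) {
  n <- length(age)
  cp <- preset$cycle
  content <- dna_content(age, cp)
  if (preset$noise_cv > 0)
    content <- content * (1 + stats::rnorm(n, 0, preset$noise_cv))
  content <- pmin(2, pmax(1, content))
  flip <- stats::runif(n)
  edu <- ifelse(labeled, flip > preset$edu_fn, flip < preset$edu_fp)
  in_m <- phase_label(age, cp) == "M"
  ph3 <- in_m & active_end & stats::runif(n) > preset$ph3_miss
  data.frame(cell_id = sprintf("c%04d", seq_len(n)),
             dna_content = content,
             edu = as.integer(edu), ph3 = as.integer(ph3),
             stringsAsFactors = FALSE)
}

#' Generate synthetic pulse-chase cohorts
#'
#' For each chase time and gonad: a zone size is drawn, a steady-state
#' population sampled, a dormant/active switching schedule simulated over
#' pulse + chase, cells labeled if their actively-traversed arc during the
#' pulse intersects S phase (a zone dormant throughout the pulse stays
#' unlabeled), ages advanced by accumulated active time, and measurement
#' noise plus EdU/PH3 misclassification applied. Deterministic given
#' `seed`.
#'
#' @param preset A [condition_preset()].
#' @param chase_times Chase durations in hours.
#' @param n_per_time Gonads per chase time (>= 1).
#' @param seed Optional integer seed.
#' @param density Steady-state age density (see [sample_steady_state()]).
#' @return List of [gonad_sample()] objects.
#' @export
generate_pulse_chase <- function(preset, chase_times = c(0, 2, 4, 6),
                                 n_per_time = 10L, seed = NULL,
                                 density = c("uniform", "exponential")) {
  stopifnot(inherits(preset, "condition_preset"))
  if (n_per_time < 1L) stop_field("n_per_time", "must be >= 1")
  density <- match.arg(density)
  cp <- preset$cycle
  with_seed(seed, {
    out <- list()
    for (chase_h in chase_times) {
      window <- preset$pulse_h + chase_h
      for (w in seq_len(n_per_time)) {
        n_cells <- draw_zone_size(preset)
        pop <- sample_steady_state(n_cells, cp, density = density)
        init_active <- stats::runif(1L) >= preset$pi_d
        sched <- if (window > 0)
          simulate_activity(preset$k_da, preset$k_ad, window, init_active)
        else empty_schedule(1)
        e_pulse <- if (window > 0) active_time(sched, preset$pulse_h) else 0
        labeled <- if (e_pulse > 0)
          arc_hits_s(pop$age, e_pulse / cp$t_c, cp)
        else rep(FALSE, n_cells)
        total_active <- if (window > 0) active_time(sched, window) else 0
        age_final <- (pop$age + total_active / cp$t_c) %% 1
        age_final[age_final >= 1] <- 0
        cells <- measure_cells(age_final, labeled, preset,
                               active_end = window > 0 && active_at(sched, window))
        out[[length(out) + 1L]] <- gonad_sample(
          worm_id = sprintf("%s_t%g_w%03d", preset$name, chase_h, w),
          arm = "L", condition = preset$name, assay = "pulse_chase",
          pulse_h = preset$pulse_h, chase_h = chase_h, cells = cells)
      }
    }
    out
  })
}

#' Generate synthetic continuous-labeling cohorts
#'
#' Per gonad, a switching schedule is simulated over the labeling window;
#' the zone labels at the onset of its first active interval (a ~260-cell
#' active zone contains S-phase cells essentially surely), so the summary
#' records `labeled = 1` iff any active time accrued. Optionally emits full
#' per-cell tables with the same measurement model as
#' [generate_pulse_chase()].
#'
#' @param preset A [condition_preset()].
#' @param durations Labeling durations in hours (non-empty, > 0).
#' @param n_per_duration Gonads per duration.
#' @param seed Optional integer seed.
#' @param cells Also emit per-cell tables? (default `FALSE`).
#' @return List with `summary` (data frame: `worm_id`, `arm`, `condition`,
#'   `label_h`, `labeled`) and `samples` (list of [gonad_sample()] or
#'   `NULL`).
#' @export
generate_continuous <- function(preset, durations = c(1, 2, 4, 6, 8),
                                n_per_duration = 40L, seed = NULL,
                                cells = FALSE) {
  stopifnot(inherits(preset, "condition_preset"))
  if (!length(durations) || any(durations <= 0))
    stop_field("durations", "must be a non-empty vector of positive hours")
  cp <- preset$cycle
  with_seed(seed, {
    rows <- list(); samples <- list()
    for (d in durations) {
      for (w in seq_len(n_per_duration)) {
        init_active <- stats::runif(1L) >= preset$pi_d
        sched <- simulate_activity(preset$k_da, preset$k_ad, d, init_active)
        at <- active_time(sched, d)
        wid <- sprintf("%s_d%g_w%03d", preset$name, d, w)
        rows[[length(rows) + 1L]] <- data.frame(
          worm_id = wid, arm = "L", condition = preset$name,
          label_h = d, labeled = as.integer(at > 0),
          stringsAsFactors = FALSE)
        if (cells) {
          n_cells <- draw_zone_size(preset)
          pop <- sample_steady_state(n_cells, cp)
          labeled_cells <- if (at > 0)
            arc_hits_s(pop$age, at / cp$t_c, cp) else rep(FALSE, n_cells)
          age_final <- (pop$age + at / cp$t_c) %% 1
          age_final[age_final >= 1] <- 0
          tbl <- measure_cells(age_final, labeled_cells, preset,
                               active_end = active_at(sched, d))
          samples[[length(samples) + 1L]] <- gonad_sample(
            worm_id = wid, arm = "L", condition = preset$name,
            assay = "continuous", label_h = d, cells = tbl)
        }
      }
    }
    list(summary = do.call(rbind, rows),
         samples = if (cells) samples else NULL)
  })
}

#' Generate sister-arm activity pairs
#'
#' Per worm, the two gonadal arms share one worm-level state draw with
#' probability `rho` and draw independently otherwise, so both arms keep
#' the marginal activity probability `1 - pi_d` while pairwise agreement
#' increases from independence (`rho = 0`) to identity (`rho = 1`).
#'
#' @param preset A [condition_preset()] (supplies the marginal activity
#'   probability).
#' @param n_worms Number of worms.
#' @param rho Within-worm state correlation in \[0, 1\].
#' @param seed Optional integer seed.
#' @return Data frame with columns `worm_id`, `active_l`, `active_r`.
#' @export
generate_sister_arms <- function(preset, n_worms = 36L, rho = 0.8,
                                 seed = NULL) {
  stopifnot(inherits(preset, "condition_preset"))
  check_prob(rho, "rho")
  p <- 1 - preset$pi_d
  with_seed(seed, {
    shared <- stats::runif(n_worms) < rho
    common <- stats::runif(n_worms) < p
    a <- ifelse(shared, common, stats::runif(n_worms) < p)
    b <- ifelse(shared, common, stats::runif(n_worms) < p)
    data.frame(worm_id = sprintf("%s_w%03d", preset$name, seq_len(n_worms)),
               active_l = a, active_r = b, stringsAsFactors = FALSE)
  })
}
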