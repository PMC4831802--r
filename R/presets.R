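# Condition presets: fully-specified generative models for synthetic
# per-gonad cell tables.

#' Construct a condition preset
#'
#' A preset fully specifies the generative model for one experimental
#' condition: the cell-cycle kinematics, the zone-level dormancy switching
#' process, zone-size distribution, and measurement error rates.
#'
#' @param name Condition label.
#' @param cycle A [cycle_params()] object.
#' @param pi_d Stationary dormant fraction in \[0, 1).
#' @param k_da Dormant-to-active switching rate per hour (> 0 unless
#'   `pi_d = 0`).
#' @param k_ad Active-to-dormant rate; default derived from stationarity,
#'   `k_ad = k_da * pi_d / (1 - pi_d)`. If supplied it must be consistent
#'   with `pi_d` within 1e-6.
#' @param zone_size_mean,zone_size_sd Zone size distribution in cells
#'   (truncated normal; mitotic zones contain ~260 cells).
#' @param noise_cv DNA-content measurement CV (calibration choice, default
#'   0.06).
#' @param edu_fn,edu_fp Per-cell EdU misclassification rates (false
#'   negative / false positive). Defaults are calibration choices keeping
#'   zone-level dormancy classification near-perfect.
#' @param ph3_miss Per-cell probability that an M-phase cell in an active
#'   zone fails to stain PH3+.
#' @param pulse_h Default EdU pulse duration in hours.
#' @return An object of class `condition_preset`.
#' @export
condition_preset <- function(name, cycle = cycle_params(), pi_d, k_da,
                             k_ad = NULL, zone_size_mean = 260,
                             zone_size_sd = 20, noise_cv = 0.06,
                             edu_fn = 0.005, edu_fp = 2e-4,
                             ph3_miss = 0.05, pulse_h = 0.5) {
  stopifnot(inherits(cycle, "cycle_params"))
  check_prob(pi_d, "pi_d", open_right = TRUE)
  check_scalar(k_da, "k_da", lower = 0)
  if (is.null(k_ad)) {
    k_ad <- k_da * pi_d / (1 - pi_d)
  } else {
    check_scalar(k_ad, "k_ad", lower = 0)
    if (k_ad + k_da > 0 && abs(pi_d - k_ad / (k_ad + k_da)) > 1e-6)
      stop_field("k_ad",
                 "inconsistent with pi_d: need pi_d = k_ad / (k_ad + k_da)")
  }
  check_scalar(zone_size_mean, "zone_size_mean", lower = 1)
  check_scalar(zone_size_sd, "zone_size_sd", lower = 0)
  check_scalar(noise_cv, "noise_cv", lower = 0)
  check_prob(edu_fn, "edu_fn"); check_prob(edu_fp, "edu_fp")
  check_prob(ph3_miss, "ph3_miss")
  check_scalar(pulse_h, "pulse_h", lower = 0)
  structure(list(name = as.character(name), cycle = cycle, pi_d = pi_d,
                 k_da = k_da, k_ad = k_ad,
                 zone_size_mean = zone_size_mean,
                 zone_size_sd = zone_size_sd, noise_cv = noise_cv,
                 edu_fn = edu_fn, edu_fp = edu_fp, ph3_miss = ph3_miss,
                 pulse_h = pulse_h),
            class = "condition_preset")
}

#' @export
print.condition_preset <- function(x, ...) {
  cat(sprintf("Condition preset '%s'\n", x$name))
  cat(sprintf("  dormancy: pi_d = %.3f (k_da = %.3g/h, k_ad = %.3g/h)\n",
              x$pi_d, x$k_da, x$k_ad))
  cat(sprintf("  zone size %g +/- %g cells; noise CV %g; EdU fn/fp %g/%g; PH3 miss %g\n",
              x$zone_size_mean, x$zone_size_sd, x$noise_cv, x$edu_fn,
              x$edu_fp, x$ph3_miss))
  print(x$cycle)
  invisible(x)
}

#' Built-in condition presets
#'
#' Named generative presets mirroring the continuous-labeling conditions:
#' reproductively active wild-type day-1 hermaphrodites (low dormancy,
#' ~5.5 h cycle), feminized genotypes with substantial dormancy (fog-1-like
#' 55%, fog-2-like 17%), conditions with sustained oocyte maturation that
#' behave close to wild type (inx-22; fog-2-like and spe-8-like), and aging
#' selfed hermaphrodites at day 3. Dormant fractions anchor to the reported
#' 1-h unlabeled fractions; switching rates, measurement noise and
#' zone-size spread are calibration choices, not measured constants.
#'
#' @return Named list of [condition_preset()] objects.
#' @examples
#' names(builtin_presets())
#' builtin_presets()$fog1_day1
#' @export
builtin_presets <- function() {
  wt_cycle <- cycle_params()  # f_m = 0.10, t_c = 5.5 h
  list(
    wt_day1 = condition_preset("wt_day1", wt_cycle,
                               pi_d = 0.05, k_da = 0.5),
    fog1_day1 = condition_preset("fog1_day1", wt_cycle,
                                 pi_d = 0.55, k_da = 0.25),
    fog2_day1 = condition_preset("fog2_day1", wt_cycle,
                                 pi_d = 0.17, k_da = 0.35),
    inx22_fog2_day1 = condition_preset("inx22_fog2_day1", wt_cycle,
                                       pi_d = 0.08, k_da = 0.45),
    spe8_day1 = condition_preset("spe8_day1", wt_cycle,
                                 pi_d = 0.07, k_da = 0.45),
    wt_day3 = condition_preset("wt_day3", wt_cycle,
                               pi_d = 0.30, k_da = 0.35)
  )
}
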