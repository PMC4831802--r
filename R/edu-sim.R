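# EdU labeling simulation: pulse, chase, continuous labeling, and the
# template library of DNA-content histogram pairs.

# Does the closed arc [age, age + arc_len] on the unit circle intersect the
# S-phase interval [s1, s2)?  Vectorized over age. Labeling requires active
# traversal, so callers pass arc_len = 0 only for an instantaneous pulse.
arc_hits_s <- function(age, arc_len, params) {
  s1 <- params$f_g1
  s2 <- params$f_g1 + params$f_s
  if (arc_len >= 1) return(rep(TRUE, length(age)))
  e <- age + arc_len
  (age < s2 & e >= s1) | (age < s2 + 1 & e >= s1 + 1)
}

#' Apply an EdU pulse to a population
#'
#' EdU is incorporated by cells in S phase. A cell becomes labeled if any
#' part of its trajectory over the pulse window lies in S; ages advance by
#' `pulse_duration / t_c`. A zero-length pulse labels exactly the cells in S
#' at that instant. Labels, once set, are never removed (label presence is
#' tracked, not intensity).
#'
#' @param population A [zone_population()].
#' @param pulse_duration Pulse length in hours; must be `< t_c` (the model
#'   assumes at most a single S-phase entry during the pulse).
#' @param params A [cycle_params()] object.
#' @return The pulsed [zone_population()].
#' @export
pulse_label <- function(population, pulse_duration, params = cycle_params()) {
  stopifnot(inherits(population, "zone_population"))
  check_scalar(pulse_duration, "pulse_duration", lower = 0)
  if (pulse_duration >= params$t_c)
    stop_field("pulse_duration",
               "must be shorter than the cycle length t_c (single-pass assumption)")
  arc <- pulse_duration / params$t_c
  population$edu <- population$edu | arc_hits_s(population$age, arc, params)
  advance(population, pulse_duration, params)
}

check_schedule_window <- function(schedule, t) {
  stopifnot(inherits(schedule, "activity_schedule"))
  check_scalar(t, "t", lower = 0)
  if (nrow(schedule) && max(schedule$end) > t + 1e-9)
    stop("activity schedule exceeds the window [0, t]", call. = FALSE)
  invisible(schedule)
}

#' Chase a pulsed population under an activity schedule
#'
#' During the chase cells progress only while the zone is active: ages
#' advance by `active_time(schedule, t) / t_c` and labels are unchanged. A
#' fully active schedule reduces to [advance()]; an empty schedule (fully
#' dormant) freezes the population.
#'
#' @param population A [zone_population()].
#' @param schedule An [activity_schedule()] contained in `[0, t]`.
#' @param t Chase duration in hours (>= 0).
#' @param params A [cycle_params()] object.
#' @return The chased [zone_population()].
#' @export
chase <- function(population, schedule, t, params = cycle_params()) {
  stopifnot(inherits(population, "zone_population"))
  check_schedule_window(schedule, t)
  advance(population, active_time(schedule, t), params)
}

#' Continuous EdU labeling under an activity schedule
#'
#' Label is present throughout `[0, t]` but cells traverse the cycle only
#' while the zone is active; a cell is labeled iff its actively-traversed
#' arc intersects S. A fully dormant schedule labels nothing; a fully active
#' window of at least one cycle labels every cell.
#'
#' @inheritParams chase
#' @return The labeled, advanced [zone_population()].
#' @export
continuous_label <- function(population, schedule, t,
                             params = cycle_params()) {
  stopifnot(inherits(population, "zone_population"))
  check_schedule_window(schedule, t)
  at <- active_time(schedule, t)
  if (at > 0) {
    arc <- at / params$t_c
    population$edu <- population$edu |
      arc_hits_s(population$age, arc, params)
  }
  advance(population, at, params)
}

#' Construct a DNA-content histogram pair
#'
#' Binned DNA-content histograms of the EdU+ and EdU- cells of one zone (or
#' one simulated template). Bins span the relative content axis \[1, 2\] and
#' are interpreted circularly: division returns content from 2n to 1n, so
#' the last bin is adjacent to the first.
#'
#' @param counts_pos,counts_neg Non-negative counts per bin for EdU+ and
#'   EdU- cells.
#' @param bin_edges `B + 1` increasing edges spanning \[1, 2\].
#' @return An object of class `histogram_pair` with fields `bin_edges`,
#'   `counts_pos`, `counts_neg` and `frac_pos` (EdU+ fraction of all cells;
#'   `NA` for an empty pair, flagged via the `empty` field).
#' @export
histogram_pair <- function(counts_pos, counts_neg,
                           bin_edges = default_bin_edges()) {
  b <- length(bin_edges) - 1L
  if (b < 1L || any(diff(bin_edges) <= 0))
    stop_field("bin_edges", "must be increasing with at least 2 values")
  if (abs(bin_edges[1L] - 1) > 1e-9 || abs(bin_edges[b + 1L] - 2) > 1e-9)
    stop_field("bin_edges", "must span [1, 2]")
  if (length(counts_pos) != b || length(counts_neg) != b)
    stop("counts must have one value per bin", call. = FALSE)
  if (any(counts_pos < 0) || any(counts_neg < 0))
    stop("counts must be non-negative", call. = FALSE)
  tot <- sum(counts_pos) + sum(counts_neg)
  structure(list(bin_edges = as.numeric(bin_edges),
                 counts_pos = as.numeric(counts_pos),
                 counts_neg = as.numeric(counts_neg),
                 frac_pos = if (tot > 0) sum(counts_pos) / tot else NA_real_,
                 empty = tot == 0),
            class = "histogram_pair")
}

#' @export
print.histogram_pair <- function(x, ...) {
  cat(sprintf("Histogram pair: %d circular bins on [1, 2], %g cells (EdU+ fraction %s)\n",
              length(x$counts_pos), sum(x$counts_pos) + sum(x$counts_neg),
              if (is.na(x$frac_pos)) "undefined" else sprintf("%.3f", x$frac_pos)))
  invisible(x)
}

#' Default circular DNA-content bins
#'
#' 32 equal-width bins on the relative content axis \[1, 2\].
#' @param b Number of bins.
#' @return Numeric vector of `b + 1` edges.
#' @export
default_bin_edges <- function(b = 32L) seq(1, 2, length.out = b + 1L)

#' Bin measured DNA contents into circular bins
#'
#' Counts values (already normalized onto \[1, 2\]) into the `B` bins
#' defined by `bin_edges`; content exactly 2 falls in the last bin.
#'
#' @param x Numeric vector of relative DNA contents.
#' @param bin_edges `B + 1` increasing edges.
#' @return Integer vector of `B` counts.
#' @export
bin_contents <- function(x, bin_edges) {
  b <- length(bin_edges) - 1L
  idx <- findInterval(pmin(pmax(x, bin_edges[1L]), bin_edges[b + 1L]),
                      bin_edges, rightmost.closed = TRUE)
  tabulate(idx, nbins = b)
}

#' Measure a population into a histogram pair
#'
#' Per-cell measured content is `dna_content(age) * (1 + N(0, noise_cv))`,
#' clamped to \[1, 2\] (multiplicative measurement noise mimicking DNA-stain
#' quantification error), then binned separately by EdU status.
#'
#' @param population A [zone_population()]; an empty population yields a
#'   zero histogram flagged `empty`, not an error.
#' @param bin_edges Bin edges spanning \[1, 2\] (see [default_bin_edges()]).
#' @param params A [cycle_params()] object.
#' @param noise_cv Coefficient of variation of measurement noise (>= 0).
#' @param seed Optional integer seed; deterministic given it.
#' @return A [histogram_pair()].
#' @export
make_histogram_pair <- function(population, bin_edges = default_bin_edges(),
                                params = cycle_params(), noise_cv = 0,
                                seed = NULL) {
  stopifnot(inherits(population, "zone_population"))
  check_scalar(noise_cv, "noise_cv", lower = 0)
  n <- nrow(population)
  with_seed(seed, {
    content <- dna_content(population$age, params)
    if (noise_cv > 0 && n > 0)
      content <- content * (1 + stats::rnorm(n, 0, noise_cv))
    content <- pmin(2, pmax(1, content))
    histogram_pair(bin_contents(content[population$edu], bin_edges),
                   bin_contents(content[!population$edu], bin_edges),
                   bin_edges)
  })
}

#' Build the template library of pulse-chase histogram pairs
#'
#' Simulates one large pulse-labeled steady-state population and records its
#' DNA-content histogram pair after advancing by phase `j / k` of a cycle,
#' for `j = 0, ..., k - 1`. Phase 0 corresponds to the moment the pulse
#' ends; phase 1 would reproduce phase 0 (all cells having undergone a full
#' cycle). These templates are the matching targets for observed zones.
#'
#' @param params A [cycle_params()] object.
#' @param k Number of evenly spaced templates (default 20).
#' @param pulse_duration EdU pulse length in hours (default 0.5).
#' @param n_sim Simulated cells per template (default 1e5).
#' @param bin_edges Bin edges (see [default_bin_edges()]).
#' @param noise_cv Measurement noise applied to templates; defaults to the
#'   generator default so templates and observations are comparable. Set to
#'   0 for exact, noiseless templates.
#' @param seed Optional integer seed.
#' @param density Steady-state age density (see [sample_steady_state()]).
#' @return An object of class `template_library`.
#' @export
build_template_library <- function(params = cycle_params(), k = 20L,
                                   pulse_duration = 0.5, n_sim = 1e5,
                                   bin_edges = default_bin_edges(),
                                   noise_cv = 0.06, seed = NULL,
                                   density = c("uniform", "exponential")) {
  if (!is.numeric(k) || length(k) != 1L || k < 2L)
    stop_field("k", "must be an integer >= 2")
  k <- as.integer(k)
  density <- match.arg(density)
  with_seed(seed, {
    pop <- sample_steady_state(n_sim, params, density = density)
    pop <- pulse_label(pop, pulse_duration, params)
    phases <- (seq_len(k) - 1L) / k
    templates <- lapply(phases, function(ph) {
      make_histogram_pair(advance(pop, ph * params$t_c, params),
                          bin_edges, params, noise_cv)
    })
    structure(list(params = params, k = k, phases = phases,
                   templates = templates, pulse_duration = pulse_duration,
                   n_sim = as.integer(n_sim), bin_edges = bin_edges,
                   noise_cv = noise_cv),
              class = "template_library")
  })
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("Template library: k = %d phases, pulse %g h, %d cells/template, %d bins, noise CV %g\n",
              x$k, x$pulse_duration, x$n_sim,
              length(x$bin_edges) - 1L, x$noise_cv))
  print(x$params)
  invisible(x)
}
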