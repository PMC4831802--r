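#' Activity schedule of a mitotic zone
#'
#' Zones switch between an actively-cycling state and a dormant state in
#' which no cell progresses through the cycle. An activity schedule records
#' the active intervals within an observation window `[0, horizon]`:
#' disjoint, sorted `(start, end)` pairs with `start < end`.
#'
#' @param start,end Numeric vectors of interval endpoints in hours.
#' @param horizon Length of the observation window in hours (> 0, and at
#'   least `max(end)`).
#' @return An object of class `activity_schedule`: a data frame with columns
#'   `start` and `end` and a `horizon` attribute.
#' @examples
#' sched <- activity_schedule(c(0, 3), c(1, 4), horizon = 6)
#' active_time(sched, 6)  # 2 h of activity in the window
#' @export
activity_schedule <- function(start = numeric(), end = numeric(), horizon) {
  if (length(start) != length(end))
    stop("`start` and `end` must have equal length", call. = FALSE)
  check_scalar(horizon, "horizon", lower = 0, strict = TRUE)
  if (length(start)) {
    o <- order(start)
    start <- start[o]; end <- end[o]
    if (any(start < 0) || any(end > horizon + 1e-9))
      stop("intervals must lie within [0, horizon]", call. = FALSE)
    if (any(end <= start))
      stop("intervals must satisfy start < end", call. = FALSE)
    if (length(start) > 1L && any(start[-1] < end[-length(end)]))
      stop("intervals must be disjoint", call. = FALSE)
  }
  structure(data.frame(start = as.numeric(start), end = as.numeric(end)),
            horizon = horizon,
            class = c("activity_schedule", "data.frame"))
}

#' @export
print.activity_schedule <- function(x, ...) {
  h <- attr(x, "horizon")
  cat(sprintf("Activity schedule: %d active interval(s) in [0, %g] h (%.2f h active)\n",
              nrow(x), h, active_time(x, h)))
  invisible(x)
}

#' Cumulative active time under a schedule
#'
#' Total overlap of the schedule's active intervals with `[0, t]`;
#' non-decreasing in `t`.
#'
#' @param schedule An [activity_schedule()].
#' @param t Time(s) in hours (vectorized).
#' @return Active hours accumulated by each `t`.
#' @export
active_time <- function(schedule, t) {
  stopifnot(inherits(schedule, "activity_schedule"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("`t` must be finite and >= 0", call. = FALSE)
  if (!nrow(schedule)) return(numeric(length(t)))
  vapply(t, function(ti) {
    sum(pmax(0, pmin(schedule$end, ti) - schedule$start))
  }, numeric(1))
}

#' Simulate two-state dormant/active switching
#'
#' Draws one realization of the zone-level switching process: a two-state
#' continuous-time Markov chain with exponential dwell times (mean `1/k_da`
#' in the dormant state, `1/k_ad` in the active state), truncated at the
#' horizon. A rate of 0 makes the corresponding state absorbing.
#'
#' @param k_da Dormant-to-active switching rate, per hour (>= 0).
#' @param k_ad Active-to-dormant switching rate, per hour (>= 0).
#' @param horizon Observation window length in hours (> 0).
#' @param initial_active Logical: does the zone start in the active state?
#' @param seed Optional integer seed.
#' @return An [activity_schedule()] of the active intervals.
#' @export
simulate_activity <- function(k_da, k_ad, horizon, initial_active,
                              seed = NULL) {
  check_scalar(k_da, "k_da", lower = 0)
  check_scalar(k_ad, "k_ad", lower = 0)
  check_scalar(horizon, "horizon", lower = 0, strict = TRUE)
  stopifnot(is.logical(initial_active), length(initial_active) == 1L)
  with_seed(seed, {
    t <- 0
    active <- initial_active
    starts <- numeric(); ends <- numeric()
    while (t < horizon) {
      rate <- if (active) k_ad else k_da
      dwell <- if (rate > 0) stats::rexp(1L, rate) else Inf
      t_next <- min(horizon, t + dwell)
      if (active && t_next > t) {
        starts <- c(starts, t)
        ends <- c(ends, t_next)
      }
      t <- t_next
      active <- !active
    }
    activity_schedule(starts, ends, horizon = horizon)
  })
}

# Fully active / fully dormant convenience schedules.
full_schedule <- function(horizon) activity_schedule(0, horizon, horizon = horizon)
empty_schedule <- function(horizon) activity_schedule(horizon = horizon)
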