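# Bet-hedging capacity simulation: populations of individuals whose gonads
# switch between dormant and active states, with reproductive capacity
# depleted linearly while active.

#' Capacity-depletion simulation parameters
#'
#' @param n Number of individuals (>= 2).
#' @param c0_mean Mean initial reproductive capacity, arbitrary capacity
#'   units (> 0).
#' @param cv0 CV of initial capacity (>= 0); default 0.12, the day-0 brood
#'   size CV.
#' @param r Depletion rate, capacity units per active hour (>= 0).
#' @param k_da Dormant-to-active switching rate per hour (>= 0).
#' @param k_ad Active-to-dormant switching rate per hour (>= 0).
#' @param p_active0 Initial probability of being active; default is the
#'   stationary probability `k_da / (k_da + k_ad)` (0.5 when both rates are
#'   zero).
#' @param horizon Simulated time span in hours (> 0); default 48 (two
#'   days).
#' @param seed Optional integer seed.
#' @return An object of class `capacity_params`.
#' @export
capacity_params <- function(n = 2000L, c0_mean = 100, cv0 = 0.12, r = 1,
                            k_da = 0.1, k_ad = 0.1, p_active0 = NULL,
                            horizon = 48, seed = NULL) {
  check_scalar(n, "n", lower = 2)
  check_scalar(c0_mean, "c0_mean", lower = 0, strict = TRUE)
  check_scalar(cv0, "cv0", lower = 0)
  check_scalar(r, "r", lower = 0)
  check_scalar(k_da, "k_da", lower = 0)
  check_scalar(k_ad, "k_ad", lower = 0)
  check_scalar(horizon, "horizon", lower = 0, strict = TRUE)
  if (is.null(p_active0)) {
    p_active0 <- if (k_da + k_ad > 0) k_da / (k_da + k_ad) else 0.5
  }
  check_prob(p_active0, "p_active0")
  structure(list(n = as.integer(n), c0_mean = c0_mean, cv0 = cv0, r = r,
                 k_da = k_da, k_ad = k_ad, p_active0 = p_active0,
                 horizon = horizon, seed = seed),
            class = "capacity_params")
}

# Vectorized two-state CTMC: active hours accumulated by each time point,
# for n independent chains. Same dwell model as simulate_activity().
sim_active_hours <- function(n, k_da, k_ad, horizon, p_active0, times) {
  t_cur <- numeric(n)
  active <- stats::runif(n) < p_active0
  acc <- matrix(0, n, length(times))
  tmax <- max(times)
  if (tmax <= 0) return(acc)
  alive <- rep(TRUE, n)
  while (any(alive)) {
    rate <- ifelse(active, k_ad, k_da)
    dwell <- rep(Inf, n)
    pos <- rate > 0 & alive
    if (any(pos)) dwell[pos] <- stats::rexp(sum(pos), rate[pos])
    t_end <- pmin(t_cur + dwell, tmax)
    idx <- which(active & alive & t_end > t_cur)
    if (length(idx)) {
      for (j in seq_along(times)) {
        acc[idx, j] <- acc[idx, j] +
          pmax(0, pmin(times[j], t_end[idx]) - t_cur[idx])
      }
    }
    t_cur <- t_end
    active <- !active
    alive <- t_cur < tmax
  }
  acc
}

# Initial capacities: normal truncated at 0 by rejection; flags heavy
# truncation (> 5% of mass below 0) since that distorts the nominal CV.
draw_capacities <- function(n, c0_mean, cv0) {
  sd0 <- cv0 * c0_mean
  flag <- stats::pnorm(0, c0_mean, sd0) > 0.05
  if (flag)
    warning("cv0 truncates > 5% of initial capacities at 0", call. = FALSE)
  x <- stats::rnorm(n, c0_mean, sd0)
  while (any(x < 0)) x[x < 0] <- stats::rnorm(sum(x < 0), c0_mean, sd0)
  structure(x, truncated = flag)
}

#' Simulate a capacity-depleting population
#'
#' Each individual starts with capacity drawn from a normal distribution
#' (mean `c0_mean`, CV `cv0`, truncated at 0) and switches between dormant
#' and active states as a two-state continuous-time Markov chain; capacity
#' depletes linearly at rate `r` per active hour and floors at 0:
#' `C_i(t) = max(0, C_i(0) - r * active_time_i(t))`. Stochastic switching
#' makes total active time heterogeneous across individuals, spreading the
#' population's remaining capacity — the mechanism behind the age-dependent
#' increase in brood-size CV.
#'
#' @param params A [capacity_params()] object.
#' @param times Evaluation times in hours (default 25 points spanning
#'   `[0, horizon]`).
#' @return An object of class `capacity_trajectory`: `times`, the `n x T`
#'   matrix `capacities`, `cv_series`, and the `truncated` flag.
#' @export
simulate_population <- function(params, times = NULL) {
  stopifnot(inherits(params, "capacity_params"))
  if (is.null(times)) times <- seq(0, params$horizon, length.out = 25L)
  if (any(times < 0) || any(times > params$horizon + 1e-9))
    stop("`times` must lie in [0, horizon]", call. = FALSE)
  with_seed(params$seed, {
    c0 <- draw_capacities(params$n, params$c0_mean, params$cv0)
    act <- sim_active_hours(params$n, params$k_da, params$k_ad,
                            params$horizon, params$p_active0, times)
    cap <- matrix(c0, params$n, length(times)) - params$r * act
    cap[cap < 0] <- 0
    structure(list(times = times, capacities = cap,
                   cv_series = apply(cap, 2L, stats::sd) / colMeans(cap),
                   truncated = isTRUE(attr(c0, "truncated")),
                   params = params),
              class = "capacity_trajectory")
  })
}

#' @export
print.capacity_trajectory <- function(x, ...) {
  cv0 <- x$cv_series[1L]
  cvT <- x$cv_series[length(x$cv_series)]
  cat(sprintf("Capacity trajectory: n = %d, %d time points over [0, %g] h\n",
              nrow(x$capacities), length(x$times), max(x$times)))
  cat(sprintf("  CV: %.3f at t = 0  ->  %.3f at horizon (%.2f-fold)\n",
              cv0, cvT, cvT / cv0))
  invisible(x)
}

#' @export
plot.capacity_trajectory <- function(x, ...) {
  graphics::plot(x$times, x$cv_series, type = "b", pch = 19,
                 xlab = "time (h)", ylab = "CV of remaining capacity", ...)
  invisible(x)
}

#' Scan switching and depletion parameters for CV amplification
#'
#' Simulates [simulate_population()] over a grid of switching rates and
#' depletion rates and reports, per grid point, the mean capacity loss
#' fraction and the fold-change `CV(horizon) / CV(0)` (against the realized
#' CV at t = 0). Several seeds per grid point are averaged. The `best`
#' attribute holds the row with the largest CV ratio, optionally restricted
#' to a mean-loss band.
#'
#' @param base A [capacity_params()] object supplying `n`, `c0_mean`,
#'   `cv0`, `horizon` and the master `seed`.
#' @param k_da,k_ad Vectors of switching rates (per hour) to scan.
#' @param r Vector of depletion rates (capacity units per active hour).
#' @param loss_band Optional `c(lo, hi)` restricting the argmax to grid
#'   points whose mean loss fraction lies in the band.
#' @param n_seeds Seeds averaged per grid point (default 1).
#' @return A data frame (class `cv_scan`) with columns `k_da`, `k_ad`, `r`,
#'   `mean_loss_fraction`, `cv_ratio`, and attribute `best`.
#' @export
scan_cv_ratio <- function(base, k_da, k_ad, r, loss_band = NULL,
                          n_seeds = 1L) {
  stopifnot(inherits(base, "capacity_params"))
  if (!length(k_da) || !length(k_ad) || !length(r))
    stop("the scan grid must be non-empty", call. = FALSE)
  combos <- expand.grid(k_da = k_da, k_ad = k_ad)
  rows <- vector("list", nrow(combos) * length(r))
  with_seed(base$seed, {
    for (ci in seq_len(nrow(combos))) {
      kd <- combos$k_da[ci]; ka <- combos$k_ad[ci]
      p0 <- if (kd + ka > 0) kd / (kd + ka) else 0.5
      ratio <- matrix(NA_real_, n_seeds, length(r))
      loss <- matrix(NA_real_, n_seeds, length(r))
      for (srep in seq_len(n_seeds)) {
        c0 <- draw_capacities(base$n, base$c0_mean, base$cv0)
        act <- sim_active_hours(base$n, kd, ka, base$horizon, p0,
                                base$horizon)[, 1L]
        cv0_real <- stats::sd(c0) / mean(c0)
        for (ri in seq_along(r)) {
          cap <- pmax(0, c0 - r[ri] * act)
          ratio[srep, ri] <- (stats::sd(cap) / mean(cap)) / cv0_real
          loss[srep, ri] <- 1 - mean(cap) / mean(c0)
        }
      }
      for (ri in seq_along(r)) {
        rows[[(ci - 1L) * length(r) + ri]] <-
          data.frame(k_da = kd, k_ad = ka, r = r[ri],
                     mean_loss_fraction = mean(loss[, ri]),
                     cv_ratio = mean(ratio[, ri]))
      }
    }
  })
  out <- do.call(rbind, rows)
  eligible <- if (is.null(loss_band)) rep(TRUE, nrow(out)) else
    out$mean_loss_fraction >= loss_band[1L] &
    out$mean_loss_fraction <= loss_band[2L]
  best <- if (any(eligible)) {
    out[eligible, ][which.max(out$cv_ratio[eligible]), ]
  } else {
    out[0L, ]
  }
  structure(out, best = best, loss_band = loss_band,
            class = c("cv_scan", "data.frame"))
}

#' @export
print.cv_scan <- function(x, ...) {
  cat(sprintf("Capacity CV scan: %d grid points\n", nrow(x)))
  best <- attr(x, "best")
  if (nrow(best)) {
    band <- attr(x, "loss_band")
    cat(sprintf("  max CV ratio%s: %.2f-fold at k_da = %g/h, k_ad = %g/h, r = %g (mean loss %.0f%%)\n",
                if (is.null(band)) "" else
                  sprintf(" (loss in [%g, %g])", band[1L], band[2L]),
                best$cv_ratio, best$k_da, best$k_ad, best$r,
                100 * best$mean_loss_fraction))
  }
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}
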