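# Dormancy analysis: zone-level classification, continuous-labeling curves,
# two-state switching fits, dispersion statistics and rank tests.

cells_of <- function(g) {
  if (inherits(g, "gonad_sample")) g$cells else as.data.frame(g)
}

#' Classify a zone as dormant
#'
#' Dormant mitotic zones are defined by the absence of any EdU-positive
#' cell after labeling.
#'
#' @param g A [gonad_sample()] (or a cells data frame with an `edu` column)
#'   containing at least one cell.
#' @return `TRUE` iff no cell is EdU-positive.
#' @export
classify_dormant <- function(g) {
  cells <- cells_of(g)
  if (!nrow(cells))
    stop("cannot classify an empty cell table", call. = FALSE)
  !any(cells$edu == 1)
}

#' Expected number of M-phase cells
#'
#' If a zone of `n` cells were cycling with M phase occupying fraction
#' `f_m` of the cycle, one would expect `n * f_m` cells in M phase at any
#' instant — e.g. 26 of 260 cells at `f_m = 0.10`. Zones lacking S-phase
#' labeling but containing far fewer M-phase cells are therefore dormant as
#' a whole, not merely caught outside S.
#'
#' @param n Zone size in cells (>= 0).
#' @param f_m M-phase fraction of the cycle, in \[0, 1\].
#' @return Expected M-phase cell count `n * f_m`.
#' @export
expected_mphase_count <- function(n, f_m) {
  check_scalar(n, "n", lower = 0)
  check_prob(f_m, "f_m")
  n * f_m
}

#' Continuous-labeling curve
#'
#' Fraction of zones remaining unlabeled as a function of time on labeled
#' food, with exact two-sided binomial confidence intervals (83% by default,
#' the error-bar convention whereby non-overlapping intervals correspond
#' roughly to a 5% pairwise test).
#'
#' @param data Data frame with columns `label_h` (assay duration, hours)
#'   and `labeled` (0/1 zone status).
#' @param level Confidence level (default 0.83).
#' @return Data frame with one row per duration: `label_h`, `n`,
#'   `n_unlabeled`, `fraction_unlabeled`, `ci_low`, `ci_high`.
#' @export
labeling_curve <- function(data, level = 0.83) {
  stopifnot(is.data.frame(data),
            all(c("label_h", "labeled") %in% names(data)))
  if (!nrow(data)) stop("no observations", call. = FALSE)
  check_prob(level, "level", open_left = TRUE, open_right = TRUE)
  durations <- sort(unique(data$label_h))
  rows <- lapply(durations, function(d) {
    y <- data$labeled[data$label_h == d]
    if (!length(y))
      stop(sprintf("empty group at duration %g h", d), call. = FALSE)
    x <- sum(y == 0)
    ci <- stats::binom.test(x, length(y), conf.level = level)$conf.int
    data.frame(label_h = d, n = length(y), n_unlabeled = x,
               fraction_unlabeled = x / length(y),
               ci_low = ci[1L], ci_high = ci[2L])
  })
  do.call(rbind, rows)
}

#' Interval-censored first-labeling observations
#'
#' A continuous-labeling assay at duration `t` observes the zone's
#' first-labeling time only up to an interval: `(0, t]` if labeled,
#' `(t, Inf)` if not.
#'
#' @param label_h Assay durations in hours.
#' @param labeled 0/1 (or logical) zone status at each duration.
#' @return Data frame with columns `left` and `right` (`Inf` allowed).
#' @export
interval_obs <- function(label_h, labeled) {
  stopifnot(length(label_h) == length(labeled))
  if (any(label_h <= 0)) stop_field("label_h", "must be > 0")
  labeled <- as.logical(labeled)
  data.frame(left = ifelse(labeled, 0, label_h),
             right = ifelse(labeled, label_h, Inf))
}

#' Fit the two-state dormancy switching model
#'
#' Under stochastic switching between dormant and active states, a zone
#' remains unlabeled at continuous-labeling duration `t` only if it started
#' dormant and has not yet switched: `U(t) = pi_d * exp(-k_da * t)`, where
#' `pi_d` is the stationary dormant fraction and `k_da` the
#' dormant-to-active rate per hour. (Once active, a ~260-cell zone labels
#' essentially immediately, so zone first-label time is the onset of the
#' first active interval.) The fit maximizes the Bernoulli likelihood of
#' the labeled/unlabeled outcomes at each assay duration.
#'
#' @param data Data frame with columns `label_h` and `labeled` (0/1), or
#'   `left`/`right` intervals as produced by [interval_obs()].
#' @return An object of class `switching_fit`: `pi_d`, `k_da`, `objective`
#'   (negative log-likelihood), `n`, `boundary` (`NULL`, `"all_labeled"` or
#'   `"none_labeled"`), and the per-duration summary `table`.
#' @seealso [predict.switching_fit()] for the fitted unlabeled-fraction
#'   curve.
#' @export
fit_switching <- function(data) {
  stopifnot(is.data.frame(data))
  if (all(c("left", "right") %in% names(data))) {
    labeled <- is.finite(data$right)
    t_obs <- ifelse(labeled, data$right, data$left)
  } else if (all(c("label_h", "labeled") %in% names(data))) {
    labeled <- as.logical(data$labeled)
    t_obs <- data$label_h
  } else {
    stop("`data` needs columns label_h/labeled or left/right", call. = FALSE)
  }
  if (any(t_obs <= 0)) stop_field("label_h", "must be > 0")
  n <- length(t_obs)
  tab <- do.call(rbind, lapply(sort(unique(t_obs)), function(d) {
    data.frame(label_h = d, n = sum(t_obs == d),
               n_unlabeled = sum(!labeled[t_obs == d]))
  }))
  if (length(unique(t_obs)) < 2L && length(unique(t_obs[labeled])) < 2L)
    stop("need >= 2 distinct durations (or >= 2 labeled endpoints) to fit",
         call. = FALSE)
  mk <- function(pi_d, k_da, objective, boundary = NULL) {
    structure(list(pi_d = pi_d, k_da = k_da, objective = objective, n = n,
                   boundary = boundary, table = tab),
              class = "switching_fit")
  }
  nll <- function(theta) {
    u <- stats::plogis(theta[1L]) * exp(-exp(theta[2L]) * t_obs)
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
    -sum(ifelse(labeled, log(1 - u), log(u)))
  }
  if (all(labeled)) return(mk(0, NA_real_, 0, boundary = "all_labeled"))
  if (!any(labeled)) return(mk(1, 0, 0, boundary = "none_labeled"))
  starts <- expand.grid(p = stats::qlogis(c(0.2, 0.5, 0.8)),
                        lk = log(c(0.05, 0.3, 1)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    op <- stats::optim(c(starts$p[i], starts$lk[i]), nll,
                       method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || op$value < best$value) best <- op
  }
  mk(stats::plogis(best$par[1L]), exp(best$par[2L]), best$value)
}

#' @export
print.switching_fit <- function(x, ...) {
  cat("Two-state dormancy switching fit: U(t) = pi_d * exp(-k_da * t)\n")
  cat(sprintf("  pi_d (stationary dormant fraction): %.4f\n", x$pi_d))
  cat(sprintf("  k_da (dormant->active rate, /h):    %s\n",
              if (is.na(x$k_da)) "indeterminate" else sprintf("%.4f", x$k_da)))
  cat(sprintf("  -logLik %.3f on %d zones\n", x$objective, x$n))
  if (!is.null(x$boundary))
    cat(sprintf("  boundary fit: %s\n", x$boundary))
  invisible(x)
}

#' @export
coef.switching_fit <- function(object, ...) {
  c(pi_d = object$pi_d, k_da = object$k_da)
}

#' @export
logLik.switching_fit <- function(object, ...) {
  structure(-object$objective, df = 2L, nobs = object$n, class = "logLik")
}

#' Predicted unlabeled fraction under a switching fit
#'
#' @param object A [fit_switching()] result.
#' @param t Durations in hours.
#' @param ... Unused.
#' @return `U(t) = pi_d * exp(-k_da * t)`.
#' @export
predict.switching_fit <- function(object, t, ...) {
  k <- if (is.na(object$k_da)) 0 else object$k_da
  object$pi_d * exp(-k * t)
}

#' @export
summary.switching_fit <- function(object, ...) {
  object$table$fraction_unlabeled <- object$table$n_unlabeled / object$table$n
  object$table$fitted <- predict(object, object$table$label_h)
  object
}

#' Mitotic index of a zone
#'
#' Fraction of cells positive for phospho-histone H3 (M-phase marker).
#'
#' @param g A [gonad_sample()] or cells data frame with a `ph3` column;
#'   at least one cell.
#' @return `count(ph3+) / count(cells)`.
#' @export
mitotic_index <- function(g) {
  cells <- cells_of(g)
  if (!nrow(cells)) stop("empty cell table", call. = FALSE)
  mean(cells$ph3 == 1)
}

#' Coefficient of variation with a bootstrap confidence interval
#'
#' The CV — standard deviation over mean — is a unit-free dispersion
#' measure; a mixture of dormant (index ~0) and active zones inflates the
#' cohort CV of the mitotic index. The CI is a percentile bootstrap over
#' resampled observations (gonads).
#'
#' @param values Numeric vector (>= 2 values, non-zero mean).
#' @param level Confidence level (default 0.95).
#' @param reps Bootstrap resamples (default 2000).
#' @param seed Optional integer seed.
#' @return An object of class `cv_result`: `cv`, `ci_low`, `ci_high`,
#'   `level`, `reps`, `seed`.
#' @export
cv_with_bootstrap <- function(values, level = 0.95, reps = 2000L,
                              seed = NULL) {
  if (length(values) < 2L) stop("need >= 2 values", call. = FALSE)
  if (abs(mean(values)) < .Machine$double.eps)
    stop("CV undefined for zero mean", call. = FALSE)
  check_prob(level, "level", open_left = TRUE, open_right = TRUE)
  cv_stat <- function(d, i) stats::sd(d[i]) / mean(d[i])
  cv <- cv_stat(values, seq_along(values))
  ci <- with_seed(seed, {
    bt <- boot::boot(values, cv_stat, R = reps)
    if (stats::sd(bt$t[, 1L]) == 0) {
      rep(bt$t0, 2L)
    } else {
      bc <- boot::boot.ci(bt, conf = level, type = "perc")
      bc$percent[1L, 4:5]
    }
  })
  structure(list(cv = cv, ci_low = ci[1L], ci_high = ci[2L], level = level,
                 reps = as.integer(reps), seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV = %.4f (%g%% percentile bootstrap CI [%.4f, %.4f], %d resamples)\n",
              x$cv, 100 * x$level, x$ci_low, x$ci_high, x$reps))
  invisible(x)
}

#' Bootstrap the difference between two cohort CVs
#'
#' Percentile bootstrap CI for `CV(a) - CV(b)`, resampling each cohort
#' independently.
#'
#' @param a,b Numeric vectors (>= 2 values each, non-zero means).
#' @inheritParams cv_with_bootstrap
#' @return List with `diff`, `ci_low`, `ci_high`, `level`.
#' @export
cv_diff_bootstrap <- function(a, b, level = 0.95, reps = 2000L,
                              seed = NULL) {
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 values per group")
  cv <- function(x) stats::sd(x) / mean(x)
  with_seed(seed, {
    d <- replicate(reps, cv(sample(a, replace = TRUE)) -
                     cv(sample(b, replace = TRUE)))
    qs <- stats::quantile(d, c((1 - level) / 2, 1 - (1 - level) / 2),
                          names = FALSE)
    list(diff = cv(a) - cv(b), ci_low = qs[1L], ci_high = qs[2L],
         level = level)
  })
}

#' Interval-censored two-sample rank (Gehan score) permutation test
#'
#' A generalization of the two-sample rank test to interval-censored
#' first-labeling times. The Gehan-type statistic is
#' `U = sum over (i in A, j in B) of s(i, j)` with `s = +1` when interval i
#' lies entirely after interval j, `-1` when entirely before, and 0 when
#' the intervals overlap; the two-sided p-value comes from the permutation
#' distribution of group labels.
#'
#' @param group_a,group_b Data frames with `left`/`right` columns (see
#'   [interval_obs()]).
#' @param n_perm Number of permutations (>= 999).
#' @param seed Optional integer seed.
#' @return List with `statistic` (U) and `p_value`.
#' @export
ic_rank_test <- function(group_a, group_b, n_perm = 1999L, seed = NULL) {
  stopifnot(is.data.frame(group_a), is.data.frame(group_b),
            nrow(group_a) > 0L, nrow(group_b) > 0L)
  if (n_perm < 999L) stop_field("n_perm", "must be >= 999")
  l <- c(group_a$left, group_b$left)
  r <- c(group_a$right, group_b$right)
  if (any(l < 0) || any(l >= r))
    stop("intervals must satisfy 0 <= left < right", call. = FALSE)
  n <- length(l); n_a <- nrow(group_a)
  # s(i, j) = 1{l_i >= r_j} - 1{r_i <= l_j}; per-observation Gehan scores
  # c_i = sum_j s(i, j). By antisymmetry U = sum of c_i over group A.
  s_mat <- outer(l, r, ">=") - outer(r, l, "<=")
  cs <- rowSums(s_mat)
  u <- sum(cs[seq_len(n_a)])
  with_seed(seed, {
    u_perm <- replicate(n_perm, sum(cs[sample.int(n, n_a)]))
    p <- (1 + sum(abs(u_perm) >= abs(u) - 1e-9)) / (n_perm + 1)
    list(statistic = u, p_value = min(1, p))
  })
}

#' Bonferroni correction
#'
#' @param p_values P-values in \[0, 1\].
#' @param m Number of tests corrected for (>= `length(p_values)`).
#' @return `min(1, p * m)` elementwise.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1))
    stop_field("p_values", "must lie in [0, 1]")
  if (m < length(p_values))
    stop_field("m", "must be >= length(p_values)")
  stats::p.adjust(p_values, method = "bonferroni", n = m)
}

#' Sister-arm concordance in EdU status
#'
#' Fraction of worms whose two gonadal arms agree in activity status
#' (presence/absence of at least one labeled cell), with a permutation
#' p-value against the null that arms are independent given the marginal
#' rates (second-arm statuses permuted across worms; one-sided toward
#' excess agreement).
#'
#' @param pairs Two-column logical (or 0/1) matrix or data frame, one row
#'   per worm.
#' @param n_perm Number of permutations (default 1999).
#' @param seed Optional integer seed.
#' @return List with `agreement` and `p_value`.
#' @export
sister_arm_agreement <- function(pairs, n_perm = 1999L, seed = NULL) {
  pairs <- as.matrix(pairs)
  if (!nrow(pairs) || ncol(pairs) != 2L)
    stop("`pairs` must have one row per worm and two columns", call. = FALSE)
  a <- as.logical(pairs[, 1L]); b <- as.logical(pairs[, 2L])
  obs <- mean(a == b)
  n <- length(a)
  with_seed(seed, {
    perm <- replicate(n_perm, mean(a == b[sample.int(n)]))
    list(agreement = obs,
         p_value = (1 + sum(perm >= obs - 1e-9)) / (n_perm + 1))
  })
}

#' Fisher's exact test on a 2x2 dormancy table
#'
#' Two-sided Fisher's exact test (hypergeometric) for association between
#' condition and dormant/active counts.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return Two-sided p-value.
#' @export
dormancy_proportion_test <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L) || any(table < 0) ||
      any(table != round(table)))
    stop("`table` must be a 2x2 matrix of non-negative integers",
         call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("both margins must be positive", call. = FALSE)
  stats::fisher.test(table)$p.value
}
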