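#' Cell-cycle parameters
#'
#' Deterministic kinematics of a cycling germ-cell population are governed by
#' the fractions of one cycle spent in each phase (G1, S, G2, M) and by the
#' total cycle length. Position within the cycle is expressed as an "age":
#' the completed fraction of one cycle, a number in \[0, 1).
#'
#' Defaults reflect the wild-type young-adult preset: M phase occupies about
#' 10% of the cycle and a full revolution takes about 5.5 hours. The
#' remaining phase fractions are configurable defaults, not measured
#' constants.
#'
#' @param f_g1,f_s,f_g2,f_m Phase fractions, each in (0, 1), summing to 1
#'   (tolerance 1e-9).
#' @param t_c Total cycle length in hours (> 0).
#'
#' @return An object of class `cycle_params`.
#' @examples
#' cp <- cycle_params()
#' phase_label(0.45, cp)
#' dna_content(0.55, cp)
#' @export
cycle_params <- function(f_g1 = 0.4, f_s = 0.3, f_g2 = 0.2, f_m = 0.1,
                         t_c = 5.5) {
  fr <- c(f_g1 = f_g1, f_s = f_s, f_g2 = f_g2, f_m = f_m)
  for (nm in names(fr)) {
    if (!is.numeric(fr[[nm]]) || length(fr[[nm]]) != 1L || !is.finite(fr[[nm]]))
      stop_field(nm, "must be a single finite number")
    if (fr[[nm]] <= 0 || fr[[nm]] >= 1)
      stop_field(nm, "must lie strictly inside (0, 1)")
  }
  if (abs(sum(fr) - 1) > 1e-9)
    stop_field("f_g1..f_m", sprintf("phase fractions must sum to 1 (got %.12g)",
                                    sum(fr)))
  check_scalar(t_c, "t_c", lower = 0, strict = TRUE)
  structure(list(f_g1 = f_g1, f_s = f_s, f_g2 = f_g2, f_m = f_m, t_c = t_c),
            class = "cycle_params")
}

#' @export
print.cycle_params <- function(x, ...) {
  cat("Cell-cycle parameters\n")
  cat(sprintf("  phase fractions: G1 %.3f | S %.3f | G2 %.3f | M %.3f\n",
              x$f_g1, x$f_s, x$f_g2, x$f_m))
  cat(sprintf("  cycle length:    %.3g h\n", x$t_c))
  invisible(x)
}

check_age <- function(age) {
  if (!is.numeric(age) || any(!is.finite(age)) || any(age < 0) || any(age >= 1))
    stop("`age` must lie in [0, 1)", call. = FALSE)
  age
}

#' Relative DNA content at a cycle position
#'
#' Maps cycle age onto relative DNA content on the 1n--2n axis: 1.0
#' throughout G1, a linear ramp from 1.0 to 2.0 across S (replication), and a
#' 2.0 plateau through G2 and M. The axis is circular: division returns
#' content from 2n to 1n.
#'
#' @param age Cycle-completion fraction(s) in \[0, 1). Vectorized.
#' @param params A [cycle_params()] object.
#' @return Numeric vector of relative DNA content in \[1, 2\].
#' @export
dna_content <- function(age, params = cycle_params()) {
  check_age(age)
  s_start <- params$f_g1
  s_end <- params$f_g1 + params$f_s
  out <- numeric(length(age))
  in_g1 <- age < s_start
  in_s <- age >= s_start & age < s_end
  out[in_g1] <- 1
  out[in_s] <- 1 + (age[in_s] - s_start) / params$f_s
  out[!in_g1 & !in_s] <- 2
  out
}

#' Phase label at a cycle position
#'
#' Interval lookup on cumulative phase fractions; intervals are half-open and
#' lower-inclusive, so `age == f_g1` is the first instant of S.
#'
#' @inheritParams dna_content
#' @return Factor-free character vector with values in `G1`, `S`, `G2`, `M`.
#' @export
phase_label <- function(age, params = cycle_params()) {
  check_age(age)
  brk <- cumsum(c(params$f_g1, params$f_s, params$f_g2))
  lab <- c("G1", "S", "G2", "M")
  lab[findInterval(age, c(0, brk)) ]
}

#' Construct a zone population
#'
#' A mitotic-zone population is a set of cells, each carrying a cycle age and
#' an EdU label status. Stored as a data frame with columns `age` (in
#' \[0, 1)) and `edu` (logical).
#'
#' @param age Numeric vector of cycle ages in \[0, 1).
#' @param edu Logical vector of EdU label states (recycled).
#' @return An object of class `zone_population` (a data frame).
#' @export
zone_population <- function(age = numeric(), edu = FALSE) {
  check_age(age)
  df <- data.frame(age = as.numeric(age),
                   edu = rep_len(as.logical(edu), length(age)))
  class(df) <- c("zone_population", "data.frame")
  df
}

#' @export
print.zone_population <- function(x, ...) {
  cat(sprintf("Zone population: %d cells, %d EdU+ (%.1f%%)\n",
              nrow(x), sum(x$edu),
              if (nrow(x)) 100 * mean(x$edu) else 0))
  invisible(x)
}

#' Sample a steady-state zone population
#'
#' Draws `n` unlabeled cells with independent cycle ages from the
#' steady-state age density. The default is uniform on \[0, 1) — the simplest
#' self-consistent closed-population model. The exponential-growth
#' alternative, with density proportional to `2^(1 - age)` (young cells are
#' overrepresented because each division creates two), is available via
#' `density = "exponential"`.
#'
#' @param n Number of cells (>= 0). Mitotic zones contain about 260 cells.
#' @param params A [cycle_params()] object.
#' @param seed Optional integer seed; the sample is deterministic given it.
#' @param density `"uniform"` (default) or `"exponential"`.
#' @return A [zone_population()] with all cells unlabeled.
#' @export
sample_steady_state <- function(n = 260, params = cycle_params(), seed = NULL,
                                density = c("uniform", "exponential")) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 0)
    stop_field("n", "must be a single non-negative number")
  n <- as.integer(n)
  density <- match.arg(density)
  with_seed(seed, {
    u <- stats::runif(n)
    age <- if (density == "uniform") u else -log2(1 - u / 2)
    zone_population(age = age, edu = FALSE)
  })
}

#' Advance a population through the cycle
#'
#' Every age is advanced by `dt / t_c` modulo 1: one full revolution on the
#' circle corresponds to every cell having undergone one full cycle. The
#' population is closed — labels are preserved, no birth or death.
#'
#' @param population A [zone_population()].
#' @param dt Elapsed time in hours (>= 0).
#' @param params A [cycle_params()] object.
#' @return The advanced [zone_population()].
#' @export
advance <- function(population, dt, params = cycle_params()) {
  stopifnot(inherits(population, "zone_population"))
  check_scalar(dt, "dt", lower = 0)
  age <- (population$age + dt / params$t_c) %% 1
  age[age >= 1] <- 0  # guard the fp edge of %% at the seam
  population$age <- age
  population
}
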