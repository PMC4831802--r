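# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Wild-type template library at the default or noiseless measurement model.
wt_library <- function(noise_cv = 0.06) {
  cached(sprintf("wtlib_%g", noise_cv),
         build_template_library(cycle_params(), n_sim = 1e5,
                                noise_cv = noise_cv, seed = 20260924))
}

# Simulate one pulsed zone advanced to true phase `phi`, measured with the
# given noise, and return its histogram pair.
observed_zone <- function(phi, noise_cv = 0, n = 260L,
                          params = cycle_params(), pulse = 0.5) {
  pop <- sample_steady_state(n, params)
  pop <- pulse_label(pop, pulse, params)
  pop <- advance(pop, (phi %% 1) * params$t_c, params)
  make_histogram_pair(pop, params = params, noise_cv = noise_cv)
}

# Shortest circular distance between two cycle fractions, in cycles.
circdist <- function(a, b) {
  d <- abs((a - b) %% 1)
  pmin(d, 1 - d)
}

# One reproducible sub-seed from the current RNG stream.
draw_subseed <- function() sample.int(.Machine$integer.max - 1L, 1L)
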