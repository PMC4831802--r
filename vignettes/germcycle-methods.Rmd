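---
title: "Models and methods in germcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in germcycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germcycle)
```

This vignette is the package's account of its models: the assumptions
behind each estimator, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator does and does not
emulate, and the numerical choices that matter when reproducing results.

## 1. Kinematic model of a cycling zone

A mitotic zone is modeled as a closed population of `n` cells (~260 in a
young-adult zone), each described by its cycle *age* `a ∈ [0, 1)` — the
completed fraction of one cell cycle — and an EdU label bit. Phase
occupancy is set by the fractions `(f_G1, f_S, f_G2, f_M)` of the cycle
spent in each phase, and time is converted to cycle fractions by the
cycle length `t_c` (hours). Relative DNA content is the deterministic
piecewise map: 1.0 through G1, a linear ramp 1.0→2.0 across S
(replication), and a 2.0 plateau through G2 and M. Division returns
content from 2n to 1n, which makes the content axis *circular* — the fact
the phase-matching metric must respect.

Defaults: `f_M = 0.10` (M phase is about a tenth of the cycle) and
`t_c = 5.5` h (one full revolution in a young-adult wild-type zone) are
the two empirically anchored values; `f_G1 = 0.4, f_S = 0.3, f_G2 = 0.2`
are configurable defaults chosen to give a realistic S fraction, since
the analysis pins down only `f_M` and the total length. All presets
expose them.

Assumptions worth stating explicitly:

* **Closed population.** No birth, death, or meiotic-entry efflux during
  the observation window, and labels are tracked as presence, not
  intensity, so label dilution across divisions is ignored. Both are
  appropriate for windows of at most ~1.5 cycles.
* **Deterministic kinematics.** All cells in a zone share `t_c`;
  stochasticity enters at the *zone* level through dormancy switching.
  Per-cell cycle-length jitter would blur template histograms slightly
  but not move their matched phases at the grid resolution used.
* **Steady-state ages are uniform on [0, 1).** This is the simplest
  self-consistent closed-population model. For an exponentially growing
  population young cells are overrepresented (density ∝ `2^(1 − a)`);
  `sample_steady_state(density = "exponential")` provides that
  alternative, and the choice is a generator/template configuration, not
  a code path difference.

## 2. EdU labeling and dormancy

EdU is incorporated during S phase. The simulator labels a cell iff the
arc of cycle positions it *actively traverses while label is present*
intersects the S interval. Zone dormancy enters as an *activity
schedule*: disjoint active intervals within the observation window. Cells
advance only during active time, and — because labeling requires
traversal — a zone that is dormant throughout the pulse stays unlabeled
even if some of its cells are parked inside S. A zero-length pulse is the
limiting case and labels exactly the cells in S at that instant.

The zone-level consequence used throughout the dormancy analysis: an
*active* 260-cell zone contains at least one S-phase cell with
probability `1 − (1 − f_S)^260 ≈ 1 − 4e-41`, so a zone labels essentially
at the onset of its first active interval. First-labeling time is
therefore the first activity onset, which is what makes the two-state
model below exact rather than approximate at realistic zone sizes.

## 3. Phase inference by circular EMD template matching

`build_template_library()` simulates one large steady-state population
(default `n_sim = 1e5`), applies the pulse (default 0.5 h), and records
the EdU+/EdU− DNA-content histogram pair after advancing by `j/k` of a
cycle for `j = 0 … k−1` (default `k = 20`, i.e. 0.05-cycle resolution).
Phase 0 is the moment the pulse ends; phase 1 reproduces phase 0.

`match_phase()` scores an observed pair against each template with

```
cost(obs, tmpl) = w⁺ · EMD_circ(pos) + (1 − w⁺) · EMD_circ(neg),
w⁺ = (frac_pos_obs + frac_pos_tmpl) / 2
```

and returns the argmin phase, the cost, and the margin to the runner-up.
Design choices here, made where the method description is genuinely
open:

* **Class-conditional histograms with fraction weights.** Matching could
  operate on the joint (EdU × content) histogram instead; the
  class-conditional form with weights proportional to class size is the
  declared choice, and an additive penalty
  `λ·|frac_pos_obs − frac_pos_tmpl|` (default `λ = 0`) is exposed for
  users who want the labeled fraction itself to inform the fit.
* **Grid estimates, no interpolation.** Estimates are restricted to the
  k-point grid; ties break toward the smaller phase. The 0.05-cycle
  quantization is the dominant error term for noiseless data.
* **Refusal on unlabeled zones.** A zone with no EdU+ cell carries no
  phase information for a labeled-cohort method; `match_phase()` flags it
  (`dormant`) instead of guessing.

The circular EMD itself is exact, not approximate: for unit-mass
histograms over `B` circular bins with cumulative difference
`F = cumsum(h1 − h2)`, the minimum-cost transport equals
`sum(|F − median(F)|)` in bin-width units. The test suite verifies this
against an independent transportation linear program on hundreds of
random small instances, and checks the metric axioms on random triples.

**Cohort summaries.** Phases are summarized by the circular mean and the
resultant `R`; the display convention for dispersion is the wedge width
`1/R`, capped at 20 when `R < 0.05` (below that the direction is
meaningless and `R`, the quantitative output, should be read instead).
Initial progression rates regress per-time circular means, unwrapped
under the assumption that consecutive chase times are less than half a
cycle apart, on chase time; inputs violating the assumption raise an
error advising denser chase times rather than guessing the winding.
The default fitting window in cohort analyses is half the nominal cycle,
restricting the "initial" rate to chase times before dormancy onset
dominates.

## 4. The two-state switching model

Zones switch dormant ⇄ active as a two-state continuous-time Markov
chain with exponential dwell times (rates `k_DA`, `k_AD`; stationary
dormant fraction `π_D = k_AD/(k_AD + k_DA)`). Under continuous labeling
a zone is unlabeled at duration `t` iff it started dormant and has not
yet switched:

```
U(t) = π_D · exp(−k_DA · t)
```

`fit_switching()` maximizes the Bernoulli likelihood of the
labeled/unlabeled outcomes over `(logit π_D, log k_DA)` (Nelder-Mead from
a small start grid; the transform keeps the parameters in range).
Degenerate datasets return boundary fits with an explicit flag rather
than optimizer output: all-labeled → `π_D = 0`, none-labeled →
`π_D = 1, k_DA = 0`.

Supporting statistics follow the zone-level view:

* **Interval-censored comparison.** A labeling assay observes the
  first-labeling time only as `(0, t]` (labeled) or `(t, ∞)` (unlabeled).
  Groups are compared by the Gehan-score statistic
  `U = Σ s(i, j)` (`s = ±1` for strictly ordered intervals, 0 for
  overlap) with a label-permutation p-value — a deliberate,
  assumption-light generalization of the rank-sum test; no survival-curve
  estimation (e.g. Turnbull NPMLE) is attempted. Permutation rather than
  asymptotic p-values are used in all bespoke tests, with mandatory
  seeds. On point data the test reproduces ordinary rank-sum decisions.
* **Mixture dispersion.** A dormant subpopulation (mitotic index ~0)
  mixed with active zones inflates the cohort CV of the mitotic index:
  `CV² = CV²_active/(1−p) + p/(1−p)` for dormant fraction `p`. CVs are
  reported with percentile bootstrap CIs (`boot::boot.ci`); CI levels
  default to 83% for figure-style error bars, 95% for significance of CV
  differences, and 99% where the capacity analysis reports CIs.
* **Sister-arm concordance** uses a permutation null that preserves the
  marginal activity rate while breaking within-worm pairing, one-sided
  toward excess agreement.

## 5. Capacity bet-hedging simulation

Each individual carries an initial capacity drawn from a normal
distribution truncated at 0 (mean `c0_mean`, CV `cv0`; default
`cv0 = 0.12`, the day-0 brood-size CV), switches states as the CTMC
above, and depletes capacity linearly at `r` units per *active* hour,
floored at zero. Both model pieces are the minimal declared choices:
the dwell-time family is exponential (pluggable in principle — the
simulator only consumes a schedule), and depletion is linear in active
time (a per-division decrement is out of scope). The CV trajectory is
reported against the *realized* CV at `t = 0`, not the nominal `cv0`,
avoiding small-sample bias in the ratio.

`scan_cv_ratio()` evaluates grids of `(k_DA, k_AD, r)`; the headline scan
(and `scripts/acceptance.R`) uses 2000 individuals over 48 h, mean dwell
times log-spaced over 0.5–100 h per state, depletion rates aimed at mean
losses of 30–70%, and five seeds averaged per grid point. Long dwell
times at intermediate occupancy maximize the spread of per-individual
active time (the population splits into nearly-always-active and
nearly-always-dormant individuals), which is where the CV amplification
peaks.

## 6. The synthetic-data generator

`builtin_presets()` ships six condition presets. Their *anchored*
parameters are the 1-h dormant fractions (wild-type-like 5%, fog-1-like
55%, fog-2-like 17%, with sustained-oogenesis conditions near wild type)
and the 5.5-h cycle. Everything else is a documented calibration choice:

| parameter | default | rationale |
|---|---|---|
| `k_da` | 0.25–0.5 /h by preset | slow enough that strongly feminized presets keep unlabeled zones past 6 h |
| `k_ad` | derived | stationarity: `k_ad = k_da π_D/(1−π_D)` |
| `zone_size_mean, sd` | 260, 20 | zones contain ~260 cells; spread is a calibration choice |
| `noise_cv` | 0.06 | plausible DNA-stain quantification error; not anchored to data |
| `edu_fn` | 0.005 | rare missed labels are harmless downstream |
| `edu_fp` | 2e-4 | kept low enough that a truly dormant 260-cell zone reads clean ~95% of the time, so zone-level dormancy classification stays near-perfect — the property the analysis treats as unambiguous. A per-cell false-positive rate as high as `edu_fn` would mislabel most dormant zones (`0.995^260 ≈ 0.27` clean) and break the definition. |
| `ph3_miss` | 0.05 | staining efficiency below 1 |
| `pulse_h` | 0.5 | standard short pulse |

Dormant zones emit no PH3 signal in the generator: dormancy arrests
progression, so M-phase figures are treated as absent in a zone that is
dormant at fixation. This is exactly the mixture structure the
mitotic-index CV analysis detects.

What the generator deliberately does **not** emulate: image segmentation
artifacts, spatial structure within the zone, EdU ingestion kinetics,
label dilution, per-cell cycle-length variability, apoptosis, and
meiotic efflux. Passing tests therefore show that the estimators recover
the generative model they assume — a necessary check of correctness and
identifiability — not that the model captures every feature of real
stained gonads.

## 7. Numerical choices and degenerate inputs

* **Bins.** 32 equal-width circular bins on [1, 2]; content exactly 2
  falls in the last bin; measured content is clamped to [1, 2] after
  multiplicative noise (clamping slightly piles mass at the 1n and 2n
  edges, identically for templates and observations).
* **Raw-intensity calibration.** `read_cell_tables()` rescales raw
  content per gonad by mapping the mode of the lower half of the
  distribution (the G1 peak, estimated by a kernel density) to 1.0. The
  estimate is scale-equivariant, so results are invariant to the
  arbitrary units of the imaging pipeline. Manual anchors can be applied
  upstream and read with `normalize = "none"`.
* **Seeds.** Every stochastic entry point takes a `seed` argument and
  restores the caller's RNG state; identical seeds give byte-identical
  outputs, and sub-seeds are drawn below 2^31.
* **Boundary behavior.** Empty populations histogram to flagged zeros
  (not errors); empty cell tables refuse classification; zero-mass
  histograms and mismatched bins are errors in the EMD; `advance()`
  guards the floating-point seam of the modular reduction so ages stay
  in [0, 1).
* **Problem sizes.** The checked-in verification uses the sizes the
  properties need and no more: 1e5-cell template libraries, 260-cell
  zones, cohorts of 8–40 gonads, 500 zones per duration for switching
  recovery, 1000 replicates for test calibration, and 2000 individuals
  for the capacity scan.

## 8. Known limitations

* Phase estimates are grid-quantized; sub-grid precision would require
  interpolating the cost profile, which is deliberately out of scope.
* The switching MLE assumes a time-homogeneous two-state process;
  age-dependent switching rates would bias `k_DA` toward an average.
* The Gehan-score test discards information in heavily overlapping
  interval configurations; with only a handful of distinct assay
  durations its power is limited, which is the price of making no
  distributional assumptions.
* The capacity simulation demonstrates *achievability* of a ~3-fold CV
  amplification under the declared model; it is not a fit to brood-size
  distributions, which the analysis does not have access to.
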