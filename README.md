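# germcycle

Cell-cycle phase inference and dormancy analysis for germline stem-cell
niches.

## The problem

The mitotic zone of a *C. elegans* gonadal arm holds ~260 cycling
stem/progenitor cells. In reproductively inactive animals these zones do
not merely slow down: they switch stochastically between an
actively-cycling state and a dormant state in which no cell progresses
through the cycle. Two consequences follow. First, population-level assays
(mitotic index, labeling fractions) mix dormant and active zones and need
zone-level analysis. Second, stochastic switching spreads the cumulative
amount of cycling — and with it the remaining reproductive capacity —
across individuals as a population ages.

`germcycle` provides the computational side of this analysis for per-cell
quantification tables (one row per segmented cell: DNA content, EdU
status, PH3 status) from EdU pulse-chase and continuous-labeling
experiments, plus a seeded generator of synthetic datasets with the
statistical structure the analysis assumes.

## Methods at the core

- **Per-gonad cycle phase by template matching.** A zone's progression
  since an EdU pulse is a phase φ ∈ [0, 1) on the unit circle (one
  revolution = one full cycle). Forward simulation of a pulse-labeled
  steady-state population yields a library of DNA-content histogram pairs
  (EdU+/EdU−) at K = 20 evenly spaced phases; an observed zone is assigned
  the phase of the best-fitting template under a **circular Earth Mover's
  Distance** (ground distance `min(|i−j|, B−|i−j|)` on B = 32 bins — the
  content axis wraps from 2n back to 1n at division), combining the EdU+
  and EdU− histograms with class-fraction weights.
- **Circular cohort statistics.** Cohorts are summarized by the circular
  mean phase and resultant `R = |mean(exp(2πiφ))|`; dispersion is displayed
  as the wedge width 1/R. Initial progression rates (cycles/h) come from
  regressing unwrapped per-time circular means on chase time; average
  cycling rate = (fraction of active zones) × (initial rate).
- **Two-state dormancy model.** Under continuous labeling a zone stays
  unlabeled only while it has never been active, so the unlabeled fraction
  follows `U(t) = π_D exp(−k_DA t)`; `fit_switching()` estimates the
  stationary dormant fraction π_D and the dormant→active rate k_DA by
  maximum likelihood from interval-censored labeling outcomes. Supporting
  statistics: Gehan-score permutation test for interval-censored labeling
  times, bootstrap CIs for the mitotic-index CV, Fisher's exact test on
  dormancy tables, sister-arm concordance permutation test.
- **Bet-hedging capacity simulation.** Individuals switch dormant/active
  as a two-state continuous-time Markov chain and deplete reproductive
  capacity linearly while active; `scan_cv_ratio()` scans dwell times and
  depletion rates for the fold-increase in the population CV of remaining
  capacity.

## Worked example

```r
library(germcycle)
presets <- builtin_presets()

# phase inference on a synthetic wild-type pulse-chase cohort
lib <- build_template_library(presets$wt_day1$cycle, seed = 1)
cohort <- generate_pulse_chase(presets$wt_day1, chase_times = c(0, 1, 2),
                               n_per_time = 10, seed = 2)
est <- fit_phases(cohort, lib)
initial_progression_rate(est)
#> Initial progression rate: 0.1850 cycles/h (SE 0.0029) over chase window [0, 2] h
circular_summary(est$phase[est$chase_h == 2])
#> Circular phase summary (n = 10): mean phase 0.370, resultant R = 0.988, wedge width 1.01

# dormancy switching from a continuous-labeling experiment
cont <- generate_continuous(presets$fog1_day1, durations = c(1, 2, 4, 6, 8),
                            n_per_duration = 60, seed = 3)
fit_switching(cont$summary)
#> Two-state dormancy switching fit: U(t) = pi_d * exp(-k_da * t)
#>   pi_d (stationary dormant fraction): 0.6086
#>   k_da (dormant->active rate, /h):    0.2659
#>   -logLik 149.490 on 300 zones
```

The recovered progression rate, 0.185 cycles/h, corresponds to a ~5.4 h
cycle (the generating preset uses 5.5 h); the resultant near 1 says the
wild-type-like cohort stays synchronized through 2 h of chase. The
switching fit recovers the fog-1-like preset (π_D = 0.55, k_DA = 0.25/h)
within sampling error of this 300-zone experiment.

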