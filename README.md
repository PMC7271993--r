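# trailcycle

Sampling-based modeling of the bidirectional interplay between cell-cycle
progression and TRAIL-induced extrinsic apoptosis in single-cell time-lapse
data.

When an unsynchronized cell population is exposed to a death-receptor
agonist such as TRAIL, two couplings confound naive analyses of the
resulting tracks. First, TRAIL slows cell-cycle progression, so phase
lengths measured after treatment mix the drug effect with normal
heterogeneity. Second, cell death right-censors phase measurements
selectively — cells with long phases are more likely to die before
completing them — so the surviving, measurable cells are a biased sample.
`trailcycle` implements the modeling framework that untangles these
effects for Fucci-type two-phase reporters (G1 vs S/G2/M), and the reverse
question: how the cycle position at treatment shapes the time to death.

## The model

Cell-cycle state is a coordinate *C* on [0, 1): G1 occupies [0, 0.45),
S/G2/M occupies [0.45, 1), division happens at 1 and [1, 2) repeats the
layout for the daughter generation. Each cell progresses linearly,
`dC/dt = g`, with phase-specific rates `g = f/T` built from lognormal phase
durations *T* (so traversing a phase takes exactly its sampled duration).
Initial positions of an unsynchronized, exponentially growing population
follow the steady-state age density `F(C0) = 2^(1-C0) ln 2`.

Three estimation problems sit on top of this kinematic core:

* **Phase prolongation _z_.** TRAIL stretches the remaining part of the
  phase a cell is in: a cell exposed *d* hours into a phase of native
  length *T* completes it at `p = T + z - d z / T` (corrected growth rate
  `g* = f / (f/g + z)`). `estimate_z()` recovers *z* by a sampling-based
  likelihood: virtual cohorts are simulated on a *z* grid, phase lengths
  are binned by the time of exposure *d*, a lognormal is fitted per bin,
  the summed negative log-likelihood of the observed (d, p) pairs is
  smoothed with a degree-5 polynomial, and the minimum gives ẑ with a
  chi-square profile CI.

* **Initial position Ĉ0.** For cells that died inside their phase, the
  position is the Monte-Carlo mean of `f·d/p_u` over truncated control
  draws `p_u | p_u > d`; for cells that completed the phase, inverting the
  prolongation map at ẑ gives the native length and hence `C0 = f·d/T`
  (`estimate_positions()`, strategy "hybrid I").

* **Death kinetics (PAD model).** Apoptosis progression *A(t)* rises with
  per-cell slope *m* (drawn as the reciprocal of the early-G1 death-time
  lognormal), decelerates to `m - p` while the cycle coordinate is beyond
  the Point of Apoptosis Deceleration (PAD), is floored at 0, and kills the
  cell when A reaches 1. `estimate_pad()` fits (p, PAD) on a grid by a
  bivariate-KDE likelihood of (C0, t_death) tuples with chi-square
  confidence regions.

A first-class synthetic-data generator (`simulate_tracks()`) produces
virtual track tables with the full statistical structure of the study
design — 19 h pre-treatment observation, treatment at t = 0, 19.25 h
post-treatment window at 15-min frames, phase-specific death
probabilities, sibling-death handling and movie-end censoring — and is the
basis of all parameter-recovery validation.

## Worked example

```r
library(trailcycle)

cfg <- experiment_config(n_cells = 2000, z_true = 3.6)
tracks <- simulate_tracks(cfg, seed = 1)
summarize_tracks(tracks)
#> # A tibble: 5 × 6
#>   phase_at_trail fate          n median_t_death iqr_t_death death_fraction
#>   <chr>          <chr>     <int>          <dbl>       <dbl>          <dbl>
#> 1 G1             apoptotic   840           2.75       1.5            0.755
#> 2 G1             survivor    273          NA         NA              0.755
#> 3 SG2M           apoptotic   611           2.75       1.5            0.696
#> 4 SG2M           mixed         6           3.62       0.625          0.696
#> 5 SG2M           survivor    270          NA         NA              0.696

ze <- estimate_z_from_tracks(tracks, "G1", z_grid = seq(0, 8, 0.25),
                             n_reps = 3, cohort_size = 3e4, seed = 2)
ze
#> Phase-prolongation estimate (G1, post_exposure mode)
#>   z_hat = 3.70 h, 95% CI [3.33, 4.06] h
#>   482 (d, p) pairs, 3 reps of 30000-cell cohorts
```

The population was generated with a true prolongation of 3.6 h and a G1
death probability of 0.76; the summary reproduces the death fraction and
the estimator brackets the generating *z*. `autoplot(ze)` draws the
likelihood profile; `tidy()`/`glance()` return the grid and the one-row
summary. The same pattern applies to `estimate_pad()` (surface raster via
`autoplot()`) and `synchronization_sweep()`
(`plot_synchronization_sweep()`). `run_pipeline(pipeline_config(...))`
chains every stage — control-phase fits with censored BIC selection,
survivor-bias reference, per-phase ẑ, positions, fate association, PAD
fit, synchronization sweep — under one master seed, and `write_report()`
serializes all artifacts.

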