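# anpitch

Ideal-observer modeling of pure-tone frequency discrimination and
fundamental-frequency (F0) discrimination from simulated human
auditory-nerve responses.

## The problem

Pitch discrimination of harmonic complex tones remains possible at very high
frequencies, where phase locking to temporal fine structure (TFS) in the
auditory nerve is believed to be absent. Whether performance there rests on
a *rate-place* code (the tonotopic profile of time-averaged firing rates) or
on residual *temporal* information is a long-standing question. One way to
attack it is to ask what an optimal decoder of the auditory nerve could
achieve: simulate the population of instantaneous firing rates
`r_i(t, θ)` evoked by a stimulus with parameter vector `θ`, and bound the
variance of any unbiased estimator of the target parameter (frequency `f` or
fundamental `F0`) with the Cramér–Rao inequality for inhomogeneous Poisson
spike trains:

    I(θ)_{αβ} = Σ_i K_i ∫₀ᵀ (1/r_i) (∂r_i/∂α)(∂r_i/∂β) dt
    var(θ̂) ≥ (E_θ[I(θ)] + A(θ))⁻¹ ,   JND = sqrt([var]₁₁)

where `A(θ)` is diagonal prior information (`1/ν²`) for randomly roved
nuisance parameters (component levels, phases). Two observers are compared:
an **all-information** observer using the full spatiotemporal rate pattern,
and a **rate-place** observer that first averages each fiber's rate over
time. The package provides the full pipeline — calibrated stimulus
synthesis, a phenomenological auditory-nerve front end with a plug-in
boundary, the Fisher/CRLB machinery with a Monte-Carlo maximum-likelihood
oracle, FDL/F0DL experiment grids with LOESS ratio summaries, and
excitation-pattern / autocorrelogram population views.

It is written for auditory and computational neuroscientists who want
desk-scale, fully reproducible ideal-observer threshold predictions, or a
reference harness into which other published auditory-nerve models can be
plugged (`register_frontend()`).

## Worked example

Predict pure-tone FDLs at 30 dB re: threshold for both observers on the
desk-scale grid (9 frequencies, 1.4–14 kHz):

```r
library(anpitch)

frontend <- make_frontend(frontend_config())
cal_map  <- calibrate_thresholds(frontend)   # 25 x 25 rate-level grid

fdl <- run_fdl(grid_preset("FDL", "desk"), frontend, cal_map = cal_map,
               seed = 1)
subset(fdl, frequency %in% c(1400, 14000),
       select = c(frequency, observer, jnd, jnd_rel_pct))
#>    frequency        observer     jnd jnd_rel_pct
#> 1       1400 all_information   0.150      0.0107
#> 2       1400      rate_place   3.465      0.2475
#> 17     14000 all_information  23.153      0.1654
#> 18     14000      rate_place  24.321      0.1737

threshold_ratio(fdl, 8500, 2000, "all_information")
#> [1] 13.14
threshold_ratio(fdl, 8500, 2000, "rate_place")
#> [1] 0.81
```

At 1.4 kHz the all-information observer resolves 0.15 Hz (0.011%) — phase
locking makes frequency coding extraordinarily precise — while the
rate-place observer needs ~0.25%. By 14 kHz phase locking is gone and the
two observers nearly coincide. The LOESS-interpolated threshold ratio
between 8.5 and 2.0 kHz is ≈ 13 for the all-information observer (an
order-of-magnitude degradation, as in high-frequency pitch psychophysics)
versus ≈ 0.8 (flat) for the rate-place observer. The same machinery run on
bandpass-filtered harmonic complexes (`run_f0dl`) yields an all-information
F0DL ratio of ≈ 10.9 between F0s of 1.4 and 0.28 kHz and a rate-place ratio
of ≈ 0.65.

The numbered scripts under `analysis/` run the full set of analyses
(calibration, FDL, F0DL, roving effects, population views) and write tidy
CSVs plus run manifests under `results/`.

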