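---
title: "Ideal-observer analysis of simulated auditory-nerve responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ideal-observer analysis of simulated auditory-nerve responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(anpitch)
```

# The model

`anpitch` links acoustic stimuli to predicted psychophysical thresholds in
three stages: (1) parametric stimulus synthesis, (2) a phenomenological
auditory-nerve front end producing expected instantaneous firing rates
$r_i(t,\theta)$ for a population of model fibers, and (3) an ideal-observer
stage that converts the sensitivity of those rates to stimulus parameters
into a lower bound on discrimination thresholds.

## Poisson ideal observer

Spike trains are modeled as inhomogeneous Poisson processes with intensity
$r_i(t, \theta)$, conditionally independent across fibers given the stimulus
parameter vector $\theta$. For any unbiased estimator of $\theta$, the
Cramér–Rao bound limits the precision, and for Poisson spike observations
the Fisher information matrix has elements

$$ I(\theta)_{\alpha\beta} \;=\; \sum_i K_i \int_0^T
   \frac{1}{r_i(t,\theta)}\,
   \frac{\partial r_i}{\partial \alpha}\,
   \frac{\partial r_i}{\partial \beta}\, dt, $$

where $K_i$ is the number of fibers sharing CF $i$'s rate pattern.
`fisher_matrix()` estimates the derivatives by central finite differences
(default relative step $10^{-4}$ for frequency/F0, 0.25 dB for levels, 1° for
phases) and integrates with the trapezoidal rule on the front-end time grid.
Rates are floored at the spontaneous rate, so $1/r$ is always finite.

Randomized stimulus parameters (level roving, phase randomization) are
nuisance dimensions of $\theta$. `expected_fisher()` averages $I(\theta)$
over draws of the roved parameters from their *uniform* synthesis
distributions, while the prior-information matrix $A(\theta)$ uses the
*normal* approximation ($1/\nu^2$ with SD 6 dB for the ±3 dB level rove and
360° for the uniform phase rove). This asymmetry — uniform in synthesis,
normal in evaluation — keeps the Fisher expectation faithful to the actual
stimulus ensemble while keeping the prior information well defined. The
variance bound for the target parameter is the target diagonal element of
$(\mathrm{E}[I] + A)^{-1}$, and the threshold (JND at the 70.7%-correct
point) is its square root.

Two observers share this machinery. The **all-information** observer uses
$r_i(t,\theta)$ as is; the **rate-place** observer first replaces every
fiber's rate by its time average (`rate_place_transform()`), which reduces
each fiber to Poisson-count information $T \bar r'^2/\bar r$. By the
Cauchy–Schwarz inequality the rate-place information never exceeds the
all-information value, and the test suite asserts this at every grid point.

### Why the expectation uses 8 draws by default

The number of rove samples used for the expectation is not specified by the
sources this design follows; 8 seeded draws keep the Monte-Carlo error of
the averaged information well below the finite-difference tolerance at desk
scale (the desk presets use 4), and the property suite checks convergence of
the expectation on a closed-form case.

### Monte-Carlo ML oracle

`oracle_ml_discrimination()` validates the bound: it draws Poisson spike
samples from $r(\cdot,\theta_0)$ and $r(\cdot,\theta_0+\Delta)$, classifies
two-interval trials by the exact log-likelihood-ratio templates, and reports
the proportion correct. With $\Delta$ equal to the CRLB-derived JND the
per-interval sensitivity is $d' = 1$, so the expected two-interval
proportion correct is $\Phi(1/\sqrt2) \approx 0.76$; the acceptance suite
requires the simulated value to fall in $[0.69, 0.80]$ at 2000 trials.

# The reference front end

The front end is an analytic chain, deliberately minimal:

1. **Gammatone filter** at each CF (4th order), unit gain at CF, bandwidth
   from the human tuning law $Q_{\mathrm{ERB}} = 12.7\,(f/\mathrm{1\,kHz})^{0.3}$
   (config-exposed constant and exponent).
2. **Rectifying saturating transduction**
   $u = 1 - \exp\{-[(1{+}a)x^+ + (1{-}a)x^-]/x_s\}$ with asymmetry
   $a = 0.8$ and saturation pressure $x_s = 3.5\times10^{-4}$ Pa.
3. **Phase-locking lowpass**: a cascade of 7 first-order stages at 4.8 kHz.
4. **Affine rate map**: $r = r_{\mathrm{spont}} + (r_{\max} -
   r_{\mathrm{spont}})\,u_{LP}$, with $r_{\max} = 250$ spikes/s and
   spontaneous rates 60/5/1 spikes/s for HSR/MSR/LSR fibers. LSR and MSR
   fibers have their saturation pressure raised by 30/15 dB (higher
   thresholds, wider dynamic range).

Calibration rationale, in order of what each parameter pins down:

* `pl_cutoff = 4800`, `pl_order = 7`: on-CF vector strength starts declining
  by 2–3 kHz and is negligible above roughly three times the cutoff. The
  relative FDL of the all-information observer is then best near
  $f_c/\sqrt 6 \approx 2$ kHz, which is where the minimum should sit.
* `asym = 0.8`: low-level vector strength $\approx a\pi/4 \approx 0.63$,
  strong but not saturated phase locking.
* `xs = 3.5e-4` Pa: puts the HSR rate-level threshold near −8 dB SPL (inside
  the −10…40 dB calibration grid) and makes 50-dB-SPL components drive HSR
  fibers to ≥ 90% of `max_rate` in the steady state while LSR fibers remain
  unsaturated — the saturation contrast that makes LSR excitation patterns
  resolve harmonics where HSR patterns are flat. Because all discrimination
  levels are specified *re: threshold*, this constant affects absolute
  saturation only, not the threshold curves.

### Oversampled transduction

The memoryless nonlinearity generates harmonics and intermodulation products
of the stimulus far above the base Nyquist frequency. Evaluated directly on
a 100-kHz grid they alias — e.g. the 12th harmonic of an 8.5-kHz tone lands
at 2 kHz — into the phase-locking passband, where the ideal observer reads
them as spurious temporal fine structure with a large frequency leverage
(the $k$-th harmonic's phase moves $k$ times faster with stimulus
frequency). The transduction stage is therefore evaluated at an oversampled
rate (`oversample = 12`, an effective 1.2 MHz): the gammatone output is
upsampled exactly by spectral zero-padding, the nonlinearity and lowpass
cascade are applied at the high rate, and the result is decimated by
spectral truncation. High-frequency JNDs converge by a factor of 4
oversampling and are stable against halving the finite-difference step to
within 2% (both are asserted in the tests); factor 12 matches the megahertz
class of internal rate this style of front end is conventionally run at for
high-frequency stimuli.

### Rate-level calibration

`calibrate_thresholds()` simulates 100-ms on-CF pure tones at 25 log-spaced
frequencies (0.2–20 kHz) and 25 levels (−10…40 dB SPL), linearly
interpolates each rate-level function, and records the lowest level whose
mean rate reaches 5% above spontaneous. All presentation levels are then set
in dB re: these thresholds (for complexes, re: the threshold at the 8th
harmonic). The reference chain has no middle-ear shaping, so its map is
nearly flat (−8.4 to −7.4 dB SPL); the mechanism exists because plug-in
front ends with middle-ear filters need it.

# Stimuli

The stimulus module is the pipeline's synthetic-data generator; its defaults
are the study conditions, not tuning knobs.

* **Pure tones**: 100 ms including 10-ms raised-cosine ramps, sine phase,
  calibrated so a tone at $L$ dB SPL has RMS $20\,\mu\mathrm{Pa}\times
  10^{L/20}$.
* **Harmonic complexes**: discrete (harmonics 6–10) or filtered — all
  harmonics to Nyquist, each scaled by the zero-phase 12th-order Butterworth
  bandpass gain with cutoffs at 5.5 and 10.5 × the nominal F0 (4–12 × F0 for
  the broader GEOM masker). The zero-phase filter is realized analytically
  as the squared magnitude of the 12-pole analog prototype — the standard
  forward–backward interpretation of a named-order zero-phase design —
  applied per component, which for stationary sinusoids is the exact
  filtered output and sidesteps the numerical instability of a 24-pole
  polynomial IIR at narrow normalized bands. Components attenuated by more
  than 100 dB are omitted. The filter's cutoffs stay anchored on the nominal
  F0 when the synthesized F0 is perturbed, so edge-harmonic gain changes are
  part of the discrimination cue, as they are for a listener.
* **Roving**: per-component level roves are uniform ±3 dB, phases uniform
  over 360° (seeded; two runs with equal seeds are identical).
* **TEN**: Gaussian noise with PSD $\propto 1/\mathrm{ERB}(f)$,
  $\mathrm{ERB}(f) = 24.7(4.37 f_{\mathrm{kHz}} + 1)$, scaled so the power in
  the ERB-wide band at 1 kHz matches the nominal level (40 dB SPL in the
  views). The defining constant-power-per-ERB property is implemented
  directly since no spectral recipe beyond that property is specified.
* **Maskers**: GEOM (one masker at the geometric-mean F0, broader band) and
  DBL (two maskers at semitone offsets of opposite sign, −5.5/+6 ST in the
  views). Masked stimuli are exact sample-wise sums of their parts.

# Experiment pipelines and summaries

FDL runs place 40 log-spaced CFs over 0.5–1.5 × the tone frequency with 72
fibers each (≈ 3000 HSR fibers, i.e. 60% of a 30,000-fiber nerve scaled to
the band); F0DL runs use 40 CFs over 5–11 × F0 with 51 fibers each. The
desk presets use 9 log-spaced frequencies (1.4–14 kHz) or F0s (0.18–1.8 kHz)
at 30 dB re: threshold; the full presets use 24 points and three levels.
Problem sizes were chosen so every pipeline completes in about a minute on
one core while the ratio summaries are stable to a few percent against grid
refinement.

Thresholds are summarized by LOESS fits of log threshold versus log
frequency on the relative scale (Weber fraction, %), and ratio summaries
interpolate the fit at 8.5/2.0 kHz (FDL) or 1.4/0.28 kHz (F0DL) —
interpolation only, extrapolation is rejected. The LOESS span is 0.5 for
grids of 16+ points and 0.75 for the 9-point desk grids (a degree-2 local
fit needs enough points per neighborhood); a power-law recovery test guards
the setting. Ratios are computed on the relative scale: the absolute (Hz)
and relative ratios differ exactly by the anchor-frequency ratio, and the
relative scale is the one on which "flat" means constant Weber fraction.

For roved runs, the nuisance dimensionality for a filtered complex is one
level and one phase per component whose post-filter level is within 40 dB of
the passband maximum (harmonics 6–11 for the 5.5–10.5 cutoffs; the 11th
sits ≈ 30 dB down and just inside the window), keeping the information
matrix small with negligible loss from deeply attenuated components.

# Population views

Excitation patterns time-average each CF's rate over fresh rove + noise
samples (200 CFs over 4–12 × F0, 10 repeats in the analysis scripts) and
report mean ± SD. Autocorrelograms compute, per CF, the mean-subtracted,
variance-normalized autocorrelation of the instantaneous rate over a
steady-state window (ramps and the post-offset tail excluded — onset
transients otherwise dominate the ACF); the sACF is the column sum across
CFs. A constant response degenerates to the raw-product normalization (flat
ACF near 1). The temporal salience of the target period is the excess of the
sACF at the period lag over its local median, divided by the number of CFs;
the per-CF normalization is used because the mean-subtracted sACF has a
near-zero local baseline, which makes a baseline-relative quotient
unstable.

# What the generator does and does not emulate

The synthetic stimuli are exactly the parametric laboratory stimuli (tones,
filtered complexes, TEN, tone-on-tone maskers) — there is no attempt to
emulate natural sounds, room acoustics, or headphone transfer functions.
The front end omits middle-ear filtering, cochlear compression and
suppression, efferents, and synaptic adaptation; rates are expected values,
with Poisson variability entering only through the observer math and the ML
oracle. Consequently, passing tests show that the ideal-observer machinery
and the qualitative structure of temporal versus rate-place coding are
implemented correctly — they do not certify quantitative fidelity to any
particular physiological dataset, and quantities tied to the front end's
calibrated parameters (e.g. the exact FDL ratio) carry the calibration's
uncertainty. Predictions for masked (GEOM/DBL) stimuli are deliberately
restricted to the population views; ideal-observer thresholds for stimuli
with external acoustic noise are out of scope, since unmodified CRLB
analysis does not account for stimulus noise.

# Numerical choices and degenerate inputs

* Finite differences are central; the frequency/F0 step is relative
  $10^{-4}$. At $10^{-3}$ the central difference decorrelates over the
  100-ms window (the phase drift $2\pi h t$ approaches a radian) and the
  step-halving guard fails; at $10^{-4}$ halving the step changes JNDs by
  well under 2%.
* Nonpositive rates are rejected before the $1/r$ integrand (spontaneous
  floors prevent them in practice); singular information matrices are
  reported as non-identifiable configurations, and grid points where that
  happens are flagged in the output, not dropped.
* Vector strength is computed over an integer number of cycles and requires
  at least 5; a zero-integral rate is a distinct error.
* Q10 probes use 300-ms tones with 50-ms ramps so ramp splatter through the
  filter tip does not bias the 10-dB-down points; the measured response is
  converted to equivalent input attenuation by inverting the on-CF
  rate-level function, so the compressive transduction cancels exactly.
* Seeds: one user seed is expanded into independent per-module streams
  (`derive_seed`), all below $2^{31}$; no function draws from an unseeded
  stream.

# Known limitations

* The rate-place observer inherits the human tuning law directly; with
  $Q_{\mathrm{ERB}} \propto f^{0.3}$ its F0DL ratio across 0.28–1.4 kHz
  computes to ≈ 0.65 rather than exactly 1 — sharper relative tuning at high
  CF makes harmonics 6–10 better resolved at high F0. The direction of the
  scientific conclusion (no high-frequency deterioration of rate-place
  thresholds, in contrast to the order-of-magnitude all-information and
  behavioral degradation) is unaffected.
* The phase-randomization factor of ≈ 2 for the all-information observer
  holds where temporal fine structure dominates (below ≈ 4 kHz in this
  chain); at higher frequencies the place floor takes over sooner than in
  front ends with sharper high-CF tuning.
* LOESS ratio summaries on 9-point grids carry a few percent of smoothing
  error; the full 24-point presets reduce it.
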