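# Population views of the simulated auditory nerve: excitation patterns
# (time-averaged rate vs CF, with variability over fresh noise/rove samples)
# and autocorrelograms with their summary autocorrelation function (sACF).

#' Excitation pattern: mean and SD of time-averaged rate across CF
#'
#' For each repeat a fresh stimulus is built (fresh level rove and fresh
#' noise via the per-repeat seed), rates are simulated at every CF and
#' time-averaged; the pattern reports the mean and standard deviation over
#' repeats.
#'
#' @param stim_builder Function `seed -> waveform` producing one stimulus
#'   realisation (rove + noise) per seed.
#' @param cfs CF grid, Hz (the harmonic-complex conventions use 200 CFs over
#'   4-12 x F0).
#' @param frontend A `frontend`.
#' @param fiber_class `"hsr"`, `"msr"` or `"lsr"`.
#' @param n_repeats Number of stimulus realisations (>= 1; 10 in the
#'   harmonic-complex conventions).
#' @param seed Integer seed expanded into one stream per repeat.
#' @return An object of class `excitation_pattern`: list with `cfs`,
#'   `mean_rate`, `sd_rate`, `fiber_class`, `n_repeats`.
#' @export
excitation_pattern <- function(stim_builder, cfs, frontend = make_frontend(),
                               fiber_class = "hsr", n_repeats = 10,
                               seed = 1) {
  stopifnot(n_repeats >= 1)
  pop <- population_spec(cfs, 1, fiber_class)
  acc <- matrix(NA_real_, n_repeats, length(cfs))
  for (i in seq_len(n_repeats)) {
    wv <- stim_builder(derive_seed(seed, i))
    acc[i, ] <- mean_rate_over(frontend$simulate(wv, pop))
  }
  structure(list(cfs = cfs, mean_rate = colMeans(acc),
                 sd_rate = apply(acc, 2, stats::sd),
                 fiber_class = fiber_class, n_repeats = n_repeats),
            class = "excitation_pattern")
}

#' Autocorrelogram of instantaneous rates across CF, with sACF
#'
#' Computes, per CF, the normalized autocorrelation of the instantaneous rate
#' over lags `[0, max_lag]` (mean-subtracted and variance-normalized, so the
#' lag-0 value is 1; a constant response falls back to raw-product
#' normalization, giving a flat ACF near 1). The sACF is the column sum of
#' the autocorrelogram over CFs.
#'
#' @param wave A `waveform` (duration must be at least `2 * max_lag`).
#' @param cfs CF grid, Hz (linear spacing in the harmonic-complex
#'   conventions, 4-12 x F0).
#' @param frontend A `frontend`.
#' @param max_lag Maximum lag, s.
#' @param fiber_class Fiber class (default `"hsr"`).
#' @param target_period Optional target period, s; stored so lags can also be
#'   read in units of the period.
#' @param window Optional analysis window `c(t0, t1)` in seconds; defaults to
#'   the steady-state portion of a 100-ms stimulus with 10-ms ramps (onset
#'   and offset transients otherwise dominate the mean-subtracted ACF).
#' @return An object of class `autocorrelogram`: `cfs`, `lags` (s),
#'   `lags_re_period` (if `target_period` given), `acf` (CF x lag), `sacf`.
#' @export
autocorrelogram <- function(wave, cfs, frontend = make_frontend(), max_lag,
                            fiber_class = "hsr", target_period = NULL,
                            window = c(0.01, wave$duration - 0.01)) {
  stopifnot(wave$duration >= 2 * max_lag)
  pop <- population_spec(cfs, 1, fiber_class)
  resp <- frontend$simulate(wave, pop)
  if (!is.null(window)) {
    keep <- resp$times >= window[1] & resp$times <= window[2]
    stopifnot(diff(window) >= 2 * max_lag)
    resp$rates <- resp$rates[, keep, drop = FALSE]
    resp$times <- resp$times[keep]
  }
  fs <- 1 / (resp$times[2] - resp$times[1])
  nl <- floor(max_lag * fs) + 1
  nt <- ncol(resp$rates)
  A <- matrix(NA_real_, length(cfs), nl)
  for (j in seq_len(length(cfs))) {
    r <- resp$rates[j, ]
    rc <- r - mean(r)
    v <- sum(rc^2)
    if (v > 1e-9 * nt * mean(r)^2) {
      # FFT-based autocovariance, normalized to 1 at lag 0
      npad <- 2^ceiling(log2(2 * nt))
      sp <- stats::fft(c(rc, numeric(npad - nt)))
      ac <- Re(stats::fft(sp * Conj(sp), inverse = TRUE))[seq_len(nl)] / npad
      A[j, ] <- ac / ac[1]
    } else {
      # degenerate constant response: raw-product normalization (flat ~ 1)
      denom <- sum(r^2)
      A[j, ] <- vapply(seq_len(nl) - 1L, function(l) {
        sum(r[seq_len(nt - l)] * r[seq_len(nt - l) + l]) / denom * nt / (nt - l)
      }, numeric(1))
    }
  }
  lags <- (seq_len(nl) - 1) / fs
  structure(list(cfs = cfs, lags = lags,
                 lags_re_period = if (!is.null(target_period))
                   lags / target_period else NULL,
                 acf = A, sacf = colSums(A),
                 target_period = target_period),
            class = "autocorrelogram")
}

#' Scalar salience of the temporal F0 cue in a summary autocorrelation
#'
#' Excess height of the sACF at the target-period lag over the local median
#' (lags in `[0.5, 1.5]` x period), expressed per CF:
#' `(sacf(period) - median) / n_cf`. Because the sACF sums mean-subtracted,
#' variance-normalized ACFs its local baseline sits near zero, so the excess
#' is normalized by the number of CFs (the sACF's scale) rather than divided
#' by the near-zero baseline itself. A flat sACF gives 0; a ridge of perfectly
#' period-locked CFs approaches 1.
#'
#' @param acg An `autocorrelogram`.
#' @param period Target period, s (must lie within the lag range).
#' @return Dimensionless salience.
#' @export
temporal_cue_salience <- function(acg, period) {
  stopifnot(period <= max(acg$lags), period >= min(acg$lags))
  peak <- stats::approx(acg$lags, acg$sacf, xout = period)$y
  loc <- acg$lags >= 0.5 * period & acg$lags <= 1.5 * period
  med <- stats::median(acg$sacf[loc])
  (peak - med) / length(acg$cfs)
}

#' Stimulus builder for the harmonic-complex view conventions
#'
#' Returns a `seed -> waveform` function producing the bandpass-filtered
#' harmonic complex at 50 dB SPL per component (level roved +/- 3 dB per
#' component per realisation), optionally with DBL maskers at a given TMR,
#' embedded in fresh TEN at 40 dB SPL in the ERB at 1 kHz.
#'
#' @param f0 Target F0, Hz.
#' @param fs Sample rate, Hz.
#' @param tmr Target-to-masker ratio, dB (`Inf` for no masker).
#' @param masker_offsets_st DBL masker offsets in semitones
#'   (default `c(-5.5, 6)`).
#' @param level Nominal level per component, dB SPL (default 50).
#' @param ten_level TEN level in the ERB at 1 kHz, dB SPL (default 40;
#'   `NULL` disables the noise).
#' @param duration Stimulus duration, s.
#' @param rove A `rove_spec` (level roving only is applied).
#' @return Function `seed -> waveform`.
#' @export
hct_view_builder <- function(f0, fs, tmr = Inf,
                             masker_offsets_st = c(-5.5, 6),
                             level = 50, ten_level = 40, duration = 0.1,
                             rove = rove_spec(phase_range = 0)) {
  target <- tone_spec("hct_filtered", f0, level = level, duration = duration)
  masker <- if (is.finite(tmr))
    masker_spec("DBL", dbl_masker_f0s(f0, masker_offsets_st), tmr = tmr)
  else NULL
  function(seed) {
    roved <- apply_rove(target, rove, derive_seed(seed, "rove"))
    make_masked_stimulus(roved, masker, ten_level, fs,
                         seed = derive_seed(seed, "noise"))
  }
}
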