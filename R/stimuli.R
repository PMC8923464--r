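# Stimulus synthesis: calibrated pure tones, harmonic complex tones (discrete
# and bandpass-filtered), threshold-equalizing noise, and masker mixtures.
# All pressures are in pascals; levels in dB SPL re 20 uPa; phases are radians
# internally and degrees at user-facing interfaces.

P_REF <- 20e-6 # Pa, reference pressure for dB SPL

#' Equivalent rectangular bandwidth of the human auditory filter
#'
#' ERB(f) = 24.7 (4.37 f/1000 + 1), with f in Hz.
#'
#' @param f Frequency in Hz.
#' @return Bandwidth in Hz.
#' @export
erb_bw <- function(f) 24.7 * (4.37 * f / 1000 + 1)

#' Construct a tone specification
#'
#' A `tone_spec` describes a pure tone (`kind = "pure"`), a harmonic complex
#' tone with an explicit harmonic set (`kind = "hct_discrete"`), or a complex
#' containing all harmonics up to Nyquist passed through a zero-phase
#' Butterworth bandpass (`kind = "hct_filtered"`).
#'
#' @param kind One of `"pure"`, `"hct_discrete"`, `"hct_filtered"`.
#' @param f_or_f0 Tone frequency (pure) or fundamental frequency F0 in Hz.
#' @param harmonics Integer harmonic numbers (discrete complexes only),
#'   strictly increasing. Ignored for filtered complexes, which include every
#'   harmonic up to Nyquist.
#' @param level Level per component in dB SPL (scalar, recycled, or one per
#'   component). For filtered complexes this is the pre-filter level of each
#'   harmonic.
#' @param phase Starting phase per component in degrees (sine convention;
#'   0 gives sin(2 pi f t)).
#' @param duration Total duration in seconds, including ramps.
#' @param ramp Raised-cosine on/off ramp duration in seconds.
#' @param filter_cutoffs Bandpass cutoffs as multiples of the nominal F0
#'   (filtered complexes), default `c(5.5, 10.5)`.
#' @param filter_order Butterworth design order (poles of the analog
#'   prototype) applied forward and backward (zero phase), default 12.
#' @param nominal_f0 Nominal F0 anchoring the filter cutoffs; defaults to
#'   `f_or_f0`. The filter stays put when F0 is perturbed, as in a roved or
#'   discriminated stimulus.
#' @return An object of class `tone_spec`.
#' @export
tone_spec <- function(kind = c("pure", "hct_discrete", "hct_filtered"),
                      f_or_f0, harmonics = NULL, level = 50, phase = 0,
                      duration = 0.1, ramp = 0.01,
                      filter_cutoffs = c(5.5, 10.5), filter_order = 12,
                      nominal_f0 = f_or_f0) {
  kind <- match.arg(kind)
  stopifnot(f_or_f0 > 0, duration > 2 * ramp, ramp >= 0)
  if (kind == "pure") harmonics <- 1L
  if (kind == "hct_discrete") {
    stopifnot(!is.null(harmonics), all(harmonics >= 1),
              all(diff(harmonics) > 0))
    harmonics <- as.integer(harmonics)
  }
  spec <- structure(list(kind = kind, f_or_f0 = f_or_f0,
                         harmonics = harmonics, level = level, phase = phase,
                         duration = duration, ramp = ramp,
                         filter_cutoffs = filter_cutoffs,
                         filter_order = filter_order,
                         nominal_f0 = nominal_f0),
                    class = "tone_spec")
  spec
}

#' Roving specification for component levels and phases
#'
#' Synthesis draws component levels uniformly within `level_halfwidth` dB of
#' nominal and phases uniformly over `phase_range` degrees. For the observer
#' math the same roves are treated as normal with `eval_level_sd` /
#' `eval_phase_sd` (the standard normal approximation to the uniform rove).
#'
#' @param level_halfwidth Half-width of the uniform level rove, dB (default 3).
#' @param phase_range Width of the uniform phase rove, degrees (default 360).
#' @param eval_level_sd Normal-approximation SD used in the prior-information
#'   matrix, dB (default 6).
#' @param eval_phase_sd Normal-approximation SD for phase, degrees
#'   (default 360).
#' @return An object of class `rove_spec`.
#' @export
rove_spec <- function(level_halfwidth = 3, phase_range = 360,
                      eval_level_sd = 6, eval_phase_sd = 360) {
  stopifnot(level_halfwidth >= 0, phase_range >= 0,
            eval_level_sd > 0, eval_phase_sd > 0)
  structure(list(level_halfwidth = level_halfwidth, phase_range = phase_range,
                 eval_level_sd = eval_level_sd, eval_phase_sd = eval_phase_sd),
            class = "rove_spec")
}

#' Apply a level/phase rove to a tone specification
#'
#' Returns a new spec whose per-component levels are perturbed by independent
#' uniform draws in +/- `level_halfwidth` dB and whose phases are offset by
#' independent uniform draws spanning `phase_range` degrees. The nominal spec
#' is untouched.
#'
#' @param spec A `tone_spec`.
#' @param rove A `rove_spec`.
#' @param seed Integer seed driving the draws (required: all roving is
#'   seeded).
#' @return A roved `tone_spec`.
#' @export
apply_rove <- function(spec, rove, seed) {
  stopifnot(inherits(spec, "tone_spec"), inherits(rove, "rove_spec"))
  n <- n_components(spec)
  with_seed(seed, {
    lev <- rep_len(spec$level, n) +
      if (rove$level_halfwidth > 0)
        stats::runif(n, -rove$level_halfwidth, rove$level_halfwidth) else 0
    ph <- rep_len(spec$phase, n) +
      if (rove$phase_range > 0)
        stats::runif(n, -rove$phase_range / 2, rove$phase_range / 2) else 0
    out <- spec
    out$level <- lev
    out$phase <- ph
    out
  })
}

# number of synthesized components of a spec (filtered complexes count all
# harmonics up to a generous Nyquist guard; resolved at synthesis time)
n_components <- function(spec, fs = NULL) {
  if (spec$kind == "hct_filtered") {
    nyq <- if (is.null(fs)) 50e3 else fs / 2
    max(1L, floor((nyq - 1e-9) / spec$f_or_f0))
  } else {
    length(spec$harmonics)
  }
}

#' Zero-phase Butterworth bandpass amplitude gain
#'
#' Amplitude response of an analog Butterworth bandpass prototype of order
#' `order` applied forward and backward (so the gain is the squared magnitude
#' of a single pass and the phase is identically zero).
#'
#' @param f Frequencies at which to evaluate the gain, Hz.
#' @param f_lo,f_hi Band edges (3-dB points of the single pass), Hz.
#' @param order Number of analog poles of the single-pass design.
#' @return Amplitude gain (linear), zero phase.
#' @export
butter_bp_gain <- function(f, f_lo, f_hi, order = 12) {
  stopifnot(f_lo > 0, f_hi > f_lo)
  # lowpass-to-bandpass mapping: Omega = (f^2 - f_lo*f_hi) / (f * (f_hi - f_lo))
  om <- ifelse(f > 0, (f^2 - f_lo * f_hi) / (f * (f_hi - f_lo)), Inf)
  (1 / (1 + om^(2 * order)))  # |H|^2 of the single pass = two-pass amplitude
}

raised_cosine_window <- function(n, fs, ramp) {
  if (ramp <= 0) return(rep(1, n))
  t <- (seq_len(n) - 1) / fs
  dur <- (n - 1) / fs
  w <- rep(1, n)
  on <- t < ramp
  off <- t > dur - ramp
  w[on] <- 0.5 - 0.5 * cos(pi * t[on] / ramp)
  w[off] <- 0.5 - 0.5 * cos(pi * (dur - t[off]) / ramp)
  w
}

new_waveform <- function(samples, fs) {
  structure(list(samples = samples, fs = fs,
                 duration = length(samples) / fs),
            class = "waveform")
}

#' Synthesize the waveform described by a tone specification
#'
#' Pure tones and discrete complexes are sums of calibrated sinusoids
#' (component RMS = 20 uPa x 10^(level/20)) with raised-cosine ramps applied
#' after summation. Filtered complexes contain all harmonics up to Nyquist,
#' each scaled by the zero-phase Butterworth gain at its frequency (the exact
#' zero-phase filter response for stationary sinusoids); harmonics attenuated
#' by more than 100 dB are omitted as numerically negligible.
#'
#' @param spec A `tone_spec`.
#' @param fs Sample rate, Hz.
#' @return A `waveform`.
#' @export
synth_tone <- function(spec, fs) {
  stopifnot(inherits(spec, "tone_spec"), fs > 0)
  n <- round(spec$duration * fs)
  t <- (seq_len(n) - 1) / fs
  if (spec$kind == "hct_filtered") {
    nh <- n_components(spec, fs)
    h <- seq_len(nh)
    freqs <- h * spec$f_or_f0
    gain <- butter_bp_gain(freqs,
                           spec$filter_cutoffs[1] * spec$nominal_f0,
                           spec$filter_cutoffs[2] * spec$nominal_f0,
                           spec$filter_order)
    keep <- gain > 10^(-100 / 20)
    freqs <- freqs[keep]
    gain <- gain[keep]
    lev <- rep_len(spec$level, nh)[keep]
    ph <- rep_len(spec$phase, nh)[keep] * pi / 180
  } else {
    freqs <- spec$harmonics * spec$f_or_f0
    gain <- rep(1, length(freqs))
    lev <- rep_len(spec$level, length(freqs))
    ph <- rep_len(spec$phase, length(freqs)) * pi / 180
  }
  if (any(freqs >= fs / 2)) {
    stop("component frequency at or above Nyquist (", fs / 2, " Hz); ",
         "raise the sample rate or lower the frequency")
  }
  amp <- sqrt(2) * P_REF * 10^(lev / 20) * gain
  x <- numeric(n)
  for (k in seq_along(freqs)) {
    x <- x + amp[k] * sin(2 * pi * freqs[k] * t + ph[k])
  }
  x <- x * raised_cosine_window(n, fs, spec$ramp)
  new_waveform(x, fs)
}

#' Threshold-equalizing noise (TEN)
#'
#' Gaussian noise spectrally shaped with power spectral density proportional
#' to 1/ERB(f), so that the power passing an ERB-wide filter is approximately
#' constant across centre frequency. The noise is scaled so that the power in
#' the ERB-wide band centred on 1 kHz corresponds to `level_in_erb_1k` dB SPL.
#'
#' @param level_in_erb_1k Level in dB SPL within the ERB at 1 kHz.
#' @param duration Noise duration in seconds (excluding lead/lag extension).
#' @param fs Sample rate, Hz.
#' @param seed Integer seed (required; same seed gives identical samples).
#' @param lead_lag Extra noise duration added before and after, seconds.
#' @param ramp Raised-cosine ramp, seconds.
#' @param f_min Low-frequency edge of the noise band, Hz (default 50).
#' @return A `waveform` of duration `duration + 2 * lead_lag`.
#' @export
synth_ten <- function(level_in_erb_1k, duration, fs, seed,
                      lead_lag = 0, ramp = 0.02, f_min = 50) {
  stopifnot(duration > 0, lead_lag >= 0)
  n <- round((duration + 2 * lead_lag) * fs)
  nf <- 2^ceiling(log2(n))
  df <- fs / nf
  f <- df * (0:(nf / 2))
  # target: integral of S over [1000 - ERB/2, 1000 + ERB/2] = p_band^2
  p_band2 <- (P_REF * 10^(level_in_erb_1k / 20))^2
  half <- erb_bw(1000) / 2
  fg <- seq(1000 - half, 1000 + half, length.out = 513)
  c0 <- p_band2 / trapz(fg, 1 / erb_bw(fg))
  s <- ifelse(f >= f_min & f < fs / 2, c0 / erb_bw(f), 0)
  x <- with_seed(seed, {
    a <- stats::rnorm(nf / 2 + 1)
    b <- stats::rnorm(nf / 2 + 1)
    xk <- sqrt(s * fs * nf / 4) * complex(real = a, imaginary = b)
    xk[1] <- 0
    xk[nf / 2 + 1] <- complex(real = Re(xk[nf / 2 + 1]), imaginary = 0)
    xf <- c(xk, Conj(rev(xk[2:(nf / 2)])))
    Re(stats::fft(xf, inverse = TRUE)) / nf
  })
  x <- x[seq_len(n)] * raised_cosine_window(n, fs, ramp)
  new_waveform(x, fs)
}

#' Masker specification for complex-tone masker conditions
#'
#' `GEOM` is a single masker at the geometric mean of the reference and target
#' F0s, synthesized like the target but with a broader passband (4-12 x
#' nominal F0 for filtered stimuli) or with harmonics 5 and 11 added (discrete
#' stimuli). `DBL` is a pair of maskers flanking the target F0 by semitone
#' offsets of opposite sign.
#'
#' @param kind `"GEOM"` or `"DBL"`.
#' @param masker_f0s Masker F0(s) in Hz: one for GEOM, two for DBL.
#' @param tmr Target-to-masker ratio in dB (`Inf` disables the masker).
#' @param filter_cutoffs Masker passband in multiples of nominal F0
#'   (filtered variant), default `c(4, 12)`.
#' @return An object of class `masker_spec`.
#' @export
masker_spec <- function(kind = c("GEOM", "DBL"), masker_f0s, tmr = 0,
                        filter_cutoffs = c(4, 12)) {
  kind <- match.arg(kind)
  if (kind == "GEOM") stopifnot(length(masker_f0s) == 1)
  if (kind == "DBL") stopifnot(length(masker_f0s) == 2)
  structure(list(kind = kind, masker_f0s = masker_f0s, tmr = tmr,
                 filter_cutoffs = filter_cutoffs),
            class = "masker_spec")
}

#' DBL masker F0s from semitone offsets
#'
#' @param target_f0 Target F0, Hz.
#' @param offsets_st Two semitone offsets of opposite sign, e.g. `c(-5.5, 6)`.
#' @return Masker F0s in Hz (`target_f0 * 2^(offset/12)`).
#' @export
dbl_masker_f0s <- function(target_f0, offsets_st = c(-5.5, 6)) {
  stopifnot(length(offsets_st) == 2, prod(sign(offsets_st)) < 0)
  target_f0 * 2^(offsets_st / 12)
}

#' Build a masked stimulus: target + attenuated masker(s) + TEN
#'
#' The output is the sample-wise sum of the independently synthesized parts.
#' Maskers are synthesized like the target (same duration, level per
#' component, filter order) but with their own F0 and the broader masker
#' passband, then attenuated by the TMR. Tones are temporally centred in the
#' noise when the noise has a lead/lag.
#'
#' @param target A `tone_spec` for the target.
#' @param masker A `masker_spec`, or `NULL` for no masker.
#' @param noise_level TEN level (dB SPL in the ERB at 1 kHz), or `NULL` for
#'   no noise.
#' @param fs Sample rate, Hz.
#' @param seed Integer seed for the noise (and any masker phase roving done
#'   upstream).
#' @param noise_lead_lag Noise lead/lag in seconds (default 0).
#' @return A `waveform`.
#' @export
make_masked_stimulus <- function(target, masker = NULL, noise_level = NULL,
                                 fs, seed = 1, noise_lead_lag = 0) {
  tw <- synth_tone(target, fs)
  x_tone <- tw$samples
  if (!is.null(masker) && is.finite(masker$tmr)) {
    g <- 10^(-masker$tmr / 20)
    for (mf0 in masker$masker_f0s) {
      mspec <- target
      mspec$f_or_f0 <- mf0
      if (target$kind == "hct_filtered" && masker$kind == "GEOM") {
        # GEOM masker: slightly broader passband, anchored on the target F0
        mspec$filter_cutoffs <- masker$filter_cutoffs
        mspec$nominal_f0 <- target$nominal_f0
      } else if (target$kind == "hct_filtered" && masker$kind == "DBL") {
        # DBL maskers: synthesized like the target, band anchored on their
        # own nominal F0
        mspec$nominal_f0 <- mf0
      } else if (target$kind == "hct_discrete" && masker$kind == "GEOM") {
        mspec$harmonics <- sort(unique(c(min(target$harmonics) - 1L,
                                         target$harmonics,
                                         max(target$harmonics) + 1L)))
      }
      x_tone <- x_tone + g * synth_tone(mspec, fs)$samples
    }
  }
  if (is.null(noise_level)) return(new_waveform(x_tone, fs))
  nz <- synth_ten(noise_level, tw$duration, fs, seed = seed,
                  lead_lag = noise_lead_lag)
  x <- nz$samples
  i0 <- round(noise_lead_lag * fs)
  x[i0 + seq_along(x_tone)] <- x[i0 + seq_along(x_tone)] + x_tone
  new_waveform(x, fs)
}

#' Export a waveform as a 32-bit float WAV file with a calibration sidecar
#'
#' Samples are written in pascals divided by `full_scale_pa`; the sidecar JSON
#' (`<path>.json`) records the calibration constant so that digital full scale
#' maps back to pascals.
#'
#' @param wave A `waveform`.
#' @param path Output path (`.wav`).
#' @param full_scale_pa Pressure in Pa mapped to digital full scale (1.0).
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path, full_scale_pa = 1) {
  x <- wave$samples / full_scale_pa
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(x) * 4L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")   # IEEE float
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(wave$fs), con, size = 4, endian = "little")
  writeBin(as.integer(wave$fs * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(x, con, size = 4, endian = "little")
  jsonlite::write_json(list(full_scale_pa = full_scale_pa,
                            sample_rate = wave$fs,
                            duration = wave$duration),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

# trapezoidal integral of y over x
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
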