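# FDL / F0DL simulation protocols: build frequency grids, run the
# all-information and rate-place observers at levels set relative to the
# calibrated rate-level thresholds, smooth thresholds with LOESS on log-log
# coordinates, and form high/low-frequency threshold ratios.

#' Experiment grid for FDL or F0DL simulations
#'
#' FDL runs place 40 CFs log-spaced over 0.5-1.5 x the tone frequency with 72
#' fibers per CF (approximately 3000 HSR fibers near the tone); F0DL runs
#' place 40 CFs over 5-11 x F0 with 51 fibers per CF.
#'
#' @param task `"FDL"` or `"F0DL"`.
#' @param frequencies Tone frequencies (FDL) or F0s (F0DL), Hz.
#' @param levels Levels re: threshold, dB (F0DL: per component re: the
#'   threshold at the 8th harmonic).
#' @param roving `"none"`, `"level"` or `"phase"`.
#' @param n_cf Number of CFs (default 40).
#' @param fibers_per_cf Fibers sharing each CF (default 72 for FDL, 51 for
#'   F0DL).
#' @param cf_span CF range as multiples of the grid frequency (defaults
#'   `c(0.5, 1.5)` for FDL, `c(5, 11)` for F0DL).
#' @return An object of class `experiment_grid`.
#' @export
experiment_grid <- function(task = c("FDL", "F0DL"), frequencies,
                            levels = 30, roving = c("none", "level", "phase"),
                            n_cf = 40,
                            fibers_per_cf = if (task == "FDL") 72 else 51,
                            cf_span = if (task == "FDL") c(0.5, 1.5)
                                      else c(5, 11)) {
  task <- match.arg(task)
  roving <- match.arg(roving)
  stopifnot(all(frequencies > 0), all(diff(frequencies) > 0) ||
              length(frequencies) == 1, n_cf >= 2, fibers_per_cf >= 1)
  structure(list(task = task, frequencies = sort(frequencies),
                 levels = levels, roving = roving, n_cf = n_cf,
                 fibers_per_cf = fibers_per_cf, cf_span = cf_span),
            class = "experiment_grid")
}

#' Desk-scale and full grid presets
#'
#' The desk preset uses 9 log-spaced frequencies (1.4-14 kHz for FDL,
#' 0.18-1.8 kHz for F0DL) at 30 dB re: threshold; the full preset uses 24
#' frequencies and three levels (20/30/40 dB re: threshold).
#'
#' @param task `"FDL"` or `"F0DL"`.
#' @param preset `"desk"` or `"full"`.
#' @param roving Roving condition passed through.
#' @return An `experiment_grid`.
#' @export
grid_preset <- function(task = c("FDL", "F0DL"), preset = c("desk", "full"),
                        roving = "none") {
  task <- match.arg(task)
  preset <- match.arg(preset)
  rng <- if (task == "FDL") c(1400, 14000) else c(180, 1800)
  n <- if (preset == "desk") 9 else 24
  levels <- if (preset == "desk") 30 else c(20, 30, 40)
  freqs <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = n)
  experiment_grid(task, freqs, levels = levels, roving = roving)
}

# harmonics of a filtered complex whose post-filter level is within
# `window_db` of the passband maximum (the nuisance set for roved runs)
nuisance_harmonics <- function(f0, cutoffs = c(5.5, 10.5), order = 12,
                               window_db = 40, fs = 100e3) {
  h <- seq_len(floor((fs / 2 - 1) / f0))
  g <- butter_bp_gain(h * f0, cutoffs[1] * f0, cutoffs[2] * f0, order)
  h[20 * log10(g) > 20 * log10(max(g)) - window_db]
}

# builder + param spec for one grid point; returns list(builder, pspec,
# theta0, baseline)
dl_task_setup <- function(grid, freq, level_spl, fs, rove) {
  if (grid$task == "FDL") {
    base_theta <- freq
    nms <- "f"; units <- "Hz"; steps <- 1e-4 * freq
    prior <- Inf; rhalf <- 0
    if (grid$roving == "level") {
      nms <- c("f", "level"); units <- c("Hz", "dB")
      base_theta <- c(freq, level_spl)
      steps <- c(steps, 0.25)
      prior <- c(Inf, rove$eval_level_sd)
      rhalf <- c(0, rove$level_halfwidth)
    } else if (grid$roving == "phase") {
      nms <- c("f", "phase"); units <- c("Hz", "rad")
      base_theta <- c(freq, 0)
      steps <- c(steps, pi / 180)
      prior <- c(Inf, rove$eval_phase_sd * pi / 180)
      rhalf <- c(0, rove$phase_range / 2 * pi / 180)
    }
    builder <- function(theta) {
      lev <- if (grid$roving == "level") theta[2] else level_spl
      ph <- if (grid$roving == "phase") theta[2] * 180 / pi else 0
      synth_tone(tone_spec("pure", theta[1], level = lev, phase = ph), fs)
    }
  } else {
    nuis <- nuisance_harmonics(freq, fs = fs)
    nn <- length(nuis)
    base_theta <- freq
    nms <- "f0"; units <- "Hz"; steps <- 1e-4 * freq
    prior <- Inf; rhalf <- 0
    if (grid$roving == "level") {
      nms <- c("f0", paste0("L", nuis)); units <- c("Hz", rep("dB", nn))
      base_theta <- c(freq, rep(level_spl, nn))
      steps <- c(steps, rep(0.25, nn))
      prior <- c(Inf, rep(rove$eval_level_sd, nn))
      rhalf <- c(0, rep(rove$level_halfwidth, nn))
    } else if (grid$roving == "phase") {
      nms <- c("f0", paste0("phi", nuis)); units <- c("Hz", rep("rad", nn))
      base_theta <- c(freq, rep(0, nn))
      steps <- c(steps, rep(pi / 180, nn))
      prior <- c(Inf, rep(rove$eval_phase_sd * pi / 180, nn))
      rhalf <- c(0, rep(rove$phase_range / 2 * pi / 180, nn))
    }
    n_harm <- floor((fs / 2 - 1) / freq)
    builder <- function(theta) {
      lev <- rep(level_spl, n_harm)
      ph <- rep(0, n_harm)
      if (grid$roving == "level") lev[nuis] <- theta[-1]
      if (grid$roving == "phase") ph[nuis] <- theta[-1] * 180 / pi
      synth_tone(tone_spec("hct_filtered", theta[1], level = lev, phase = ph,
                           nominal_f0 = freq), fs)
    }
  }
  pspec <- param_spec(nms, units, target = 1, prior_sd = prior,
                      rove_half = rhalf, step = steps)
  list(builder = builder, pspec = pspec, theta0 = base_theta)
}

#' Run an FDL or F0DL simulation over a grid
#'
#' For each grid frequency and level, synthesizes the 100-ms stimulus (pure
#' tone with starting phase 0, or the bandpass-filtered complex in sine
#' phase), sets the presentation level relative to the calibrated rate-level
#' threshold (at the stimulus frequency for FDL; at the 8th harmonic for
#' F0DL), computes the expected Fisher matrix plus prior information, inverts,
#' and returns thresholds for the requested observers.
#'
#' @param grid An `experiment_grid`.
#' @param frontend A `frontend` (default reference configuration).
#' @param cal_map A `threshold_map` (computed from the front end if omitted).
#' @param observers Subset of `c("all_information", "rate_place")`.
#' @param n_draws Monte-Carlo draws for the expectation over roved
#'   parameters (ignored for non-roved runs).
#' @param seed Integer seed (expanded into independent per-grid-point
#'   streams).
#' @param rove A `rove_spec` giving rove widths and evaluation SDs.
#' @return A tidy data frame (class `threshold_curve`): task, frequency,
#'   level_re_thr, level_spl, observer, roving, jnd (Hz), jnd_rel_pct,
#'   flagged (TRUE where the information matrix was singular), seed.
#' @export
run_discrimination <- function(grid, frontend = make_frontend(),
                               cal_map = NULL,
                               observers = c("all_information", "rate_place"),
                               n_draws = 4, seed = 1, rove = rove_spec()) {
  stopifnot(inherits(grid, "experiment_grid"))
  observers <- match.arg(observers, several.ok = TRUE)
  if (is.null(cal_map)) cal_map <- calibrate_thresholds(frontend)
  fs <- frontend$config$fs
  rows <- list()
  for (freq in grid$frequencies) {
    cfs <- 10^seq(log10(grid$cf_span[1] * freq),
                  log10(grid$cf_span[2] * freq), length.out = grid$n_cf)
    pop <- population_spec(cfs, grid$fibers_per_cf, "hsr")
    for (lev in grid$levels) {
      cal_freq <- if (grid$task == "FDL") freq else 8 * freq
      level_spl <- level_re_threshold(cal_freq, lev, cal_map)
      setup <- dl_task_setup(grid, freq, level_spl, fs, rove)
      rate_fn <- make_rate_fn(setup$builder, pop, frontend)
      point_seed <- derive_seed(seed, paste(grid$task, freq, lev, grid$roving))
      for (obs in observers) {
        fn <- if (obs == "rate_place") rate_place_fn(rate_fn) else rate_fn
        res <- tryCatch({
          EI <- expected_fisher(fn, setup$pspec, setup$theta0,
                                n_draws = n_draws, seed = point_seed)
          v <- crlb_variance(EI, prior_info(setup$pspec), setup$pspec$target)
          threshold_from_variance(v, baseline = freq)
        }, error = function(e) NULL)
        rows[[length(rows) + 1]] <- data.frame(
          task = grid$task, frequency = freq, level_re_thr = lev,
          level_spl = level_spl, observer = obs, roving = grid$roving,
          jnd = if (is.null(res)) NA_real_ else res$jnd,
          jnd_rel_pct = if (is.null(res)) NA_real_ else res$jnd_rel_pct,
          flagged = is.null(res), seed = seed)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("threshold_curve", "data.frame")
  out
}

#' @rdname run_discrimination
#' @export
run_fdl <- function(grid, ...) {
  stopifnot(grid$task == "FDL")
  run_discrimination(grid, ...)
}

#' @rdname run_discrimination
#' @export
run_f0dl <- function(grid, ...) {
  stopifnot(grid$task == "F0DL")
  run_discrimination(grid, ...)
}

# LOESS fit of log10(relative jnd) vs log10(frequency) for one observer/level
loess_log_fit <- function(curve, observer, level = NULL, span = NULL) {
  d <- curve[curve$observer == observer & !curve$flagged, ]
  if (!is.null(level)) d <- d[d$level_re_thr == level, ]
  if (nrow(d) < 4) stop("too few grid points for a LOESS fit")
  if (is.null(span)) span <- if (nrow(d) >= 16) 0.5 else 0.75
  stats::loess(log10(jnd_rel_pct) ~ log10(frequency), data = d,
               span = span, degree = 2, surface = "direct",
               control = stats::loess.control(iterations = 1))
}

#' LOESS-interpolated threshold ratio between two frequencies
#'
#' Fits LOESS to log threshold (relative units, Delta/baseline) versus log
#' frequency for one observer and level, and returns the ratio of the
#' interpolated thresholds at `f_hi` and `f_lo`. Requests outside the grid
#' span are rejected (interpolation only).
#'
#' @param curve A `threshold_curve` from [run_discrimination()].
#' @param f_hi,f_lo Anchor frequencies, Hz (defaults: 8.5/2.0 kHz for FDL,
#'   1.4/0.28 kHz for F0DL).
#' @param observer Observer to summarise (default `"all_information"`).
#' @param level Level re: threshold to summarise (default: the only level
#'   present, else 30).
#' @param span LOESS span (default 0.5, widened to 0.75 for grids under 16
#'   points).
#' @return The dimensionless threshold ratio jnd(f_hi)/jnd(f_lo).
#' @export
threshold_ratio <- function(curve, f_hi = NULL, f_lo = NULL,
                            observer = "all_information", level = NULL,
                            span = NULL) {
  task <- curve$task[1]
  if (is.null(f_hi)) f_hi <- if (task == "FDL") 8500 else 1400
  if (is.null(f_lo)) f_lo <- if (task == "FDL") 2000 else 280
  if (is.null(level)) {
    levs <- unique(curve$level_re_thr)
    level <- if (length(levs) == 1) levs else 30
  }
  rng <- range(curve$frequency)
  if (f_hi < rng[1] || f_hi > rng[2] || f_lo < rng[1] || f_lo > rng[2]) {
    stop("anchor frequency outside the simulated grid span (no extrapolation)")
  }
  fit <- loess_log_fit(curve, observer, level, span)
  pred <- stats::predict(fit, data.frame(frequency = c(f_hi, f_lo)))
  10^(pred[1] - pred[2])
}

#' Per-frequency effect of roving: threshold ratio roved / fixed
#'
#' @param curve_roved,curve_fixed Matching `threshold_curve`s (same task,
#'   frequencies, levels and observers; different roving condition).
#' @return A data frame with the element-wise jnd ratio per frequency, level
#'   and observer.
#' @export
roving_effect <- function(curve_roved, curve_fixed) {
  key <- c("task", "frequency", "level_re_thr", "observer")
  m <- merge(curve_roved[, c(key, "jnd", "roving")],
             curve_fixed[, c(key, "jnd")],
             by = key, suffixes = c("_roved", "_fixed"))
  if (nrow(m) != nrow(curve_roved)) {
    stop("grids do not match between the roved and fixed curves")
  }
  m$ratio <- m$jnd_roved / m$jnd_fixed
  m[order(m$observer, m$frequency, m$level_re_thr), ]
}
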