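# Reference front end: spontaneous-rate floor, rate bounds, determinism,
# phase-locking rolloff, saturation contrast between fiber classes,
# rate-level calibration, vector strength, Q10 and the plug-in contract.

test_that("silence yields the spontaneous rate; rates stay within bounds", {
  cfg <- frontend_config()
  silence <- synth_tone(tone_spec("pure", 1000, level = -400), cfg$fs)
  pop <- population_spec(c(500, 2000, 8000), 1, c("hsr", "msr", "lsr"))
  resp <- simulate_rates(silence, pop, cfg)
  expect_equal(resp$rates[1, ], rep(cfg$spont[["hsr"]], ncol(resp$rates)),
               tolerance = 1e-6)
  expect_equal(resp$rates[2, ], rep(cfg$spont[["msr"]], ncol(resp$rates)),
               tolerance = 1e-6)
  expect_equal(resp$rates[3, ], rep(cfg$spont[["lsr"]], ncol(resp$rates)),
               tolerance = 1e-6)

  loud <- synth_tone(tone_spec("pure", 2000, level = 70), cfg$fs)
  r <- simulate_rates(loud, population_spec(c(1500, 2000), 1, "hsr"), cfg)
  expect_true(all(r$rates >= cfg$spont[["hsr"]] - 1e-9))
  expect_true(all(r$rates <= cfg$max_rate + 1e-9))
  # pure function of (waveform, config)
  r2 <- simulate_rates(loud, population_spec(c(1500, 2000), 1, "hsr"), cfg)
  expect_identical(r$rates, r2$rates)
  expect_error(simulate_rates(loud, population_spec(6e4, 1, "hsr"), cfg),
               "Nyquist")
})

test_that("phase locking rolls off above the cutoff and vanishes by 3x", {
  cfg <- frontend_config()
  map <- ref_cal_map()
  freqs <- c(4800, 6500, 9000, 14400)
  vs <- vapply(freqs, function(f)
    oncf_vector_strength(f, level_re_threshold(f, 30, map), cfg), numeric(1))
  expect_true(all(diff(vs) < 0))                  # non-increasing above cutoff
  expect_lt(vs[length(vs)], 0.1)                  # negligible at 3x cutoff
  # strong phase locking well below the cutoff
  expect_gt(oncf_vector_strength(1000, level_re_threshold(1000, 30, map),
                                 cfg), 0.1)
})

test_that("HSR fibers saturate at 50 dB SPL per component; LSR do not", {
  cfg <- frontend_config()
  for (f0 in c(280, 1400)) {
    wv <- synth_tone(tone_spec("hct_discrete", f0, harmonics = 6:10,
                               level = 50), cfg$fs)
    on_cf <- c(7, 8, 9) * f0
    hsr <- steady_rate(simulate_rates(wv, population_spec(on_cf, 1, "hsr"),
                                      cfg))
    lsr <- steady_rate(simulate_rates(wv, population_spec(on_cf, 1, "lsr"),
                                      cfg))
    expect_true(all(hsr >= 0.9 * cfg$max_rate))
    expect_true(all(lsr < 0.9 * cfg$max_rate))
  }
})

test_that("rate-level calibration inverts a closed-form front end", {
  # synthetic adapter whose mean rate is analytic in level:
  # r(t) = spont * (1 + g * rms(p)), so threshold solves g * rms = 0.05
  spont <- 50; g <- 40
  adapter <- list(simulate = function(wave, population) {
    r <- spont * (1 + g * sqrt(mean(wave$samples^2)))
    structure(list(rates = matrix(r, length(population$cfs),
                                  length(wave$samples)),
                   times = (seq_along(wave$samples) - 1) / wave$fs,
                   cfs = population$cfs, k = population$fibers_per_cf,
                   spont = rep(spont, length(population$cfs)),
                   duration = wave$duration),
              class = "rate_response")
  }, config = list(fs = 20e3))
  map <- calibrate_thresholds(adapter, freqs = c(500, 1000),
                              levels = seq(-10, 40, length.out = 25),
                              cache = FALSE)
  # analytic inversion: rms at threshold = 0.05/g; the probe tone's ramps
  # reduce its rms by sqrt(1 - ramp * 5/4 / dur) relative to a full tone
  ramp_factor <- sqrt((0.1 - 2 * 0.01 * (1 - 3 / 8)) / 0.1)
  thr_exact <- 20 * log10(0.05 / g / (20e-6 * ramp_factor))
  expect_equal(map$thresholds, rep(thr_exact, 2), tolerance = 0.05)
  # criterion is 5% above spont, e.g. 52.5 for spont 50 (checked implicitly
  # by the inversion); query at a grid frequency returns the stored value
  expect_identical(threshold_at(map, 1000), map$thresholds[2])
  expect_error(threshold_at(map, 100), "range")
})

test_that("levels re: threshold add onto the calibrated threshold", {
  map <- structure(list(freqs = c(1000, 2000), thresholds = c(12, 20),
                        warn = c(FALSE, FALSE)), class = "threshold_map")
  expect_equal(level_re_threshold(1000, 0, map), 12)
  expect_equal(level_re_threshold(1000, 30, map), 42)
  expect_equal(level_re_threshold(1500, 10, map) -
               level_re_threshold(1500, 0, map), 10)
})

test_that("calibration flags frequencies that never reach criterion", {
  deaf <- list(simulate = function(wave, population) {
    structure(list(rates = matrix(10, length(population$cfs),
                                  length(wave$samples)),
                   times = (seq_along(wave$samples) - 1) / wave$fs,
                   cfs = population$cfs, k = population$fibers_per_cf,
                   spont = rep(10, length(population$cfs)),
                   duration = wave$duration),
              class = "rate_response")
  }, config = list(fs = 20e3))
  expect_warning(map <- calibrate_thresholds(deaf, freqs = 1000,
                                             levels = c(0, 20, 40),
                                             cache = FALSE),
                 "criterion")
  expect_true(map$warn[1])
  expect_equal(map$thresholds[1], 40)
})

test_that("vector strength matches closed forms", {
  dt <- 1e-5
  t <- seq(0, 0.1 - dt, by = dt)
  f <- 200
  expect_lt(vector_strength(rep(7, length(t)), t, f), 1e-3)  # constant -> 0
  half <- pmax(sin(2 * pi * f * t), 0)
  expect_equal(vector_strength(half, t, f), pi / 4, tolerance = 1e-3)
  # impulse-like rate concentrated at one phase -> 1
  pulse <- as.numeric((t * f) %% 1 < 0.01)
  expect_gt(vector_strength(pulse, t, f), 0.99)
  expect_error(vector_strength(rep(0, length(t)), t, f), "undefined")
  expect_error(vector_strength(half[1:100], t[1:100], f), "cycles")
})

test_that("Q10 matches the filter magnitude response and sharpens with CF", {
  cfg <- frontend_config()
  # brute-force oracle: sweep the gammatone magnitude response itself
  q10_oracle <- function(cf) {
    b <- 1.019 * cf / q_erb(cf, cfg)
    fgrid <- seq(cf * 0.3, cf * 1.9, length.out = 20001)
    mag_db <- -20 * log10((1 + ((fgrid - cf) / b)^2)^(cfg$gt_order / 2))
    above <- fgrid[mag_db >= -10]
    cf / (max(above) - min(above))
  }
  q_meas <- vapply(c(1000, 4000), function(cf) q10(cfg, cf), numeric(1))
  q_orac <- vapply(c(1000, 4000), q10_oracle, numeric(1))
  expect_equal(q_meas, q_orac, tolerance = 0.02)
  expect_true(all(q_meas > 0))
  # monotone sharpening above 1 kHz under the human tuning law
  expect_true(all(diff(q_meas) > 0))
})

test_that("the plug-in interface accepts the reference chain, rejects others", {
  expect_silent(register_frontend(ref_frontend()))
  bad_neg <- list(simulate = function(wave, population) {
    r <- ref_frontend()$simulate(wave, population)
    r$rates[1, 1] <- -1
    r
  }, config = list(fs = 100e3))
  expect_error(register_frontend(bad_neg), "non-negative")
  bad_shape <- list(simulate = function(wave, population) {
    r <- ref_frontend()$simulate(wave, population)
    r$times <- r$times[-1]
    r
  }, config = list(fs = 100e3))
  expect_error(register_frontend(bad_shape), "time-grid")
})
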