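#!/usr/bin/env Rscript
# Rate-level threshold calibration for the reference auditory-nerve front end.
#
# Simulates 100-ms pure tones at 25 log-spaced frequencies (0.2-20 kHz) and
# 25 levels (-10 to 40 dB SPL) for on-CF HSR fibers, records the level at
# which the mean rate first exceeds 1.05 x spontaneous, and writes the
# threshold map used by every later level-setting step ("dB re: threshold").

suppressMessages(library(anpitch))
seed <- 1
dir.create("results", showWarnings = FALSE)

frontend <- make_frontend(frontend_config())
map <- calibrate_thresholds(frontend)

out <- data.frame(frequency_hz = map$freqs, threshold_db_spl = map$thresholds,
                  at_grid_max = map$warn)
write_results_csv(out, "results/rate_level_thresholds.csv")
write_manifest(run_manifest(seed, "calibration", frontend$config),
               "results/rate_level_thresholds_manifest.json")

cat(sprintf("rate-level thresholds: %.1f to %.1f dB SPL over %.2f-%.1f kHz\n",
            min(map$thresholds), max(map$thresholds),
            min(map$freqs) / 1000, max(map$freqs) / 1000))
cat("The map is nearly flat: the reference chain has no middle-ear shaping,\n")
cat("so 'dB re: threshold' mainly removes the residual calibration offset.\n")
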