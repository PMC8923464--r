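#!/usr/bin/env Rscript
# Effect of level roving and phase randomization on predicted thresholds.
#
# Stimulus parameters that vary from trial to trial become nuisance
# dimensions of the observer: the expected Fisher matrix is averaged over
# the uniform synthesis rove (+-3 dB level; 360 deg phase) and the prior
# information uses the normal approximation (SD 6 dB / 360 deg). This script
# compares roved and fixed runs at three pure-tone frequencies in the
# TFS-dominated range and three HCT F0s.
#
# Findings this script reproduces: phase randomization roughly doubles
# all-information thresholds (the classic analytic prediction) but leaves
# the rate-place observer untouched; level roving has little effect on
# either observer.

suppressMessages(library(anpitch))
seed <- 1
dir.create("results", showWarnings = FALSE)

frontend <- make_frontend(frontend_config())
map <- calibrate_thresholds(frontend)

tone_f <- c(1600, 2240, 3150)
hct_f0 <- c(200, 280, 400)
rows <- list()
for (task in c("FDL", "F0DL")) {
  freqs <- if (task == "FDL") tone_f else hct_f0
  fixed <- run_discrimination(experiment_grid(task, freqs), frontend,
                              cal_map = map, seed = seed)
  for (rv in c("phase", "level")) {
    roved <- run_discrimination(experiment_grid(task, freqs, roving = rv),
                                frontend, cal_map = map, seed = seed,
                                n_draws = 4)
    eff <- roving_effect(roved, fixed)
    eff$task <- task
    eff$roving <- rv
    rows[[paste(task, rv)]] <- eff
  }
}
out <- do.call(rbind, rows)
write_results_csv(out, "results/roving_effects.csv")
write_manifest(run_manifest(seed, "roving", frontend$config),
               "results/roving_manifest.json")

for (task in c("FDL", "F0DL")) {
  for (rv in c("phase", "level")) {
    for (obs in c("all_information", "rate_place")) {
      sel <- out$task == task & out$roving == rv & out$observer == obs
      cat(sprintf("%-4s %-5s %-16s threshold ratio roved/fixed: %s\n",
                  task, rv, obs,
                  paste(sprintf("%.2f", out$ratio[sel]), collapse = " ")))
    }
  }
}
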