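# Shared fixtures: the reference front end and its calibration map are
# computed once per test run (calibrate_thresholds memoises per config).

ref_frontend <- function() make_frontend(frontend_config())

ref_cal_map <- function() calibrate_thresholds(ref_frontend())

# steady-state time-averaged rate (ramps and post-offset tail excluded)
steady_rate <- function(resp, ramp = 0.01, dur = 0.1) {
  keep <- resp$times >= ramp & resp$times <= dur - ramp
  rowMeans(resp$rates[, keep, drop = FALSE])
}

# a synthetic rate_response for observer-math tests
fake_response <- function(rates, dt = 1e-4, k = 1) {
  if (!is.matrix(rates)) rates <- matrix(rates, nrow = 1)
  structure(list(rates = rates, times = (seq_len(ncol(rates)) - 1) * dt,
                 cfs = seq_len(nrow(rates)) * 1000,
                 k = rep_len(k, nrow(rates)),
                 spont = rep(1, nrow(rates)),
                 duration = ncol(rates) * dt),
            class = "rate_response")
}
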