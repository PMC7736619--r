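#!/usr/bin/env Rscript
# Stage 3 — staircase calibration of the random-dot-motion stimulus for
# the synthetic observer, and verification of the two-down-one-up
# stationary accuracy (~70.7% correct).
source("analysis/00_config.R")

obs <- CFG$observer
params <- cache_or("stim_params", run_calibration(
  obs, list(n_trials = CFG$calib_trials),
  seed = derive_seed(SEED, "calib")))
message(sprintf("calibrated: C = {%.3f, %.3f}, D = {%.1f, %.1f} deg",
                params$c_l, params$c_h, params$d_l, params$d_h))

st <- staircase_stationary_accuracy(obs, params, n_trials = 10000,
                                    seed = derive_seed(SEED, "stat"))
message(sprintf("stationary staircase accuracy: %.1f%% (C_L*D_H %.1f%%, C_H*D_L %.1f%%)",
                100 * st$accuracy, 100 * st$by_condition[["c_l_d_h"]],
                100 * st$by_condition[["c_h_d_l"]]))

write_tsv(data.frame(
  c_l = params$c_l, c_m = params$c_m, c_h = params$c_h,
  d_l = params$d_l, d_m = params$d_m, d_h = params$d_h,
  stationary_accuracy = st$accuracy,
  acc_cl_dh = st$by_condition[["c_l_d_h"]],
  acc_ch_dl = st$by_condition[["c_h_d_l"]]), "03_calibration.tsv")
message("stage 3 done")
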