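#!/usr/bin/env Rscript
# Stage 4 — simulate surgical sessions (task + trial-locked serotonin
# uncertainty transients + FSCV forward model) and decode them with the
# trained grid.
source("analysis/00_config.R")
if (!file.exists(file.path(CACHE, "models.rds")))
  source("analysis/02_train_decoder.R")
if (!file.exists(file.path(CACHE, "stim_params.rds")))
  source("analysis/03_calibrate_task.R")
models <- readRDS(file.path(CACHE, "models.rds"))
params <- readRDS(file.path(CACHE, "stim_params.rds"))
pop <- probe_population(waveform = CFG$waveform)

sessions <- cache_or("sessions", lapply(seq_len(CFG$n_sessions), function(s) {
  tab <- generate_session(params, CFG$observer,
                          config = list(n_trials = CFG$n_trials,
                                        session_id = paste0("s", s)),
                          seed = derive_seed(SEED, paste0("task", s)))
  probe <- sample_probe_model(pop, derive_seed(SEED, paste0("vivo", s)),
                              probe_id = paste0("invivo", s))
  generate_invivo_session(tab, CFG$effect_spec, probe,
                          seed = derive_seed(SEED, paste0("rec", s)))
}))

decoded <- cache_or("decoded", lapply(sessions, function(rec)
  decode_session(models, rec)))

for (s in seq_along(decoded)) {
  d <- decoded[[s]]
  message(sprintf("session %d: %d sweeps decoded, chosen cell (%d, %d)",
                  s, length(d$timestamps), d$chosen_cell[1],
                  d$chosen_cell[2]))
  # decoded vs latent ground truth (correlation of 5-HT series)
  gt <- sessions[[s]]$ground_truth
  message(sprintf("  decoded-vs-truth correlation: DA %.3f, 5-HT %.3f",
                  cor(d$DA, gt$DA), cor(d$`5HT`, gt$`5HT`)))
  write_tsv(data.frame(timestamp = d$timestamps, DA = d$DA,
                       `5HT` = d$`5HT`, pH = d$pH, check.names = FALSE),
            sprintf("04_decoded_s%d.tsv", s))
}

tabs <- do.call(rbind, lapply(sessions, `[[`, "trials"))
tabs$participant <- tabs$session_id
write_tsv(tabs, "04_trial_table.tsv")
message("stage 4 done")
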