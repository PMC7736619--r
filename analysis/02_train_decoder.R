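#!/usr/bin/env Rscript
# Stage 2 — train the 5x5 range-grid elastic-net decoder and evaluate it
# on naive probes withheld from training.
source("analysis/00_config.R")
if (!file.exists(file.path(CACHE, "pool.rds")))
  source("analysis/01_simulate_invitro.R")
pool <- cache_or("pool", stop("pool cache missing"))

models <- cache_or("models", fit_grid(
  pool, CFG$grid, alphas = CFG$alphas, folds = CFG$folds,
  seed = derive_seed(SEED, "cv"), nlambda = CFG$nlambda,
  waveform = CFG$waveform))
print(models)

alpha_tab <- do.call(rbind, lapply(models$cells, function(c)
  data.frame(i = c$cell[1], j = c$cell[2], alpha = c$alpha,
             lambda = c$lambda, cv_error = c$cv_error,
             n_train = c$n_train)))
write_tsv(alpha_tab, "02_grid_fits.tsv")

pop <- probe_population(waveform = CFG$waveform)
naive <- cache_or("naive_sets", lapply(seq_len(CFG$n_naive_probes),
  function(k) generate_probe_datasets(
    sample_probe_model(pop, derive_seed(SEED, paste0("naive", k)),
                       probe_id = paste0("naive", k)),
    seed = derive_seed(SEED, paste0("nds", k)),
    protocols = CFG$protocols)))
ev <- evaluate_on_naive_probes(models, naive)
write_tsv(ev$single_analyte, "02_naive_single_analyte.tsv")
write_tsv(ev$ph_sweep, "02_naive_ph_sweep.tsv")

message(sprintf(
  "naive-probe evaluation: predicted-vs-known R^2 %.3f-%.3f; pH cross-talk %.1f%% (DA) / %.1f%% (5-HT) of a 900 nM step",
  min(ev$single_analyte$r2), max(ev$single_analyte$r2),
  100 * mean(ev$ph_sweep$da_excursion / ev$ph_sweep$da_step900),
  100 * mean(ev$ph_sweep$ht_excursion / ev$ph_sweep$ht_step900)))
message("stage 2 done")
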