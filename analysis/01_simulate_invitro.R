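#!/usr/bin/env Rscript
# Stage 1 — synthetic in vitro training data.
# Draws a population of carbon-fiber probes, runs the three flow-cell
# protocols (DA 0-4500 nM, 5-HT 0-4500 nM, pH 6.9-7.8) on each, and
# assembles the pooled training set from third-quarter sweeps.
source("analysis/00_config.R")

pop <- probe_population(waveform = CFG$waveform)
probes <- cache_or("train_probes", lapply(seq_len(CFG$n_train_probes),
  function(k) sample_probe_model(pop, derive_seed(SEED, paste0("probe", k)))))

sets <- cache_or("train_sets", lapply(seq_along(probes), function(k)
  generate_probe_datasets(probes[[k]],
                          seed = derive_seed(SEED, paste0("ds", k)),
                          protocols = CFG$protocols)))

pool <- cache_or("pool", assemble_training_pool(
  sets, counts = CFG$counts, seed = derive_seed(SEED, "pool")))

message(sprintf("pool: %d rows x %d features from %d probes (%s rows/probe)",
                nrow(pool$features), ncol(pool$features),
                CFG$n_train_probes, paste(CFG$counts, collapse = "+")))
stopifnot(all(table(pool$probe_of) == sum(CFG$counts)))

write_tsv(data.frame(probe = names(table(pool$probe_of)),
                     rows = as.integer(table(pool$probe_of))),
          "01_pool_counts.tsv")

# a small labeled sweep sample for inspection
ds <- sets[[1]]$DA
keep <- seq(1, nrow(ds$current), length.out = 20)
write_sweep_container(
  list(current = ds$current[keep, ], labels = ds$labels[keep, ],
       time = ds$time[keep], quarter = ds$quarter[keep],
       analyte = "DA", probe_id = ds$probe_id, waveform = ds$waveform),
  file.path(RESULTS, "01_example_sweeps.csv"))
message("stage 1 done")
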