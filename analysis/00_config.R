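# Shared settings for the analysis scripts. Every script can be run on
# its own; intermediate objects are cached under scratch/cache/.
library(voltdecode)

SEED <- 20260101 %% 100000
RESULTS <- "results"
CACHE <- file.path("scratch", "cache")
dir.create(CACHE, showWarnings = FALSE, recursive = TRUE)

# Reduced desk scale: 100-sample sweeps, 5 training + 2 naive probes,
# 500 sampled rows per probe, 3 elastic-net mixing values.
CFG <- run_config(seed = SEED, scale = "reduced",
                  out_dir = file.path(RESULTS, "pipeline"),
                  n_sessions = 2, n_trials = 300)

cache_or <- function(name, code) {
  path <- file.path(CACHE, paste0(name, ".rds"))
  if (file.exists(path)) return(readRDS(path))
  value <- code
  saveRDS(value, path)
  value
}

write_tsv <- function(x, name) {
  utils::write.table(x, file.path(RESULTS, name), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  message("wrote ", file.path(RESULTS, name))
}
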