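#!/usr/bin/env Rscript
# Stage 5 — event-locked encoding analyses on the decoded sessions:
# condition-split time-point tests, the sliding-window encoding
# regression, and choice-RT tercile profiles.
source("analysis/00_config.R")
if (!file.exists(file.path(CACHE, "decoded.rds")))
  source("analysis/04_simulate_and_decode.R")
sessions <- readRDS(file.path(CACHE, "sessions.rds"))
decoded <- readRDS(file.path(CACHE, "decoded.rds"))

tabs <- do.call(rbind, lapply(sessions, `[[`, "trials"))
tabs$participant <- tabs$session_id
kept <- exclude_trials(tabs)
message(sprintf("%d/%d trials kept after exclusion", nrow(kept), nrow(tabs)))

tensors <- lapply(seq_along(decoded), function(s) {
  kt <- kept[kept$session_id == paste0("s", s), , drop = FALSE]
  preprocess_snippets(decoded[[s]], kt, "stimulus", "5HT")
})
tensor <- tensors[[1]]
tensor$values <- do.call(rbind, lapply(tensors, `[[`, "values"))
tensor$trial_meta <- do.call(rbind, lapply(tensors, `[[`, "trial_meta"))
tensor$trial_meta$participant <- tensor$trial_meta$session_id

# serotonin split by coherence: the uncertainty signature
lo <- tensor$trial_meta$coherence_level == "low"
ta <- tensor; ta$values <- tensor$values[lo, , drop = FALSE]
tb <- tensor; tb$values <- tensor$values[!lo, , drop = FALSE]
coh <- timepoint_two_sample(ta, tb)
write_tsv(coh, "05_5ht_coherence_timepoints.tsv")
band <- range(coh$time[coh$sig & coh$mean_a > coh$mean_b])
message(sprintf("5-HT low>high coherence separation significant %.1f-%.1f s post-stimulus (uncorrected)",
                band[1], band[2]))

profile <- sliding_encoding_regression(tensor)
write_tsv(as.data.frame(profile), "05_encoding_profile.tsv")
pk <- which.max(abs(profile$coef["coherence", ]))
message(sprintf("coherence encoding peak: beta = %.2f at %.1f s (p = %.2g)",
                profile$coef["coherence", pk], profile$time_axis[pk],
                profile$p["coherence", pk]))

# choice-locked tercile profiles (dopamine and serotonin)
for (a in c("DA", "5HT")) {
  cht <- lapply(seq_along(decoded), function(s) {
    kt <- kept[kept$session_id == paste0("s", s), , drop = FALSE]
    preprocess_snippets(decoded[[s]], kt, "choice", a)
  })
  ch <- cht[[1]]
  ch$values <- do.call(rbind, lapply(cht, `[[`, "values"))
  ch$trial_meta <- do.call(rbind, lapply(cht, `[[`, "trial_meta"))
  tp <- rt_tercile_profiles(ch)
  out <- data.frame(time = tp$time_axis, t(tp$means))
  names(out) <- c("time", "fast", "medium", "slow")
  write_tsv(out, sprintf("05_choice_terciles_%s.tsv", a))
}
message("stage 5 done")
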