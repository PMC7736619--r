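#!/usr/bin/env Rscript
# Stage 6 — trial-type transition statistics and the hierarchical
# behavioral regressions.
source("analysis/00_config.R")
if (!file.exists(file.path(CACHE, "decoded.rds")))
  source("analysis/04_simulate_and_decode.R")
sessions <- readRDS(file.path(CACHE, "sessions.rds"))
decoded <- readRDS(file.path(CACHE, "decoded.rds"))

tabs <- do.call(rbind, lapply(sessions, `[[`, "trials"))
tabs$participant <- tabs$session_id
kept <- exclude_trials(tabs)

tstats <- transition_probabilities(kept)
message("experienced transition probabilities (rows = previous type):")
print(round(tstats$probabilities, 3))
write_tsv(as.data.frame.table(tstats$probabilities,
                              responseName = "probability"),
          "06_transition_probabilities.tsv")

tens <- lapply(seq_along(decoded), function(s) {
  kt <- kept[kept$session_id == paste0("s", s), , drop = FALSE]
  preprocess_snippets(decoded[[s]], kt, "stimulus", "5HT", smooth = FALSE)
})
tensor <- tens[[1]]
tensor$values <- do.call(rbind, lapply(tens, `[[`, "values"))
tensor$trial_meta <- do.call(rbind, lapply(tens, `[[`, "trial_meta"))
tresp <- transition_responses(tensor)
treg <- transition_regression(tresp, tstats)
message(sprintf("5-HT response ~ transition probability: slope %.2f, t(%d) = %.2f, p = %.3f (simple)",
                treg$simple$slope, treg$simple$df, treg$simple$t,
                treg$simple$p))
if (!is.null(treg$controlled))
  message(sprintf("  controlled: t(%d) = %.2f, p = %.3f",
                  treg$controlled$df, treg$controlled$t,
                  treg$controlled$p))
write_tsv(rbind(cbind(model = "simple", treg$simple),
                if (!is.null(treg$controlled))
                  cbind(model = "controlled", treg$controlled)),
          "06_transition_regression.tsv")

fit <- suppressWarnings(fit_behavior_models(tabs))
print(fit$coefficients)
write_tsv(fit$coefficients, "06_behavior_coefficients.tsv")
message("stage 6 done")
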