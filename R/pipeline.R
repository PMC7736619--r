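#' Configuration for a full pipeline run
#'
#' A single seed fans out to per-stage seeds through a fixed counter
#' scheme, so every stage is individually reproducible and no two stages
#' share an RNG stream. Two problem scales are bundled: `"reduced"` (the
#' default; 100-sample sweeps, 5 training + 2 naive probes, 500 sampled
#' rows per probe, 3 mixing values) sized to run in minutes, and
#' `"paper"` (1000-sample sweeps, 20 training + 6 naive probes,
#' 2500/2500/500 rows per probe, 11 mixing values) matching the
#' full-scale study design.
#'
#' @param seed Global seed.
#' @param scale `"reduced"` or `"paper"`.
#' @param out_dir Output directory for tables and the run report.
#' @param n_sessions,n_trials Simulated surgical sessions and trials per
#'   session.
#' @param observer An [observer_params()].
#' @param effect_spec Event-locked concentration effects for the
#'   simulated sessions (default: the serotonin uncertainty motif).
#' @param calib_trials Calibration trials (default 240).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, scale = c("reduced", "paper"),
                       out_dir = tempfile("voltdecode_run_"),
                       n_sessions = 2, n_trials = 120,
                       observer = observer_params(),
                       effect_spec = effect_uncertainty_5ht(),
                       calib_trials = 240) {
  scale <- match.arg(scale)
  if (scale == "paper") {
    waveform <- waveform_spec()
    cfg <- list(n_train_probes = 20, n_naive_probes = 6,
                counts = c(DA = 2500, `5HT` = 2500, pH = 500),
                protocols = NULL,  # invitro_protocol defaults
                alphas = seq(0, 1, by = 0.1), folds = 10, nlambda = 50)
  } else {
    waveform <- waveform_spec(sample_rate = 1e4)
    cfg <- list(n_train_probes = 5, n_naive_probes = 2,
                counts = c(DA = 225, `5HT` = 225, pH = 50),
                protocols = list(
                  DA = invitro_protocol("DA", step = 100, replicates = 3,
                                        dwell = 8),
                  `5HT` = invitro_protocol("5HT", step = 100,
                                           replicates = 3, dwell = 8),
                  pH = invitro_protocol("pH", replicates = 3, dwell = 8)),
                alphas = c(0, 0.5, 1), folds = 5, nlambda = 30)
  }
  structure(c(list(seed = seed, scale = scale, out_dir = out_dir,
                   waveform = waveform, grid = grid_spec(),
                   n_sessions = n_sessions, n_trials = n_trials,
                   observer = observer, effect_spec = effect_spec,
                   calib_trials = calib_trials),
              cfg),
            class = "run_config")
}

pipeline_log <- function(...) message("[voltdecode] ", sprintf(...))

#' Run the full simulation-to-analysis pipeline
#'
#' Chains every stage: in vitro probe datasets, training-pool assembly,
#' grid training, naive-probe evaluation, staircase calibration, task
#' session simulation, in vivo recording synthesis, decoding, snippet
#' preprocessing, and the encoding/transition/behavioral analyses.
#' Tables are written as TSV under `config$out_dir` together with a
#' plain-markdown run report; the fitted models and intermediate objects
#' are returned invisibly.
#'
#' @param config A [run_config()].
#' @return (Invisibly) a list with all stage outputs.
#' @export
run_full_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  pop <- probe_population(waveform = config$waveform)
  stage <- function(name, code) {
    pipeline_log("stage: %s", name)
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  train_probes <- stage("probes", lapply(seq_len(config$n_train_probes),
    function(k) sample_probe_model(pop, derive_seed(seed, paste0("probe", k)))))
  naive_probes <- lapply(seq_len(config$n_naive_probes), function(k)
    sample_probe_model(pop, derive_seed(seed, paste0("naive", k)),
                       probe_id = paste0("naive", k)))

  train_sets <- stage("invitro", lapply(seq_along(train_probes), function(k)
    generate_probe_datasets(train_probes[[k]],
                            seed = derive_seed(seed, paste0("ds", k)),
                            protocols = config$protocols)))
  naive_sets <- lapply(seq_along(naive_probes), function(k)
    generate_probe_datasets(naive_probes[[k]],
                            seed = derive_seed(seed, paste0("nds", k)),
                            protocols = config$protocols))

  pool <- stage("pool", assemble_training_pool(
    train_sets, counts = config$counts, seed = derive_seed(seed, "pool")))
  models <- stage("train", fit_grid(
    pool, config$grid, alphas = config$alphas, folds = config$folds,
    seed = derive_seed(seed, "cv"), nlambda = config$nlambda,
    waveform = config$waveform))
  evaluation <- stage("evaluate",
                      evaluate_on_naive_probes(models, naive_sets))

  params <- stage("calibrate", run_calibration(
    config$observer, list(n_trials = config$calib_trials),
    seed = derive_seed(seed, "calib")))

  sessions <- list(); decoded <- list(); tables <- list()
  for (s in seq_len(config$n_sessions)) {
    tab <- stage(paste0("session", s), generate_session(
      params, config$observer,
      config = list(n_trials = config$n_trials,
                    session_id = paste0("s", s)),
      seed = derive_seed(seed, paste0("task", s))))
    probe <- sample_probe_model(pop, derive_seed(seed, paste0("vivo", s)),
                                probe_id = paste0("invivo", s))
    rec <- generate_invivo_session(tab, config$effect_spec, probe,
                                   seed = derive_seed(seed, paste0("rec", s)))
    decoded[[s]] <- stage(paste0("decode", s), decode_session(models, rec))
    sessions[[s]] <- rec
    tables[[s]] <- tab
  }
  pooled_table <- do.call(rbind, tables)
  pooled_table$participant <- pooled_table$session_id

  kept <- exclude_trials(pooled_table)
  tensors <- lapply(seq_len(config$n_sessions), function(s) {
    kt <- kept[kept$session_id == paste0("s", s), , drop = FALSE]
    preprocess_snippets(decoded[[s]], kt, "stimulus", "5HT")
  })
  tensor <- tensors[[1]]
  if (config$n_sessions > 1) {
    tensor$values <- do.call(rbind, lapply(tensors, `[[`, "values"))
    tensor$trial_meta <- do.call(rbind, lapply(tensors, `[[`, "trial_meta"))
  }
  tensor$trial_meta$participant <- tensor$trial_meta$session_id

  lo <- tensor$trial_meta$coherence_level == "low"
  ta <- tensor; ta$values <- tensor$values[lo, , drop = FALSE]
  tb <- tensor; tb$values <- tensor$values[!lo, , drop = FALSE]
  coh_test <- stage("timepoint-test", timepoint_two_sample(ta, tb))
  profile <- stage("encoding", sliding_encoding_regression(tensor))
  tstats <- stage("transitions", transition_probabilities(kept))
  tresp <- transition_responses(tensor)
  treg <- tryCatch(transition_regression(tresp, tstats),
                   error = function(e) NULL)
  behavior <- stage("behavior",
                    suppressWarnings(fit_behavior_models(pooled_table)))

  wt <- function(x, f) utils::write.table(
    x, file.path(config$out_dir, f), sep = "\t", row.names = FALSE,
    quote = FALSE)
  wt(pooled_table, "trial_table.tsv")
  wt(data.frame(timestamp = decoded[[1]]$timestamps,
                DA = decoded[[1]]$DA, `5HT` = decoded[[1]]$`5HT`,
                pH = decoded[[1]]$pH, check.names = FALSE),
     "decoded_series_s1.tsv")
  wt(as.data.frame(profile), "encoding_profile.tsv")
  wt(coh_test, "coherence_timepoint_test.tsv")
  wt(behavior$coefficients, "behavior_coefficients.tsv")
  wt(evaluation$single_analyte, "naive_single_analyte.tsv")
  wt(evaluation$ph_sweep, "naive_ph_sweep.tsv")

  report <- c(
    "# voltdecode run report",
    sprintf("- scale: %s; seed: %d", config$scale, config$seed),
    sprintf("- training pool: %d probes x (%s) rows = %d rows",
            config$n_train_probes,
            paste(config$counts, collapse = "+"), nrow(pool$features)),
    sprintf("- fitted cells: %d (alphas: %s)",
            length(config$grid$midpoints)^2,
            paste(config$alphas, collapse = ", ")),
    sprintf("- calibrated: C_M=%.3f, D_L=%.1f, D_H=%.1f",
            params$c_m, params$d_l, params$d_h),
    sprintf("- sessions: %d x %d trials; %d trials kept after exclusion",
            config$n_sessions, config$n_trials, nrow(kept)),
    sprintf("- chosen decoder cell, session 1: (%d, %d)",
            decoded[[1]]$chosen_cell[1], decoded[[1]]$chosen_cell[2]),
    "- per-timepoint tests are reported uncorrected for multiple comparisons")
  writeLines(report, file.path(config$out_dir, "report.md"))

  invisible(list(config = config, pool = pool, models = models,
                 evaluation = evaluation, params = params,
                 sessions = sessions, decoded = decoded,
                 trial_table = pooled_table, kept = kept,
                 tensor = tensor, coherence_test = coh_test,
                 encoding = profile, transitions = tstats,
                 transition_responses = tresp,
                 transition_regression = treg, behavior = behavior))
}
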