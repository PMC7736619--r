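# Shared lightweight fixtures. Heavy fixtures (trained grids) are built
# once at the top of the test files that need them.

# Short waveform for fast tests: 2 ms sweep at 25 kHz -> 50 samples.
tiny_waveform <- function() waveform_spec(sample_rate = 2.5e4)

# Reduced-scale waveform used by decoder tests: 100-sample sweeps.
small_waveform <- function() waveform_spec(sample_rate = 1e4)

small_protocols <- function(step = 100, replicates = 3, dwell = 8) {
  list(DA = invitro_protocol("DA", step = step, replicates = replicates,
                             dwell = dwell),
       `5HT` = invitro_protocol("5HT", step = step,
                                replicates = replicates, dwell = dwell),
       pH = invitro_protocol("pH", replicates = replicates, dwell = dwell))
}

# Small training pool: n_probes x (n_da + n_ht + n_ph) rows.
small_pool <- function(waveform = small_waveform(), n_probes = 3,
                       counts = c(DA = 120, `5HT` = 120, pH = 40),
                       noise_sd = NULL, seed = 42) {
  pop <- if (is.null(noise_sd)) probe_population(waveform = waveform)
    else probe_population(waveform = waveform, noise_sd = noise_sd,
                          drift_amplitude = if (noise_sd == 0) 0 else 0.2)
  probes <- lapply(seq_len(n_probes), function(k)
    sample_probe_model(pop, seed * 100 + k))
  sets <- lapply(seq_along(probes), function(k)
    generate_probe_datasets(probes[[k]], seed = seed + k,
                            protocols = small_protocols()))
  assemble_training_pool(sets, counts = counts, seed = seed)
}

# A z-scored snippet-tensor-shaped object built directly from a matrix.
fake_tensor <- function(values, lock = "stimulus", meta = NULL) {
  axis <- if (lock == "stimulus") seq(-1, 5, by = 0.1) else
    seq(-4, 4, by = 0.1)
  stopifnot(ncol(values) == length(axis))
  structure(list(values = values, time_axis = axis, lock = lock,
                 analyte = "5HT",
                 trial_meta = meta %||%
                   data.frame(trial_index = seq_len(nrow(values)) - 1L),
                 zscored = TRUE, smoothed = FALSE),
            class = "snippet_tensor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Trial table with the four factorial conditions balanced, for analyses
# that need design structure without a full observer simulation.
fake_trial_table <- function(n, seed = 1, session_id = "s1") {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  withr_seed({
    data.frame(
      trial_index = seq_len(n) - 1L, session_id = session_id,
      coherence_level = sample(c("low", "high"), n, TRUE),
      coherence = 0.2,
      distance_level = sample(c("low", "high"), n, TRUE),
      distance = 20,
      accuracy = rbinom(n, 1, 0.7),
      rt = 0.3 + rlnorm(n, -0.2, 0.3),
      confidence = ifelse(runif(n) < 1 / 3,
                          50 + 10 * sample(0:5, n, TRUE), NA),
      stim_on = 6 * seq_len(n), stim_off = 6 * seq_len(n) + 1,
      ref_on = 6 * seq_len(n) + 1,
      choice_time = 6 * seq_len(n) + 2,
      fixation_on = 6 * seq_len(n) - 1,
      stringsAsFactors = FALSE)
  })
}
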