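#' Event-locked concentration effect specification
#'
#' Declares, per analyte and event type, a Gaussian transient kernel that
#' is added to the latent concentration series at each event, optionally
#' restricted to a condition (e.g. serotonin increases after stimulus
#' onset on low-coherence trials only). Amplitudes are in nM and signed.
#'
#' @param analyte `"DA"` or `"5HT"`.
#' @param event Name of the trial-table event column the kernel locks to
#'   (`"stim_on"`, `"ref_on"`, `"choice_time"`, ...).
#' @param latency Kernel peak latency after the event (s).
#' @param width Kernel SD (s).
#' @param amplitude Peak amplitude (nM, signed).
#' @param cond_var,cond_value Optional trial-table column and value the
#'   kernel is restricted to (e.g. `"coherence_level"`, `"low"`).
#' @return One effect row; combine with `rbind()` into an effect spec.
#'   `effect_null()` is the empty spec.
#' @export
effect_kernel <- function(analyte, event, latency, width, amplitude,
                          cond_var = NA_character_,
                          cond_value = NA_character_) {
  stopifnot(analyte %in% c("DA", "5HT"), width > 0)
  data.frame(analyte = analyte, event = event, latency = latency,
             width = width, amplitude = amplitude,
             cond_var = cond_var, cond_value = cond_value,
             stringsAsFactors = FALSE)
}

#' @rdname effect_kernel
#' @export
effect_null <- function() {
  effect_kernel("DA", "stim_on", 0.5, 0.2, 0)[0, ]
}

#' Default serotonin sensory-uncertainty effect
#'
#' Serotonin transiently increases shortly after stimulus onset on
#' low-coherence trials and decreases on high-coherence trials — the
#' uncertainty-tracking motif the encoding analyses are designed to
#' detect.
#'
#' @param amplitude Peak amplitude (nM) of each branch.
#' @param latency,width Kernel timing (s).
#' @export
effect_uncertainty_5ht <- function(amplitude = 150, latency = 0.8,
                                   width = 0.35) {
  rbind(
    effect_kernel("5HT", "stim_on", latency, width, +amplitude,
                  "coherence_level", "low"),
    effect_kernel("5HT", "stim_on", latency, width, -amplitude,
                  "coherence_level", "high"))
}

#' Simulate an in vivo recording session
#'
#' Builds the latent 10 Hz dopamine/serotonin/pH concentration series for
#' a simulated task session — tonic baseline levels plus condition-
#' dependent event-locked transients plus a slow sinusoidal wander — and
#' passes it through the probe's forward model sweep by sweep. The latent
#' series is retained as ground truth for recovery tests.
#'
#' @param trial_table A [generate_session()] trial table with event times.
#' @param effect_spec An effect spec ([effect_kernel()] rows, possibly
#'   [effect_null()]).
#' @param probe A [sample_probe_model()] result.
#' @param seed RNG seed for measurement noise.
#' @param baseline Named tonic levels, default `c(DA = 1000, "5HT" = 1000,
#'   pH = 7.4)` (nM; pH unitless).
#' @param latent_drift_amp Amplitude (nM) of the slow concentration
#'   wander shared by DA and 5-HT (period 120 s), default 50.
#' @param tail Seconds of recording kept after the last event (default 8).
#' @return A `session_recording`: `sweeps` (n x sweep_samples),
#'   `timestamps` (sweep centres, s), `sweep_starts`, `ground_truth`
#'   (data.frame time/DA/`5HT`/pH), `trials`, `probe_id`, `waveform`.
#' @export
generate_invivo_session <- function(trial_table, effect_spec, probe,
                                    seed = 1,
                                    baseline = c(DA = 1000, `5HT` = 1000,
                                                 pH = 7.4),
                                    latent_drift_amp = 50, tail = 8) {
  stopifnot(inherits(probe, "probe_model"))
  wf <- probe$waveform
  ev_cols <- c("fixation_on", "stim_on", "stim_off", "ref_on", "choice_time")
  stopifnot(all(ev_cols %in% names(trial_table)))
  span <- max(trial_table$choice_time) + tail
  n_sweeps <- as.integer(round(span / wf$repetition_period))
  starts <- (seq_len(n_sweeps) - 1) * wf$repetition_period
  ts <- timestamp_predictions(wf, starts)
  if (any(unlist(trial_table[ev_cols]) > span) ||
      any(unlist(trial_table[ev_cols]) < 0))
    stop("event time outside session span", call. = FALSE)

  da <- rep(baseline[["DA"]], n_sweeps)
  ht <- rep(baseline[["5HT"]], n_sweeps)
  ph <- rep(baseline[["pH"]], n_sweeps)
  if (nrow(effect_spec)) {
    for (r in seq_len(nrow(effect_spec))) {
      e <- effect_spec[r, ]
      rows <- if (is.na(e$cond_var)) seq_len(nrow(trial_table)) else
        which(trial_table[[e$cond_var]] == e$cond_value)
      if (!e$event %in% names(trial_table))
        stop("unknown event column: ", e$event, call. = FALSE)
      for (tt in trial_table[[e$event]][rows]) {
        tau <- ts - (tt + e$latency)
        keep <- abs(tau) < 4 * e$width
        bump <- e$amplitude * exp(-0.5 * (tau[keep] / e$width)^2)
        if (e$analyte == "DA") da[keep] <- da[keep] + bump
        else ht[keep] <- ht[keep] + bump
      }
    }
  }
  if (latent_drift_amp > 0) {
    wander <- latent_drift_amp * sin(2 * pi * ts / 120)
    da <- da + wander
    ht <- ht - wander
  }
  da <- pmax(da, 0); ht <- pmax(ht, 0)
  sweeps <- with_seed(seed,
                      synthesize_sweep_matrix(probe, da, ht, ph, ts))
  structure(list(
    sweeps = sweeps, timestamps = ts, sweep_starts = starts,
    ground_truth = data.frame(time = ts, DA = da, `5HT` = ht, pH = ph,
                              check.names = FALSE),
    trials = trial_table, probe_id = probe$probe_id, waveform = wf
  ), class = "session_recording")
}

#' Validate and ingest an externally supplied sweep container as a session
#'
#' Reads a sweep container written by [write_sweep_container()] (or any
#' file matching its schema) and returns a `session_recording` without
#' ground truth, ready for [decode_session()]. The sweep length must match
#' the waveform the decoder was trained under.
#'
#' @param path Container path.
#' @param waveform Expected [waveform_spec()].
#' @return A `session_recording` (with `ground_truth = NULL`).
#' @export
ingest_external_session <- function(path, waveform = waveform_spec()) {
  x <- read_sweep_container(path, waveform)
  if (is.null(x$time) || !length(x$time))
    stop("container missing dataset: timestamps", call. = FALSE)
  if (ncol(x$current) != waveform$sweep_samples)
    stop("sweep length ", ncol(x$current), " does not match the trained ",
         "waveform (", waveform$sweep_samples,
         " samples); check the waveform spec", call. = FALSE)
  structure(list(
    sweeps = x$current, timestamps = x$time,
    sweep_starts = x$time - waveform$sweep_duration / 2,
    ground_truth = NULL, trials = NULL,
    probe_id = x$probe_id, waveform = waveform
  ), class = "session_recording")
}
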