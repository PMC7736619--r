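wf <- tiny_waveform()
pop <- probe_population(waveform = wf)
pr <- sample_probe_model(pop, 4)
obs <- observer_params()
params <- stimulus_parameters(c_m = 0.3, d_l = 12, d_h = 28)
tab <- generate_session(params, obs, list(n_trials = 20), seed = 1)

test_that("a null effect spec yields a flat latent series up to drift", {
  rec <- generate_invivo_session(tab, effect_null(), pr, seed = 1,
                                 latent_drift_amp = 0)
  expect_equal(diff(range(rec$ground_truth$DA)), 0)
  expect_equal(diff(range(rec$ground_truth$`5HT`)), 0)
  expect_equal(nrow(rec$sweeps), length(rec$timestamps))
  # timestamps strictly increasing at the repetition period
  expect_true(all(diff(rec$timestamps) > 0))
  expect_equal(unique(round(diff(rec$timestamps), 9)),
               round(wf$repetition_period, 9))
})

test_that("sweep count follows the session duration and repetition rate", {
  rec <- generate_invivo_session(tab, effect_null(), pr, seed = 1, tail = 8)
  span <- max(tab$choice_time) + 8
  expect_equal(nrow(rec$sweeps),
               as.integer(round(span / wf$repetition_period)))
})

test_that("condition-dependent kernels peak at their specified latency", {
  eff <- effect_uncertainty_5ht(amplitude = 200, latency = 0.8,
                                width = 0.3)
  rec <- generate_invivo_session(tab, eff, pr, seed = 1,
                                 latent_drift_amp = 0)
  gt <- rec$ground_truth
  lags <- seq(0, 2, by = wf$repetition_period)
  lo <- tab$stim_on[tab$coherence_level == "low"]
  hi <- tab$stim_on[tab$coherence_level == "high"]
  at <- function(events, lag) {
    idx <- vapply(events + lag, function(t)
      which.min(abs(gt$time - t)), integer(1))
    mean(gt$`5HT`[idx])
  }
  diff_curve <- vapply(lags, function(l) at(lo, l) - at(hi, l), numeric(1))
  expect_equal(lags[which.max(diff_curve)], 0.8,
               tolerance = wf$repetition_period + 1e-9)
  expect_gt(max(diff_curve), 300)  # ~2 x amplitude at the peak
})

test_that("events outside the recording span are rejected", {
  bad <- tab
  bad$stim_on[3] <- max(tab$choice_time) + 100  # beyond span = max + tail
  expect_error(generate_invivo_session(bad, effect_null(), pr),
               "outside session span")
  neg <- tab
  neg$fixation_on[1] <- -5
  expect_error(generate_invivo_session(neg, effect_null(), pr),
               "outside session span")
  unk <- effect_kernel("DA", "nonevent", 0.5, 0.2, 10)
  expect_error(generate_invivo_session(tab, unk, pr), "unknown event")
})

test_that("exported sessions re-ingest identically and validate length", {
  rec <- generate_invivo_session(tab[1:5, ], effect_null(), pr, seed = 2,
                                 tail = 2)
  path <- tempfile(fileext = ".csv")
  write_sweep_container(list(current = rec$sweeps, time = rec$timestamps,
                             quarter = rep(NA_integer_, nrow(rec$sweeps)),
                             labels = data.frame(
                               DA = NA_real_, `5HT` = NA_real_,
                               pH = NA_real_, check.names = FALSE)[
                                 rep(1, nrow(rec$sweeps)), ],
                             analyte = NULL, probe_id = rec$probe_id,
                             waveform = wf),
                        path)
  back <- ingest_external_session(path, waveform = wf)
  expect_equal(back$sweeps, rec$sweeps, tolerance = 1e-12)
  expect_equal(back$timestamps, rec$timestamps)
  expect_error(ingest_external_session(path, waveform = waveform_spec()),
               "does not match the trained")
})
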