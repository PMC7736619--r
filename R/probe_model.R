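#' Population parameters for synthetic carbon-fiber probes
#'
#' Describes the distribution that individual probes are drawn from. Each
#' analyte responds with a fixed unit-response current shape (template)
#' whose amplitude scales affinely with concentration (dopamine and
#' serotonin, in nM) or with the deviation of pH from 7.4. Templates are
#' smooth localized bumps at distinct positions along the sweep, with a
#' secondary lobe for the monoamines so that analyte information is
#' distributed across the voltammogram rather than confined to one peak.
#' Probe-to-probe variation jitters template positions, widths, amplitudes
#' and gains around the population means.
#'
#' Current is in arbitrary units; only the relative structure matters to
#' the decoder, which operates on differentiated sweeps and whose outputs
#' are per-trial z-scored downstream.
#'
#' @param waveform A [waveform_spec()]; fixes the sweep length.
#' @param variation_scale Non-negative multiplier on all probe-to-probe
#'   jitter; 0 makes every probe identical to the population mean.
#' @param noise_sd SD of i.i.d. Gaussian current noise per sample
#'   (arbitrary units).
#' @param drift_amplitude Amplitude of the slow additive baseline drift
#'   (arbitrary units); the drift is a smooth quasi-periodic function of
#'   recording time with probe-specific phases.
#' @param gain_da,gain_ht Current units per nM for dopamine and serotonin.
#' @param gain_ph Current units per pH unit of deviation from 7.4.
#' @return A `probe_population` list.
#' @export
probe_population <- function(waveform = waveform_spec(),
                             variation_scale = 1,
                             noise_sd = 0.25,
                             drift_amplitude = 0.2,
                             gain_da = 2e-3, gain_ht = 2e-3, gain_ph = 5) {
  if (variation_scale < 0)
    stop("variation_scale must be non-negative", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(list(
    waveform = waveform,
    variation_scale = variation_scale,
    noise_sd = noise_sd,
    drift_amplitude = drift_amplitude,
    gains = c(DA = gain_da, `5HT` = gain_ht, pH = gain_ph),
    # template geometry in fractions of the sweep: centre, width, amplitude
    baseline_amp = 10,
    template_geometry = list(
      DA    = list(centers = c(0.30, 0.62), widths = c(0.080, 0.090),
                   amps = c(1.0, 0.5)),
      `5HT` = list(centers = c(0.44, 0.80), widths = c(0.075, 0.080),
                   amps = c(1.0, 0.5)),
      pH    = list(centers = c(0.12, 0.93), widths = c(0.100, 0.080),
                   amps = c(1.0, 0.6))
    ),
    drift_periods = c(300, 97)
  ), class = "probe_population")
}

gaussian_bump <- function(u, center, width, amp) {
  amp * exp(-0.5 * ((u - center) / width)^2)
}

build_template <- function(n, geom) {
  u <- (seq_len(n) - 0.5) / n
  v <- numeric(n)
  for (k in seq_along(geom$centers))
    v <- v + gaussian_bump(u, geom$centers[k], geom$widths[k], geom$amps[k])
  v
}

#' Draw one probe from a probe population
#'
#' Deterministic in `seed`: the same (population, seed) pair always yields
#' the same probe; distinct seeds yield distinct but correlated probes
#' (their templates stay close to the population mean).
#'
#' @param population A [probe_population()].
#' @param seed Integer seed identifying the probe.
#' @param probe_id Optional identifier; defaults to `"probe<seed>"`.
#' @return A `probe_model` with the baseline current template, per-analyte
#'   unit-response templates, gains, drift and noise parameters.
#' @export
sample_probe_model <- function(population, seed, probe_id = NULL) {
  stopifnot(inherits(population, "probe_population"))
  n <- population$waveform$sweep_samples
  vs <- population$variation_scale
  with_seed(seed, {
    u <- (seq_len(n) - 0.5) / n
    # baseline: broad asymmetric background current, probe-scaled
    base_scale <- exp(stats::rnorm(1, 0, 0.05 * vs))
    baseline <- population$baseline_amp * base_scale *
      (sin(pi * u)^0.8 + 0.15 * u)
    # construction variation: electrode-level common modes (a shift of
    # every redox feature along the sweep, a shared width scale) dominate
    # over small per-feature residuals, as probes from one construction
    # process vary mainly in surface kinetics and sensitivity
    axis_shift <- stats::rnorm(1, 0, 0.0015 * vs)
    width_scale <- exp(stats::rnorm(1, 0, 0.015 * vs))
    templates <- lapply(population$template_geometry, function(geom) {
      centers <- geom$centers + axis_shift +
        stats::rnorm(length(geom$centers), 0, 0.0015 * vs)
      widths <- geom$widths * width_scale *
        exp(stats::rnorm(length(geom$widths), 0, 0.015 * vs))
      amps <- geom$amps * exp(stats::rnorm(length(geom$amps), 0, 0.04 * vs))
      build_template(n, list(centers = centers, widths = widths, amps = amps))
    })
    gains <- population$gains * exp(stats::rnorm(3, 0, 0.10 * vs))
    structure(list(
      probe_id = probe_id %||% paste0("probe", seed),
      waveform = population$waveform,
      baseline = baseline,
      templates = templates,
      gains = gains,
      drift_amplitude = population$drift_amplitude,
      drift_periods = population$drift_periods,
      drift_phases = stats::runif(2, 0, 2 * pi),
      noise_sd = population$noise_sd,
      seed = as.integer(seed)
    ), class = "probe_model")
  })
}

# Slow additive baseline drift at recording time t (s); deterministic per
# probe, smooth, zero-mean over long windows.
probe_drift <- function(probe, t) {
  a <- probe$drift_amplitude
  if (a == 0) return(rep(0, length(t)))
  p <- probe$drift_periods
  ph <- probe$drift_phases
  a * (sin(2 * pi * t / p[1] + ph[1]) + 0.5 * sin(2 * pi * t / p[2] + ph[2]))
}

# Vectorised forward model: one row per (da, ht, ph, t) tuple.
# current = baseline + gain_DA*DA*tmpl_DA + gain_5HT*5HT*tmpl_5HT
#           + gain_pH*(pH - 7.4)*tmpl_pH + drift(t) + noise
synthesize_sweep_matrix <- function(probe, da, ht, ph, t, noise_on = TRUE,
                                    drift_on = TRUE) {
  stopifnot(inherits(probe, "probe_model"))
  m <- max(length(da), length(ht), length(ph), length(t))
  da <- rep_len(da, m); ht <- rep_len(ht, m)
  ph <- rep_len(ph, m); t <- rep_len(t, m)
  if (any(da < 0) || any(ht < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  if (any(ph < 6.0) || any(ph > 8.5))
    stop("pH outside plausible range [6.0, 8.5]", call. = FALSE)
  n <- probe$waveform$sweep_samples
  amp <- cbind(probe$gains[["DA"]] * da,
               probe$gains[["5HT"]] * ht,
               probe$gains[["pH"]] * (ph - 7.4))
  tm <- rbind(probe$templates$DA, probe$templates$`5HT`, probe$templates$pH)
  cur <- amp %*% tm                       # m x n analyte responses
  cur <- sweep(cur, 2, probe$baseline, `+`)
  if (drift_on) cur <- cur + probe_drift(probe, t)
  if (noise_on && probe$noise_sd > 0)
    cur <- cur + matrix(stats::rnorm(m * n, 0, probe$noise_sd), m, n)
  cur
}

#' Synthesize one labeled voltammogram
#'
#' Forward model of a single FSCV sweep on a probe: the baseline current
#' plus affine analyte responses, slow baseline drift, and optional
#' per-sample Gaussian noise. With all analytes at baseline (DA = 0,
#' 5-HT = 0, pH = 7.4), no drift and no noise, the sweep equals the probe's
#' baseline template exactly.
#'
#' @param probe A [sample_probe_model()] result.
#' @param da,ht Dopamine and serotonin concentrations (nM, non-negative).
#' @param ph Solution pH.
#' @param t Recording time (s); drives the drift term.
#' @param noise_on,drift_on Toggles for the stochastic and drift terms.
#' @return A `labeled_sweep`: `current` (length `sweep_samples`), `labels`
#'   (named DA/5HT/pH), `probe_id`, `solution_time`, `quarter` (NA here;
#'   assigned by [generate_invitro_dataset()]).
#' @export
synthesize_sweep <- function(probe, da = 0, ht = 0, ph = 7.4, t = 0,
                             noise_on = TRUE, drift_on = TRUE) {
  cur <- synthesize_sweep_matrix(probe, da, ht, ph, t, noise_on, drift_on)
  structure(list(current = drop(cur),
                 labels = c(DA = da, `5HT` = ht, pH = ph),
                 probe_id = probe$probe_id,
                 solution_time = t,
                 quarter = NA_integer_),
            class = "labeled_sweep")
}

# Pairwise absolute cosine similarity between analyte templates; the
# forward model is identifiable only if templates are well separated.
template_cosines <- function(probe) {
  tm <- rbind(DA = probe$templates$DA,
              `5HT` = probe$templates$`5HT`,
              pH = probe$templates$pH)
  nrm <- sqrt(rowSums(tm^2))
  cmat <- abs((tm %*% t(tm)) / outer(nrm, nrm))
  cmat[upper.tri(cmat)]
}
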