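#' Parametric synthetic observer
#'
#' The observer perceives the net motion direction corrupted by von Mises
#' noise whose concentration grows with coherence, then judges the percept
#' against the reference line. Reaction times follow a shifted lognormal
#' decreasing in both coherence and distance; confidence maps the
#' normalized angular margin of the percept onto the discrete 50-100%
#' scale. The defaults produce the qualitative factorial effects expected
#' of human observers on this task: accuracy and confidence increase, and
#' RT decreases, with both coherence and distance.
#'
#' @param kappa_scale,kappa_power von Mises concentration of the perceived
#'   direction: `kappa(C) = kappa_scale * C^kappa_power` (monotone in C).
#' @param lapse Probability of a random choice, in [0, 0.1].
#' @param rt_shift,rt_mu0,rt_beta_c,rt_beta_d,rt_sigma Shifted-lognormal
#'   RT: `rt = rt_shift + exp(rt_mu0 - rt_beta_c*C - rt_beta_d*D/45 +
#'   rt_sigma*Z)` seconds from reference onset.
#' @param conf_slope,conf_noise Confidence mapping: the angular margin of
#'   the percept in units of perceptual noise is scaled by `conf_slope`,
#'   jittered with SD `conf_noise`, pushed through a normal CDF and
#'   rounded onto {50, 60, ..., 100}.
#' @return An `observer_params` list.
#' @export
observer_params <- function(kappa_scale = 9, kappa_power = 0.8,
                            lapse = 0.01,
                            rt_shift = 0.3, rt_mu0 = 0.2,
                            rt_beta_c = 0.8, rt_beta_d = 0.5,
                            rt_sigma = 0.25,
                            conf_slope = 0.8, conf_noise = 0.3) {
  if (lapse < 0 || lapse > 0.1)
    stop("lapse must lie in [0, 0.1]", call. = FALSE)
  if (kappa_scale <= 0 || kappa_power <= 0)
    stop("kappa map must be monotone increasing (positive parameters)",
         call. = FALSE)
  structure(list(kappa_scale = kappa_scale, kappa_power = kappa_power,
                 lapse = lapse,
                 rt = list(shift = rt_shift, mu0 = rt_mu0,
                           beta_c = rt_beta_c, beta_d = rt_beta_d,
                           sigma = rt_sigma),
                 conf = list(slope = conf_slope, noise = conf_noise)),
            class = "observer_params")
}

kappa_of <- function(observer, coherence) {
  observer$kappa_scale * coherence^observer$kappa_power
}

# von Mises sampler (Best & Fisher 1979 rejection scheme), mean 0,
# concentration kappa, output in radians in (-pi, pi]. No distribution
# package on hand provides this, so it is implemented directly.
rvonmises <- function(n, kappa) {
  kappa <- rep_len(kappa, n)
  out <- numeric(n)
  small <- kappa < 1e-8
  out[small] <- stats::runif(sum(small), -pi, pi)
  todo <- which(!small)
  if (length(todo)) {
    k <- kappa[todo]
    a <- 1 + sqrt(1 + 4 * k^2)
    b <- (a - sqrt(2 * a)) / (2 * k)
    r <- (1 + b^2) / (2 * b)
    got <- rep(FALSE, length(todo))
    while (any(!got)) {
      i <- which(!got)
      u1 <- stats::runif(length(i)); u2 <- stats::runif(length(i))
      u3 <- stats::runif(length(i))
      z <- cos(pi * u1)
      f <- (1 + r[i] * z) / (r[i] + z)
      cq <- k[i] * (r[i] - f)
      ok <- (cq * (2 - cq) - u2 > 0) | (log(cq / u2) + 1 - cq >= 0)
      acc <- i[ok]
      out[todo[acc]] <- sign(u3[ok] - 0.5) * acos(pmax(-1, pmin(1, f[ok])))
      got[acc] <- TRUE
    }
  }
  out
}

#' Probability of a correct choice by direct integration
#'
#' With the motion direction at angular distance `D` (deg) from the
#' reference, the choice is correct when the perceptual error leaves the
#' percept on the motion side of the reference, i.e. when the von Mises
#' error (deg) falls in (-D, 180 - D). This integrates the von Mises
#' density over that arc (independent of Monte Carlo simulation) and
#' applies the lapse rate.
#'
#' @param observer An [observer_params()].
#' @param coherence,distance Stimulus levels (fraction; deg).
#' @param n_grid Integration grid resolution.
#' @return Probability of a correct choice.
#' @export
p_correct <- function(observer, coherence, distance, n_grid = 7200) {
  stopifnot(length(coherence) == length(distance) ||
              length(coherence) == 1 || length(distance) == 1)
  m <- max(length(coherence), length(distance))
  coherence <- rep_len(coherence, m); distance <- rep_len(distance, m)
  kap <- kappa_of(observer, coherence)
  vapply(seq_len(m), function(i) {
    th <- seq(-pi, pi, length.out = n_grid + 1)[-1] - pi / n_grid
    dens <- exp(kap[i] * cos(th))
    dens <- dens / sum(dens)
    d_rad <- distance[i] * pi / 180
    inside <- th > -d_rad & th < pi - d_rad
    p <- sum(dens[inside])
    observer$lapse * 0.5 + (1 - observer$lapse) * p
  }, numeric(1))
}

# Vectorised observer core: given coherences and distances (deg), draw
# perceptual errors, choices, accuracy, RT and the raw confidence margin.
observer_choices <- function(observer, coherence, distance) {
  n <- length(coherence)
  kap <- kappa_of(observer, coherence)
  err <- rvonmises(n, kap) * 180 / pi        # perceptual error, deg
  side <- sample(c(-1, 1), n, replace = TRUE) # +1: motion CCW of reference
  # percept relative to reference = side*distance + err; choice by its sign
  rel <- ang_diff(side * distance + err, 0)
  choice <- ifelse(rel >= 0, 1, -1)
  lapsed <- stats::runif(n) < observer$lapse
  choice[lapsed] <- sample(c(-1, 1), sum(lapsed), replace = TRUE)
  acc <- as.integer(choice == side)
  rt <- observer$rt$shift +
    exp(observer$rt$mu0 - observer$rt$beta_c * coherence -
          observer$rt$beta_d * distance / 45 +
          stats::rnorm(n, 0, observer$rt$sigma))
  sigma_deg <- 180 / pi / sqrt(pmax(kappa_of(observer, coherence), 1e-6))
  z <- abs(rel) / sigma_deg
  q <- stats::pnorm(observer$conf$slope *
                      (z + stats::rnorm(n, 0, observer$conf$noise)))
  confidence <- pmin(100, pmax(50, round(q * 10) * 10))
  list(side = side, err = err, choice = choice, accuracy = acc,
       rt = rt, confidence = confidence)
}

# Single Bernoulli outcome used inside staircases (draws from the current
# RNG stream; calibration wraps the whole loop in one seed).
simulate_outcome <- function(observer, coherence, distance) {
  oc <- observer_choices(observer, coherence, distance)
  oc$accuracy == 1L
}

#' Simulate a single trial
#'
#' Draws the motion direction uniformly on 1-360 deg, places the reference
#' at plus or minus the condition's distance (side uniform), and passes
#' the stimulus through the observer. Returned as a one-row trial table.
#'
#' @param params A [stimulus_parameters()].
#' @param levels List with `coherence` and `distance`, each `"low"` or
#'   `"high"`.
#' @param observer An [observer_params()].
#' @param seed RNG seed.
#' @return A one-row data.frame in the trial-table format of
#'   [generate_session()].
#' @export
simulate_trial <- function(params, levels, observer, seed = 1) {
  with_seed(seed, {
    tab <- generate_session(params, observer,
                            config = list(n_trials = 4, conf_prob = 0),
                            seed = NULL,
                            forced_levels = list(
                              coherence = rep(levels$coherence, 4),
                              distance = rep(levels$distance, 4)))
    tab[1, , drop = FALSE]
  })
}

#' Simulate a session of the factorial task
#'
#' Coherence and distance levels are sampled independently and uniformly
#' on each trial (the 2x2 factorial design); the motion direction is drawn
#' anew from 1-360 deg; confidence is probed on approximately one third of
#' trials. Event times are laid out on a session clock: fixation, a
#' uniform 0.5-1 s delay, the motion stimulus, the reference at stimulus
#' offset, the choice at reference onset plus RT, then feedback (0.25 s)
#' and, on confidence trials, the rating period.
#'
#' @param params A [stimulus_parameters()].
#' @param observer An [observer_params()].
#' @param config List: `n_trials` (required, >= 4), `conf_prob` (default
#'   1/3), `session_id` (default `"s1"`), `conf_duration` (default 1.5 s),
#'   `iti` (default 0.5 s).
#' @param seed RNG seed (`NULL` to use the current RNG stream).
#' @param forced_levels Optional list of per-trial `"low"`/`"high"` level
#'   vectors overriding the random factorial draw.
#' @return A `trial_table` data.frame, one row per trial, with condition
#'   levels and values, the stimulus geometry, the response (choice,
#'   accuracy, rt, confidence) and the event times `fixation_on`,
#'   `stim_on`, `stim_off`, `ref_on`, `choice_time` (s).
#' @export
generate_session <- function(params, observer, config = list(), seed = 1,
                             forced_levels = NULL) {
  n <- config$n_trials
  if (is.null(n) || n < 4) stop("n_trials must be at least 4", call. = FALSE)
  run <- function() {
    conf_prob <- config$conf_prob %||% (1 / 3)
    co_lev <- forced_levels$coherence %||%
      sample(c("low", "high"), n, replace = TRUE)
    di_lev <- forced_levels$distance %||%
      sample(c("low", "high"), n, replace = TRUE)
    coherence <- ifelse(co_lev == "low", params$c_l, params$c_h)
    distance <- ifelse(di_lev == "low", params$d_l, params$d_h)
    oc <- observer_choices(observer, coherence, distance)
    motion <- stats::runif(n, 0, 360)
    motion <- ifelse(motion == 0, 360, motion)
    reference <- (motion - oc$side * distance) %% 360
    conf_on <- stats::runif(n) < conf_prob
    confidence <- ifelse(conf_on, oc$confidence, NA_real_)
    fix_delay <- stats::runif(n, 0.5, 1.0)
    stim_dur <- params$stimulus_duration
    post <- 0.25 + (config$iti %||% 0.5) +
      ifelse(conf_on, config$conf_duration %||% 1.5, 0)
    trial_span <- fix_delay + stim_dur + oc$rt + post
    fixation_on <- c(0, cumsum(trial_span))[seq_len(n)]
    stim_on <- fixation_on + fix_delay
    stim_off <- stim_on + stim_dur
    ref_on <- stim_off
    choice_time <- ref_on + oc$rt
    data.frame(
      trial_index = seq_len(n) - 1L,
      session_id = config$session_id %||% "s1",
      coherence_level = co_lev, coherence = coherence,
      distance_level = di_lev, distance = distance,
      motion_dir = motion, reference_dir = reference,
      correct_side = ifelse(oc$side > 0, "CCW", "CW"),
      choice = ifelse(oc$choice > 0, "CCW", "CW"),
      accuracy = oc$accuracy, rt = oc$rt, confidence = confidence,
      fixation_on = fixation_on, stim_on = stim_on, stim_off = stim_off,
      ref_on = ref_on, choice_time = choice_time,
      stringsAsFactors = FALSE)
  }
  tab <- if (is.null(seed)) run() else with_seed(seed, run())
  class(tab) <- c("trial_table", "data.frame")
  tab
}
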