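#' Two-down-one-up staircase state
#'
#' Adaptive rule used for stimulus calibration: after two consecutive
#' correct decisions the calibrated parameter is made harder (decreased),
#' after one incorrect decision it is made easier (increased). The
#' stationary point of this rule sits at sqrt(0.5) ~ 70.7% correct.
#'
#' @param target Which parameter is calibrated: `"coherence"`,
#'   `"distance_low"` or `"distance_high"`.
#' @param value Starting level.
#' @param step Increment; defaults to 0.01 for coherence and 1 deg for
#'   distance.
#' @param bounds Clamping range; defaults to [0.01, 1] for coherence and
#'   [1, 45] deg for distance (display/task limits).
#' @return A `staircase_state`.
#' @export
staircase_state <- function(target = c("coherence", "distance_low",
                                       "distance_high"),
                            value, step = NULL, bounds = NULL) {
  target <- match.arg(target)
  is_c <- target == "coherence"
  step <- step %||% if (is_c) 0.01 else 1
  bounds <- bounds %||% if (is_c) c(0.01, 1) else c(1, 45)
  if (value < bounds[1] || value > bounds[2])
    stop("starting value outside bounds", call. = FALSE)
  structure(list(target = target, value = value, correct_streak = 0L,
                 step = step, bounds = bounds),
            class = "staircase_state")
}

#' Apply one trial outcome to a staircase
#'
#' Two consecutive correct decisions decrease the level by one step (and
#' reset the streak); one incorrect decision increases it by one step (and
#' resets the streak); a single correct decision only increments the
#' streak. Levels are clamped to the staircase bounds.
#'
#' @param state A [staircase_state()].
#' @param correct Logical outcome of the trial.
#' @return The updated `staircase_state`.
#' @export
update_staircase <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct))
  if (correct) {
    if (state$correct_streak >= 1L) {
      state$value <- max(state$bounds[1], state$value - state$step)
      state$correct_streak <- 0L
    } else {
      state$correct_streak <- 1L
    }
  } else {
    state$value <- min(state$bounds[2], state$value + state$step)
    state$correct_streak <- 0L
  }
  state
}

#' Stimulus parameters from calibration
#'
#' A pair of coherences and a pair of distances tied by the calibration
#' identities: `C_L = C_M * 0.5`, `C_H = C_M * 2`, `C_M = (C_L + C_H) / 2`
#' does not hold under those multipliers, so `C_M` is carried explicitly
#' as the staircased medium value; `D_M = (D_L + D_H) / 2`.
#'
#' @param c_m Medium coherence (staircased).
#' @param d_l,d_h Low/high angular distance (deg).
#' @param stimulus_duration Motion stimulus duration (s).
#' @param reference_max_offset Maximum |motion - reference| angle (deg).
#' @return A `stimulus_parameters` list with `c_l`, `c_m`, `c_h`, `d_l`,
#'   `d_m`, `d_h`.
#' @export
stimulus_parameters <- function(c_m, d_l, d_h, stimulus_duration = 1.0,
                                reference_max_offset = 45) {
  c_l <- c_m * 0.5; c_h <- min(1, c_m * 2)
  if (!(c_l > 0 && c_l < c_h && c_h <= 1))
    stop("coherence pair outside (0, 1]", call. = FALSE)
  if (!(d_l > 0 && d_l < d_h && d_h <= reference_max_offset))
    stop("distance pair outside (0, reference_max_offset]", call. = FALSE)
  structure(list(c_l = c_l, c_m = c_m, c_h = c_h,
                 d_l = d_l, d_m = (d_l + d_h) / 2, d_h = d_h,
                 stimulus_duration = stimulus_duration,
                 reference_max_offset = reference_max_offset),
            class = "stimulus_parameters")
}

#' Calibrate stimulus parameters with interleaved staircases
#'
#' Mirrors the presurgical calibration procedure: coherence and distance
#' are calibrated in alternating blocks. In coherence blocks a medium
#' coherence `C_M` is staircased at the current medium distance `D_M`
#' (initialised at 0.3 and 20 respectively). In distance blocks two
#' staircases run interleaved trial-by-trial: the low distance `D_L` at
#' high coherence (`2 C_M`) and the high distance `D_H` at low coherence
#' (`C_M / 2`). `D_M` is re-derived as the midpoint after every distance
#' block. Each staircase targets ~70.7% correct, so the returned
#' low-coherence/high-distance and high-coherence/low-distance conditions
#' should both sit near 71% accuracy.
#'
#' @param observer An [observer_params()].
#' @param config List: `n_trials` (default 240), `block_length` (default
#'   20), `c_m_init` (0.3), `d_m_init` (20).
#' @param seed RNG seed.
#' @return A [stimulus_parameters()] object with attribute `"trace"`
#'   (per-trial staircase levels).
#' @export
run_calibration <- function(observer, config = list(), seed = 1) {
  n_trials <- config$n_trials %||% 240
  blk <- config$block_length %||% 20
  sc_c <- staircase_state("coherence", config$c_m_init %||% 0.3)
  d_init <- config$d_m_init %||% 20
  sc_dl <- staircase_state("distance_low", d_init)
  sc_dh <- staircase_state("distance_high", d_init)
  d_m <- d_init
  trace <- matrix(NA_real_, n_trials, 3,
                  dimnames = list(NULL, c("c_m", "d_l", "d_h")))
  with_seed(seed, {
    n_blocks <- ceiling(n_trials / blk)
    trial <- 0L
    for (b in seq_len(n_blocks)) {
      coherence_block <- b %% 2L == 1L  # alternate C, D, C, D, ...
      block_start <- c(sc_c$value, sc_dl$value, sc_dh$value)
      for (k in seq_len(min(blk, n_trials - trial))) {
        trial <- trial + 1L
        if (coherence_block) {
          ok <- simulate_outcome(observer, sc_c$value, d_m)
          sc_c <- update_staircase(sc_c, ok)
        } else if (k %% 2L == 1L) {
          ok <- simulate_outcome(observer, min(1, 2 * sc_c$value), sc_dl$value)
          sc_dl <- update_staircase(sc_dl, ok)
        } else {
          ok <- simulate_outcome(observer, 0.5 * sc_c$value, sc_dh$value)
          sc_dh <- update_staircase(sc_dh, ok)
        }
        trace[trial, ] <- c(sc_c$value, sc_dl$value, sc_dh$value)
      }
      if (!coherence_block) d_m <- (sc_dl$value + sc_dh$value) / 2
      block_end <- c(sc_c$value, sc_dl$value, sc_dh$value)
      pinned <- block_start == block_end &
        (block_start %in% c(sc_c$bounds, sc_dl$bounds))
      if (any(pinned))
        warning("a staircase stayed pinned at a bound for an entire block",
                call. = FALSE)
    }
  })
  out <- stimulus_parameters(sc_c$value, min(sc_dl$value, sc_dh$value - 1e-9),
                             max(sc_dh$value, sc_dl$value + 1e-9))
  attr(out, "trace") <- trace
  out
}

#' Stationary accuracy of the calibrated distance staircases
#'
#' Continues the two distance staircases from their calibrated levels —
#' low distance at high coherence and high distance at low coherence,
#' interleaved trial by trial, with the coherence pair frozen — and
#' measures choice accuracy over the post-burn-in staircase trials. In
#' the stationary regime of a two-down-one-up rule this sits at
#' sqrt(0.5), about 70.7% correct, in both conditions.
#'
#' @param observer An [observer_params()].
#' @param params Calibrated [stimulus_parameters()].
#' @param n_trials Stationary trials to measure over (after burn-in).
#' @param burn_in Staircase trials discarded before measurement.
#' @param seed RNG seed.
#' @return List: `accuracy` (pooled over both conditions), `by_condition`
#'   (named c_l_d_h / c_h_d_l), `final_d_l`, `final_d_h`, `n_trials`.
#' @export
staircase_stationary_accuracy <- function(observer, params,
                                          n_trials = 10000,
                                          burn_in = 500, seed = 1) {
  sc_dl <- staircase_state("distance_low", params$d_l)
  sc_dh <- staircase_state("distance_high", params$d_h)
  total <- burn_in + n_trials
  acc <- logical(total); cond <- character(total)
  with_seed(seed, {
    for (k in seq_len(total)) {
      if (k %% 2L == 1L) {
        ok <- simulate_outcome(observer, params$c_h, sc_dl$value)
        sc_dl <- update_staircase(sc_dl, ok)
        cond[k] <- "c_h_d_l"
      } else {
        ok <- simulate_outcome(observer, params$c_l, sc_dh$value)
        sc_dh <- update_staircase(sc_dh, ok)
        cond[k] <- "c_l_d_h"
      }
      acc[k] <- ok
    }
  })
  keep <- seq_len(total) > burn_in
  list(accuracy = mean(acc[keep]),
       by_condition = vapply(c("c_l_d_h", "c_h_d_l"), function(cc)
         mean(acc[keep & cond == cc]), numeric(1)),
       final_d_l = sc_dl$value, final_d_h = sc_dh$value,
       n_trials = n_trials)
}
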