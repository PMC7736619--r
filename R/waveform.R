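#' Specify a triangular FSCV measurement waveform
#'
#' The measurement waveform is a triangular voltage excursion: hold at
#' `v_low`, ramp up to `v_high` at `scan_rate`, ramp straight back down to
#' `v_low` at `-scan_rate`, then hold again. Current is digitised at
#' `sample_rate` during the triangular portion only; the samples recorded
#' during one excursion form a voltammogram (sweep).
#'
#' The default arguments describe the in vivo measurement protocol: a
#' -0.6 V to +1.4 V ramp at 400 V/s with a 90 ms hold, giving a 10 ms sweep
#' of 1000 samples repeated at 10 Hz. A 6.67 ms hold gives the 60 Hz
#' conditioning protocol used to equilibrate the electrode surface.
#'
#' @param v_low,v_high Holding and apex potentials (V); `v_high > v_low`.
#' @param scan_rate Ramp slope (V/s), strictly positive.
#' @param hold_duration Time spent at `v_low` between sweeps (s).
#' @param sample_rate Digitisation rate during the sweep (Hz).
#' @return An object of class `waveform_spec` with derived constants
#'   `sweep_duration` (s), `sweep_samples`, `repetition_period` (s) and
#'   `repetition_hz`.
#' @examples
#' wf <- waveform_spec()            # 10 Hz measurement waveform
#' wf$sweep_samples                 # 1000
#' waveform_spec(hold_duration = 1 / 150)$repetition_hz  # ~60 Hz
#' @export
waveform_spec <- function(v_low = -0.6, v_high = 1.4, scan_rate = 400,
                          hold_duration = 0.090, sample_rate = 1e5) {
  if (!is.finite(scan_rate) || scan_rate <= 0)
    stop("scan_rate must be strictly positive", call. = FALSE)
  if (!is.finite(v_high) || !is.finite(v_low) || v_high <= v_low)
    stop("v_high must exceed v_low", call. = FALSE)
  if (hold_duration <= 0 || sample_rate <= 0)
    stop("hold_duration and sample_rate must be strictly positive",
         call. = FALSE)
  sweep_duration <- 2 * (v_high - v_low) / scan_rate
  spec <- list(
    v_low = v_low, v_high = v_high, scan_rate = scan_rate,
    hold_duration = hold_duration, sample_rate = sample_rate,
    sweep_duration = sweep_duration,
    sweep_samples = as.integer(round(sample_rate * sweep_duration)),
    repetition_period = hold_duration + sweep_duration,
    repetition_hz = 1 / (hold_duration + sweep_duration)
  )
  class(spec) <- "waveform_spec"
  spec
}

#' Build the voltage trace of a triangular sweep
#'
#' Returns the applied potential at each digitisation point of the
#' triangular portion, together with the derived waveform constants.
#'
#' @param spec A [waveform_spec()].
#' @return A list with `voltage` (length `sweep_samples`), `time`
#'   (s within the sweep), and the constants `sweep_duration`,
#'   `sweep_samples`, `repetition_period`, `repetition_hz`.
#' @export
build_waveform <- function(spec) {
  stopifnot(inherits(spec, "waveform_spec"))
  n <- spec$sweep_samples
  t <- (seq_len(n) - 0.5) / spec$sample_rate
  half <- spec$sweep_duration / 2
  v <- ifelse(t <= half,
              spec$v_low + spec$scan_rate * t,
              spec$v_high - spec$scan_rate * (t - half))
  list(voltage = v, time = t,
       sweep_duration = spec$sweep_duration,
       sweep_samples = n,
       repetition_period = spec$repetition_period,
       repetition_hz = spec$repetition_hz)
}

#' @export
print.waveform_spec <- function(x, ...) {
  cat(sprintf(
    "FSCV waveform: %.2f V -> %.2f V at %g V/s; %0.3g ms sweep (%d samples), %0.3g ms hold, %.3g Hz repetition\n",
    x$v_low, x$v_high, x$scan_rate, 1000 * x$sweep_duration,
    x$sweep_samples, 1000 * x$hold_duration, x$repetition_hz))
  invisible(x)
}

#' Timestamps for a series of sweeps
#'
#' Each prediction inherits the timestamp of the centre of the triangular
#' portion of the sweep that produced it.
#'
#' @param spec A [waveform_spec()].
#' @param sweep_starts Start times of the sweeps (s, session clock).
#' @return Numeric vector of timestamps (s).
#' @examples
#' timestamp_predictions(waveform_spec(), 12.0)  # 12.005
#' @export
timestamp_predictions <- function(spec, sweep_starts) {
  stopifnot(inherits(spec, "waveform_spec"))
  sweep_starts + spec$sweep_duration / 2
}
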