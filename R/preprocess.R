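#' Trial exclusion rules
#'
#' Drops trials whose choice reaction time lies more than 3 SD from the
#' session mean (computed per session on raw RT), plus the first and last
#' trial of each session. Returns the filtered table with an exclusion
#' log attached as attribute `"exclusion_log"`.
#'
#' @param table A trial table with `rt` and `session_id`.
#' @param recompute Recompute the exclusion statistics even if the table
#'   has already been filtered once. With `recompute = FALSE` an
#'   already-filtered table passes through unchanged, making the
#'   operation idempotent.
#' @return The filtered `trial_table`; rows keep their original
#'   `trial_index`; attribute `exclusions_applied` marks the result.
#' @export
exclude_trials <- function(table, recompute = TRUE) {
  stopifnot("rt" %in% names(table))
  if (isTRUE(attr(table, "exclusions_applied")) && !recompute)
    return(table)
  log <- list()
  keep <- rep(TRUE, nrow(table))
  for (s in unique(table$session_id)) {
    idx <- which(table$session_id == s)
    rt <- table$rt[idx]
    mu <- mean(rt); sd_ <- stats::sd(rt)
    out_rt <- if (is.finite(sd_) && sd_ > 0)
      abs(rt - mu) > 3 * sd_ else rep(FALSE, length(rt))
    ends <- idx %in% c(idx[1], idx[length(idx)])
    drop <- out_rt | ends
    for (k in which(drop)) {
      reason <- if (ends[k] && out_rt[k]) "first/last trial; RT outside 3 SD"
        else if (ends[k]) "first/last trial" else "RT outside 3 SD"
      log[[length(log) + 1L]] <- data.frame(
        session_id = s, trial_index = table$trial_index[idx[k]],
        reason = reason)
    }
    keep[idx[drop]] <- FALSE
  }
  out <- table[keep, , drop = FALSE]
  if (nrow(out) < 4)
    stop("fewer than 4 trials remain after exclusion", call. = FALSE)
  attr(out, "exclusion_log") <-
    if (length(log)) do.call(rbind, log) else
      data.frame(session_id = character(), trial_index = integer(),
                 reason = character())
  attr(out, "exclusions_applied") <- TRUE
  out
}

snippet_axis <- function(lock = c("stimulus", "choice"), hz = 10) {
  lock <- match.arg(lock)
  if (lock == "stimulus") seq(-1, 5, by = 1 / hz)
  else seq(-4, 4, by = 1 / hz)
}

#' Extract event-locked snippets from a decoded series
#'
#' Aligns the decoded concentration series onto a fixed relative time
#' grid at 10 Hz around each trial's lock event: stimulus onset (window
#' -1 to +5 s, 61 timepoints) or choice submission (-4 to +4 s, 81
#' timepoints). Alignment is by nearest timestamp; trials whose window
#' leaves the recording are dropped with a warning.
#'
#' @param series A `prediction_series` (or any list with `timestamps` and
#'   the analyte vector), typically from [decode_session()].
#' @param table Trial table supplying event times.
#' @param lock `"stimulus"` or `"choice"`.
#' @param analyte `"DA"` or `"5HT"`.
#' @return A `snippet_tensor`: `values` (trials x timepoints),
#'   `time_axis`, `lock`, `analyte`, `trial_meta` (the matched trial
#'   rows), `zscored`, `smoothed`.
#' @export
extract_snippets <- function(series, table, lock = c("stimulus", "choice"),
                             analyte = c("5HT", "DA")) {
  lock <- match.arg(lock); analyte <- match.arg(analyte)
  axis <- snippet_axis(lock)
  ev <- if (lock == "stimulus") table$stim_on else table$choice_time
  ts <- series$timestamps
  x <- series[[analyte]]
  ok <- ev + axis[1] >= ts[1] & ev + axis[length(axis)] <= ts[length(ts)]
  if (!all(ok))
    warning(sum(!ok), " trial(s) dropped: snippet window outside recording",
            call. = FALSE)
  if (!any(ok)) stop("no trial window fits inside the recording",
                     call. = FALSE)
  ev <- ev[ok]
  vals <- t(vapply(ev, function(t0) {
    idx <- round((t0 + axis - ts[1]) / (ts[2] - ts[1])) + 1
    x[pmin(pmax(idx, 1), length(ts))]
  }, numeric(length(axis))))
  structure(list(values = vals, time_axis = axis, lock = lock,
                 analyte = analyte,
                 trial_meta = table[ok, , drop = FALSE],
                 zscored = FALSE, smoothed = FALSE),
            class = "snippet_tensor")
}

#' Z-score each trial's snippet
#'
#' Each row (trial) is centred on its own mean and scaled by its own SD —
#' the only normalization applied to decoded series, chosen because the
#' analyses concern within-trial transients and must be comparable across
#' trials and participants. Constant rows become all zeros and are
#' flagged in attribute `"constant_rows"`.
#'
#' @param tensor A `snippet_tensor` (not yet z-scored).
#' @return The z-scored tensor.
#' @export
znorm_per_trial <- function(tensor) {
  if (isTRUE(tensor$zscored)) stop("tensor is already z-scored",
                                   call. = FALSE)
  v <- tensor$values
  mu <- rowMeans(v)
  sd_ <- apply(v, 1, stats::sd)
  const <- !is.finite(sd_) | sd_ == 0
  sd_[const] <- 1
  tensor$values <- (v - mu) / sd_
  tensor$values[const, ] <- 0
  tensor$zscored <- TRUE
  attr(tensor, "constant_rows") <- which(const)
  tensor
}

#' Causal running-average smoothing
#'
#' The smoothed estimate at time point t is the mean over time points
#' t-4 to t (a trailing 0.5 s window at 10 Hz); the first columns average
#' over the available prefix.
#'
#' @param tensor A `snippet_tensor`.
#' @param width Window length in seconds (must be a positive multiple of
#'   the sampling period).
#' @return The smoothed tensor.
#' @export
smooth_running <- function(tensor, width = 0.5) {
  dt <- tensor$time_axis[2] - tensor$time_axis[1]
  k <- width / dt
  if (width <= 0 || abs(k - round(k)) > 1e-8)
    stop("width must be a positive multiple of the sampling period",
         call. = FALSE)
  k <- as.integer(round(k))
  v <- tensor$values
  cs <- cbind(0, t(apply(v, 1, cumsum)))
  n <- ncol(v)
  lo <- pmax(0L, seq_len(n) - k)  # window covers (lo+1)..t
  sm <- (cs[, seq_len(n) + 1, drop = FALSE] - cs[, lo + 1, drop = FALSE])
  tensor$values <- sweep(sm, 2, seq_len(n) - lo, `/`)
  tensor$smoothed <- TRUE
  tensor
}

#' Standard snippet pipeline
#'
#' Extraction, per-trial z-scoring, then 0.5 s running-average smoothing —
#' in that order.
#'
#' @inheritParams extract_snippets
#' @param smooth Apply [smooth_running()] (default TRUE).
#' @export
preprocess_snippets <- function(series, table, lock = "stimulus",
                                analyte = "5HT", smooth = TRUE) {
  tensor <- znorm_per_trial(extract_snippets(series, table, lock, analyte))
  if (smooth) tensor <- smooth_running(tensor) else tensor
}
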