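trial_type_levels <- c("lowC.lowD", "lowC.highD", "highC.lowD",
                       "highC.highD")

#' Trial type of each row
#'
#' One of the four cells of the 2x2 coherence-by-distance design.
#'
#' @param table A trial table.
#' @return Factor with levels `lowC.lowD`, `lowC.highD`, `highC.lowD`,
#'   `highC.highD`.
#' @export
trial_types <- function(table) {
  factor(paste0(ifelse(table$coherence_level == "low", "lowC", "highC"),
                ".",
                ifelse(table$distance_level == "low", "lowD", "highD")),
         levels = trial_type_levels)
}

# Consecutive chronological pairs within a session: pairs broken by
# excluded trials (non-adjacent original indices) are dropped, not
# bridged.
transition_pairs <- function(table) {
  ord <- order(table$session_id, table$trial_index)
  tab <- table[ord, , drop = FALSE]
  n <- nrow(tab)
  if (n < 2) stop("need at least 2 trials", call. = FALSE)
  prev <- seq_len(n - 1); cur <- prev + 1
  ok <- tab$session_id[prev] == tab$session_id[cur] &
    tab$trial_index[cur] - tab$trial_index[prev] == 1L
  ty <- trial_types(tab)
  list(table = tab, prev = prev[ok], cur = cur[ok], types = ty)
}

#' Experienced trial-type transition statistics
#'
#' Counts how often each trial type succeeded each trial type over
#' consecutive trials, row-normalizes the counts into conditional
#' probabilities P(type_t | type_t-1), and reports the marginal type
#' frequencies. Under randomized condition sampling every conditional
#' probability is 0.25 in expectation.
#'
#' @param table A trial table in chronological order (post-exclusion
#'   tables are handled by dropping broken pairs).
#' @return A `transition_stats`: `counts` (4x4, rows = previous type),
#'   `probabilities` (row-normalized), `marginals`, `n_pairs`.
#' @export
transition_probabilities <- function(table) {
  tp <- transition_pairs(table)
  counts <- table(prev = tp$types[tp$prev], cur = tp$types[tp$cur])
  counts <- unclass(counts)
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs > 0, rs, 1)
  probs[rs == 0, ] <- NA_real_
  marg <- as.numeric(table(tp$types)) / length(tp$types)
  names(marg) <- trial_type_levels
  structure(list(counts = counts, probabilities = probs,
                 marginals = marg, n_pairs = length(tp$prev)),
            class = "transition_stats")
}

#' Mean neuromodulator response per trial-type transition
#'
#' Averages each trial's stimulus-locked snippet over a fixed window
#' (default 0 to 1.5 s, the period during which the current trial type is
#' revealed; 16 samples at 10 Hz), then averages across trials within
#' each ordered (previous type, current type) pair. Also returns the mean
#' choice accuracy per pair, used by the controlled regression.
#'
#' @param tensor A stimulus-locked `snippet_tensor`.
#' @param window Averaging window (s relative to stimulus onset), closed
#'   on both ends.
#' @return List: `responses` (4x4, rows = previous type; NA where a pair
#'   never occurred), `accuracy` (4x4), `n` (4x4 trial counts),
#'   `window_samples`.
#' @export
transition_responses <- function(tensor, window = c(0, 1.5)) {
  cols <- which(tensor$time_axis >= window[1] - 1e-9 &
                  tensor$time_axis <= window[2] + 1e-9)
  per_trial <- rowMeans(tensor$values[, cols, drop = FALSE])
  tp <- transition_pairs(tensor$trial_meta)
  resp <- acc <- nmat <- matrix(NA_real_, 4, 4,
                                dimnames = list(prev = trial_type_levels,
                                                cur = trial_type_levels))
  # per_trial follows tensor row order; reindex through the sorted table
  ord <- order(tensor$trial_meta$session_id, tensor$trial_meta$trial_index)
  per_trial <- per_trial[ord]
  acc_trial <- tensor$trial_meta$accuracy[ord]
  pt <- as.integer(tp$types[tp$prev]); ct <- as.integer(tp$types[tp$cur])
  for (a in 1:4) for (b in 1:4) {
    sel <- pt == a & ct == b
    nmat[a, b] <- sum(sel)
    if (any(sel)) {
      resp[a, b] <- mean(per_trial[tp$cur[sel]])
      acc[a, b] <- mean(acc_trial[tp$cur[sel]])
    }
  }
  list(responses = resp, accuracy = acc, n = nmat,
       window_samples = length(cols))
}

#' Regress transition responses on transition probabilities
#'
#' Simple model: the 16 mean responses against the 16 conditional
#' transition probabilities (t reported with df = n_pairs - 2). The
#' controlled model adds the marginal probability of the current type and
#' the mean choice accuracy per transition (df = n_pairs - 4). Pairs that
#' never occurred are dropped and the df adjust accordingly.
#'
#' @param responses Output of [transition_responses()].
#' @param stats A [transition_probabilities()] result.
#' @return List of one-row data.frames `simple` and (if accuracy is
#'   available) `controlled`: `slope`, `t`, `df`, `p`, `n`.
#' @export
transition_regression <- function(responses, stats) {
  r <- as.vector(responses$responses)
  p <- as.vector(stats$probabilities)
  marg <- rep(stats$marginals, each = 4)   # marginal of the current type
  a <- as.vector(responses$accuracy)
  use <- is.finite(r) & is.finite(p)
  if (sum(use) < 3) stop("fewer than 3 usable transition pairs",
                         call. = FALSE)
  tidy_slope <- function(fit, term, n) {
    s <- suppressWarnings(summary(fit)$coefficients)
    slope <- s[term, 1]; tt <- s[term, 3]; pv <- s[term, 4]
    if (!is.finite(tt)) {  # zero-residual perfect fit: |t| -> Inf
      tt <- sign(slope) * Inf
      pv <- 0
    }
    data.frame(slope = slope, t = tt, df = fit$df.residual, p = pv, n = n)
  }
  simple <- stats::lm(r[use] ~ p[use])
  out <- list(simple = tidy_slope(simple, 2, sum(use)))
  usec <- use & is.finite(a)
  if (sum(usec) >= 5) {
    ctrl <- stats::lm(r[usec] ~ p[usec] + marg[usec] + a[usec])
    out$controlled <- tidy_slope(ctrl, 2, sum(usec))
  }
  out
}
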