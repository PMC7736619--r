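#' The 5x5 training-range grid
#'
#' Dopamine and serotonin concentration ranges (0-4500 nM) are each
#' divided into five non-overlapping 900 nM intervals, forming a 5x5 grid
#' of training cells. Intervals are half-open [lo, hi) except the last,
#' which closes at 4500 so the grid is exhaustive. Each cell carries the
#' midpoints of its two ranges — the anchor used by the in vivo
#' prediction-selection rule.
#'
#' @param conc_max Upper end of the calibrated range (nM).
#' @param n_ranges Number of intervals per analyte.
#' @return A `grid_spec` with `breaks`, `midpoints` and `n_ranges`.
#' @export
grid_spec <- function(conc_max = 4500, n_ranges = 5) {
  breaks <- seq(0, conc_max, length.out = n_ranges + 1)
  structure(list(breaks = breaks,
                 midpoints = (breaks[-1] + breaks[-(n_ranges + 1)]) / 2,
                 width = diff(breaks)[1],
                 n_ranges = as.integer(n_ranges)),
            class = "grid_spec")
}

# Interval index of concentration values under the grid (last bin closed).
grid_bin <- function(grid, x) {
  b <- findInterval(x, grid$breaks, rightmost.closed = TRUE)
  b[b == grid$n_ranges + 1L] <- grid$n_ranges
  b
}

#' First-difference voltammograms into decoder features
#'
#' Analyte inference uses the derivative of each voltammogram: first
#' differences along the sample axis, so 1000-sample sweeps yield
#' Q = 999 features.
#'
#' @param sweep_matrix n_sweeps x L matrix (or a single sweep vector).
#' @return n_sweeps x (L-1) feature matrix.
#' @export
differentiate <- function(sweep_matrix) {
  if (is.null(dim(sweep_matrix)))
    sweep_matrix <- matrix(sweep_matrix, nrow = 1)
  if (ncol(sweep_matrix) < 2)
    stop("sweeps must have at least 2 samples", call. = FALSE)
  sweep_matrix[, -1, drop = FALSE] -
    sweep_matrix[, -ncol(sweep_matrix), drop = FALSE]
}

#' Assemble the pooled training set from per-probe in vitro datasets
#'
#' Draws, per probe, a fixed number of rows from each protocol (default
#' 2500 dopamine, 2500 serotonin and 500 pH rows), restricted to sweeps
#' from the third quarter of each concentration level's dwell timeline,
#' and differentiates the pooled sweeps into features.
#'
#' @param probe_datasets List (one element per probe) of named dataset
#'   bundles `list(DA = , "5HT" = , pH = )` from
#'   [generate_probe_datasets()].
#' @param counts Named per-probe sampling budget.
#' @param seed RNG seed for the random draws.
#' @return A `training_pool`: `features` (N x Q), `labels` (N x 3 matrix,
#'   DA/`5HT`/pH), `probe_of`, `analyte_of` (source protocol per row),
#'   `counts`.
#' @export
assemble_training_pool <- function(probe_datasets,
                                   counts = c(DA = 2500, `5HT` = 2500,
                                              pH = 500),
                                   seed = 1) {
  feats <- list(); labs <- list(); probe_of <- c(); analyte_of <- c()
  with_seed(seed, {
    for (p in seq_along(probe_datasets)) {
      bundle <- probe_datasets[[p]]
      for (a in names(counts)) {
        ds <- bundle[[a]]
        if (is.null(ds))
          stop("probe ", p, " lacks a ", a, " protocol dataset",
               call. = FALSE)
        third <- which(ds$quarter == 3L)
        if (length(third) < counts[[a]])
          stop("probe ", ds$probe_id, ": only ", length(third),
               " third-quarter ", a, " rows; ", counts[[a]], " requested",
               call. = FALSE)
        take <- sort(sample(third, counts[[a]]))
        feats[[length(feats) + 1L]] <-
          differentiate(ds$current[take, , drop = FALSE])
        labs[[length(labs) + 1L]] <- as.matrix(ds$labels[take, ])
        probe_of <- c(probe_of, rep(ds$probe_id, length(take)))
        analyte_of <- c(analyte_of, rep(a, length(take)))
      }
    }
  })
  labels <- do.call(rbind, labs)
  colnames(labels) <- c("DA", "5HT", "pH")
  structure(list(features = do.call(rbind, feats), labels = labels,
                 probe_of = probe_of, analyte_of = analyte_of,
                 counts = counts),
            class = "training_pool")
}

#' Restrict the pool to one grid cell
#'
#' A cell (i, j) trains on the dopamine-protocol rows whose DA label falls
#' in range i, the serotonin-protocol rows whose 5-HT label falls in range
#' j, and the full set of pH-protocol rows (the same pH data enters every
#' cell).
#'
#' @param pool A [assemble_training_pool()] result.
#' @param grid A [grid_spec()].
#' @param i,j DA and 5-HT range indices (1-based).
#' @return List with `features`, `labels`, `probe_of`, `rows` (pool row
#'   indices).
#' @export
build_cell_dataset <- function(pool, grid, i, j) {
  stopifnot(i >= 1, i <= grid$n_ranges, j >= 1, j <= grid$n_ranges)
  da_rows <- which(pool$analyte_of == "DA" &
                     grid_bin(grid, pool$labels[, "DA"]) == i)
  ht_rows <- which(pool$analyte_of == "5HT" &
                     grid_bin(grid, pool$labels[, "5HT"]) == j)
  ph_rows <- which(pool$analyte_of == "pH")
  if (!length(da_rows)) stop("empty DA stratum for cell (", i, ",", j, ")",
                             call. = FALSE)
  if (!length(ht_rows)) stop("empty 5-HT stratum for cell (", i, ",", j,
                             ")", call. = FALSE)
  rows <- c(da_rows, ht_rows, ph_rows)
  list(features = pool$features[rows, , drop = FALSE],
       labels = pool$labels[rows, , drop = FALSE],
       probe_of = pool$probe_of[rows], rows = rows)
}

# Probe-stratified fold assignment: folds are balanced within each probe
# so no fold is dominated by a single electrode.
stratified_folds <- function(probe_of, nfolds) {
  foldid <- integer(length(probe_of))
  for (p in unique(probe_of)) {
    idx <- which(probe_of == p)
    foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  foldid
}

#' Fit the 5x5 grid of multi-response elastic-net models
#'
#' For every grid cell, fits multi-response (Gaussian) linear models of
#' the three concentration labels on the differentiated voltammogram
#' features under the elastic-net penalty
#' \deqn{P_\alpha(\beta) = (1-\alpha)\tfrac12\|\beta\|_2^2 +
#'   \alpha\|\beta\|_1,}
#' for each mixing value in `alphas` (default 0, 0.1, ..., 1) with
#' k-fold cross-validation. Within each alpha the regularization strength
#' minimizing mean cross-validated error is kept (`lambda.min`); the cell
#' then keeps the alpha with the lowest mean CV error. Fold assignment is
#' seeded and stratified by probe.
#'
#' @param pool A [assemble_training_pool()] result.
#' @param grid A [grid_spec()].
#' @param alphas Elastic-net mixing grid.
#' @param folds Number of CV folds.
#' @param seed Seed for fold assignment.
#' @param nlambda Length of the lambda path per fit.
#' @param waveform Waveform the pool was recorded under (stored for
#'   feature-width checks at prediction time).
#' @return A `grid_model_set`: `cells` (n x n list of fitted cells, each
#'   with `coefficients` (Q x 3), `intercepts`, `alpha`, `lambda`,
#'   `cv_error`, `n_train`), `grid`, `alphas`, `feature_width`.
#' @export
fit_grid <- function(pool, grid = grid_spec(),
                     alphas = seq(0, 1, by = 0.1), folds = 10, seed = 1,
                     nlambda = 50, waveform = NULL) {
  q <- ncol(pool$features)
  cells <- vector("list", grid$n_ranges^2)
  dim(cells) <- c(grid$n_ranges, grid$n_ranges)
  for (i in seq_len(grid$n_ranges)) {
    for (j in seq_len(grid$n_ranges)) {
      cd <- build_cell_dataset(pool, grid, i, j)
      foldid <- with_seed(derive_seed(seed, sprintf("fold-%d-%d", i, j)),
                          stratified_folds(cd$probe_of, folds))
      best <- NULL
      for (a in alphas) {
        fit <- tryCatch(
          glmnet::cv.glmnet(cd$features, cd$labels, family = "mgaussian",
                            alpha = a, foldid = foldid, nlambda = nlambda,
                            standardize = TRUE),
          error = function(e)
            stop("cross-validation failed in cell (", i, ",", j,
                 ") at alpha=", a, ": ", conditionMessage(e),
                 call. = FALSE))
        k <- which.min(fit$cvm)
        if (is.null(best) || fit$cvm[k] < best$cv_error)
          best <- list(fit = fit, alpha = a, lambda = fit$lambda[k],
                       cv_error = fit$cvm[k])
      }
      co <- glmnet::coef.glmnet(best$fit$glmnet.fit, s = best$lambda)
      coefs <- vapply(co, function(m) as.numeric(m[-1, 1]), numeric(q))
      ints <- vapply(co, function(m) m[1, 1], numeric(1))
      colnames(coefs) <- names(ints) <- c("DA", "5HT", "pH")
      cells[[i, j]] <- list(cell = c(i, j), coefficients = coefs,
                            intercepts = ints, alpha = best$alpha,
                            lambda = best$lambda, cv_error = best$cv_error,
                            n_train = nrow(cd$features))
    }
  }
  structure(list(cells = cells, grid = grid, alphas = alphas,
                 feature_width = q, waveform = waveform),
            class = "grid_model_set")
}

#' @export
print.grid_model_set <- function(x, ...) {
  n <- x$grid$n_ranges
  cat(sprintf("grid_model_set: %dx%d cells, %d features, alphas {%s}\n",
              n, n, x$feature_width,
              paste(format(x$alphas), collapse = ", ")))
  a <- matrix(vapply(x$cells, function(c) c$alpha, numeric(1)), n, n)
  cat("chosen alpha per cell:\n"); print(a)
  invisible(x)
}

#' Predict concentrations with every grid cell
#'
#' @param models A [fit_grid()] result.
#' @param sweeps A `session_recording`, an `invitro_dataset`, or a raw
#'   sweep matrix (rows = sweeps). Sweeps are differentiated with the
#'   training convention before prediction.
#' @return n x n list of N x 3 prediction matrices (DA, `5HT`, pH).
#' @export
predict_all_cells <- function(models, sweeps) {
  stopifnot(inherits(models, "grid_model_set"))
  m <- if (inherits(sweeps, "session_recording")) sweeps$sweeps
       else if (inherits(sweeps, "invitro_dataset")) sweeps$current
       else sweeps
  x <- differentiate(m)
  if (ncol(x) != models$feature_width)
    stop("feature width ", ncol(x), " does not match training width ",
         models$feature_width, call. = FALSE)
  n <- models$grid$n_ranges
  out <- vector("list", n^2); dim(out) <- c(n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    cell <- models$cells[[i, j]]
    y <- x %*% cell$coefficients
    out[[i, j]] <- sweep(y, 2, cell$intercepts, `+`)
  }
  out
}

# Modal sign with the tie convention: a cell is inadmissible only when -1
# is the strict modal sign category (ties break toward admissible).
modal_sign_is_negative <- function(y) {
  s <- sign(y)
  n_neg <- sum(s == -1)
  n_neg > sum(s == 0) && n_neg > sum(s == 1)
}

#' Select the in vivo prediction via the range-midpoint error rule
#'
#' For each cell and each monoamine, the error e is the sum of squared
#' deviations of the cell's predictions from the midpoint of its training
#' range — set to infinity when the modal sign of the predictions is
#' negative (a physically inadmissible cell). pH is ignored. The cell
#' minimizing e(DA) + e(5-HT) supplies the session's predictions.
#'
#' @param cell_predictions Output of [predict_all_cells()].
#' @param grid The [grid_spec()] the models were trained on.
#' @param timestamps Optional timestamps to attach (s).
#' @param analytes Which monoamines' error terms drive selection (default
#'   both, the in vivo rule). In vitro evaluation on single-analyte
#'   ladders restricts selection to the varied analyte, because the
#'   modal-sign admissibility of an analyte whose true concentration is
#'   exactly zero is a coin flip.
#' @param sign_rule Apply the modal-sign admissibility rule (default
#'   TRUE).
#' @return A `prediction_series`: `timestamps`, `DA`, `5HT`, `pH`,
#'   `chosen_cell` (i, j), `cell_errors` (n x n, `Inf` where
#'   inadmissible).
#' @export
select_prediction <- function(cell_predictions, grid, timestamps = NULL,
                              analytes = c("DA", "5HT"),
                              sign_rule = TRUE) {
  n <- grid$n_ranges
  e <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    y <- cell_predictions[[i, j]]
    term <- function(a, mid) {
      if (!a %in% analytes) return(0)
      if (sign_rule && modal_sign_is_negative(y[, a])) return(Inf)
      sum((y[, a] - mid)^2)
    }
    e[i, j] <- term("DA", grid$midpoints[i]) +
      term("5HT", grid$midpoints[j])
  }
  if (all(!is.finite(e)))
    stop("no admissible cell: every cell's modal predicted sign is negative",
         call. = FALSE)
  # argmin with ties broken in row-major order (lowest i, then j)
  best <- which(t(e) == min(e), arr.ind = TRUE)[1, , drop = TRUE]
  chosen <- c(best[[2]], best[[1]])
  y <- cell_predictions[[chosen[1], chosen[2]]]
  structure(list(timestamps = timestamps %||% seq_len(nrow(y)),
                 DA = y[, "DA"], `5HT` = y[, "5HT"], pH = y[, "pH"],
                 chosen_cell = chosen, cell_errors = e),
            class = "prediction_series")
}

#' Decode a session end to end
#'
#' @param models A [fit_grid()] result.
#' @param session A `session_recording`.
#' @return A `prediction_series` with the session's timestamps.
#' @export
decode_session <- function(models, session) {
  stopifnot(inherits(session, "session_recording"))
  preds <- predict_all_cells(models, session)
  select_prediction(preds, models$grid, session$timestamps)
}

#' Evaluate the decoder on naive probes withheld from training
#'
#' Three assessments against probes the model never saw:
#' \describe{
#'   \item{single_analyte}{DA and 5-HT ladders split into thirds spanning
#'     1500 nM each; per third, predicted vs known summarized by slope,
#'     intercept and R-squared.}
#'   \item{ph_sweep}{pH varied with both monoamines absent; the induced
#'     spurious DA and 5-HT excursions are reported relative to the
#'     predicted response to a 900 nM true step on the same probe.}
#'   \item{mixture}{optional mixed DA + 5-HT solutions at stable pH;
#'     per-analyte recovery error.}
#' }
#'
#' @param models A [fit_grid()] result.
#' @param naive List of per-probe dataset bundles (as from
#'   [generate_probe_datasets()]) for probes absent from the pool.
#' @param mixtures Optional list of `invitro_dataset`-shaped mixture sets
#'   whose `labels` carry the true DA and 5-HT values.
#' @return A `naive_evaluation` list with data.frames `single_analyte`,
#'   `ph_sweep` and (optionally) `mixture`.
#' @export
evaluate_on_naive_probes <- function(models, naive, mixtures = NULL) {
  grid <- models$grid
  third_edges <- seq(0, grid$breaks[length(grid$breaks)], length.out = 4)
  single <- list(); phs <- list()
  for (p in seq_along(naive)) {
    bundle <- naive[[p]]
    pid <- bundle$DA$probe_id
    for (a in c("DA", "5HT")) {
      ds <- bundle[[a]]
      known <- ds$labels[[a]]
      bin <- findInterval(known, third_edges, rightmost.closed = TRUE)
      for (th in 1:3) {
        rows <- which(bin == th)
        if (length(rows) < 10) next
        preds <- predict_all_cells(models, ds$current[rows, , drop = FALSE])
        sel <- select_prediction(preds, grid, analytes = a)
        fit <- stats::lm(sel[[a]] ~ known[rows])
        single[[length(single) + 1L]] <- data.frame(
          probe = pid, analyte = a, third = th,
          slope = unname(stats::coef(fit)[2]),
          intercept = unname(stats::coef(fit)[1]),
          r2 = summary(fit)$r.squared, n = length(rows))
      }
    }
    ph_ds <- bundle$pH
    sel_ph <- select_prediction(predict_all_cells(models, ph_ds$current),
                                grid, sign_rule = FALSE)
    # systematic excursion: range of the per-pH-level mean prediction
    # (averages measurement noise out of the specificity estimate)
    level_range <- function(pred, level) {
      mu <- tapply(pred, level, mean)
      max(mu) - min(mu)
    }
    # reference: predicted response to a 900 nM true step on this probe
    step_resp <- function(analyte) {
      ds <- bundle[[analyte]]
      known <- ds$labels[[analyte]]
      sel <- select_prediction(predict_all_cells(models, ds$current), grid,
                               analytes = analyte)
      lo <- known <= min(known) + 1e-9
      hi <- abs(known - 900) <= 450
      abs(mean(sel[[analyte]][hi]) - mean(sel[[analyte]][lo]))
    }
    phs[[length(phs) + 1L]] <- data.frame(
      probe = pid,
      da_excursion = level_range(sel_ph$DA, ph_ds$labels$pH),
      ht_excursion = level_range(sel_ph$`5HT`, ph_ds$labels$pH),
      da_step900 = step_resp("DA"), ht_step900 = step_resp("5HT"))
  }
  out <- list(single_analyte = do.call(rbind, single),
              ph_sweep = do.call(rbind, phs))
  if (!is.null(mixtures)) {
    mix <- lapply(mixtures, function(ds) {
      sel <- select_prediction(predict_all_cells(models, ds$current), grid)
      data.frame(probe = ds$probe_id,
                 da_true = mean(ds$labels$DA), ht_true = mean(ds$labels$`5HT`),
                 da_pred = mean(sel$DA), ht_pred = mean(sel$`5HT`))
    })
    out$mixture <- do.call(rbind, mix)
  }
  class(out) <- "naive_evaluation"
  out
}

#' Generate a fixed-concentration mixture dataset on a probe
#'
#' Constant DA and 5-HT concentrations at stable pH, used by the
#' naive-probe mixture evaluation.
#'
#' @param probe A [sample_probe_model()] result.
#' @param da,ht True concentrations (nM).
#' @param n_sweeps Number of sweeps.
#' @param seed RNG seed.
#' @export
generate_mixture_dataset <- function(probe, da, ht, n_sweeps = 100,
                                     seed = 1) {
  t <- (seq_len(n_sweeps) - 1) * probe$waveform$repetition_period
  cur <- with_seed(seed, synthesize_sweep_matrix(probe, da, ht, 7.4, t))
  structure(list(current = cur,
                 labels = data.frame(DA = da, `5HT` = ht, pH = 7.4,
                                     check.names = FALSE)[rep(1, n_sweeps), ],
                 time = t, quarter = rep(3L, n_sweeps),
                 level = NULL, analyte = "mixture",
                 probe_id = probe$probe_id, waveform = probe$waveform),
            class = "invitro_dataset")
}
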