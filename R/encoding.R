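#' Per-timepoint two-sample t test between conditions
#'
#' Classic (equal-variance) independent-samples t test at every timepoint
#' of two snippet tensors on the same time axis, with a significance mask
#' at p < 0.05. No multiple-comparison correction is applied across
#' timepoints — the package mirrors the exploratory convention of
#' reporting uncorrected per-timepoint tests, and annotates it.
#'
#' @param tensor_a,tensor_b `snippet_tensor`s with identical time axes.
#' @return data.frame: `time`, `mean_a`, `mean_b`, `t`, `df`, `p`, `sig`.
#' @export
timepoint_two_sample <- function(tensor_a, tensor_b) {
  stopifnot(isTRUE(all.equal(tensor_a$time_axis, tensor_b$time_axis)))
  a <- tensor_a$values; b <- tensor_b$values
  na <- nrow(a); nb <- nrow(b)
  if (na < 2 || nb < 2)
    stop("each group needs at least 2 trials", call. = FALSE)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tt <- ifelse(se > 0, (ma - mb) / se, 0)
  df <- na + nb - 2
  p <- ifelse(se > 0, 2 * stats::pt(-abs(tt), df), 1)
  data.frame(time = tensor_a$time_axis, mean_a = ma, mean_b = mb,
             t = tt, df = df, p = p, sig = p < 0.05)
}

#' Per-timepoint one-sample t test against zero
#'
#' @param tensor A `snippet_tensor`.
#' @return data.frame: `time`, `mean`, `t`, `df`, `p`, `sig`.
#' @export
timepoint_one_sample <- function(tensor) {
  v <- tensor$values
  n <- nrow(v)
  if (n < 2) stop("need at least 2 trials", call. = FALSE)
  m <- colMeans(v)
  se <- apply(v, 2, stats::sd) / sqrt(n)
  tt <- ifelse(se > 0, m / se, 0)
  p <- ifelse(se > 0, 2 * stats::pt(-abs(tt), n - 1), 1)
  data.frame(time = tensor$time_axis, mean = m, t = tt, df = n - 1,
             p = p, sig = p < 0.05)
}

# Build the z-scored encoding design from a tensor's trial metadata.
# Coherence and distance enter as their two-level condition codes; the
# interaction is the product of the z-scored mains, itself z-scored;
# accuracy and log RT are nuisance covariates.
encoding_design <- function(meta, group_mode = "pooled-intercepts") {
  zc <- zscore(as.numeric(meta$coherence_level == "high"))
  zd <- zscore(as.numeric(meta$distance_level == "high"))
  zx <- zscore(zc * zd)
  za <- zscore(meta$accuracy)
  zr <- zscore(log(meta$rt))
  X <- cbind(coherence = zc, distance = zd, interaction = zx,
             accuracy = za, log_rt = zr)
  part <- meta$participant %||% meta$session_id
  if (group_mode == "pooled-intercepts" && length(unique(part)) > 1) {
    P <- stats::model.matrix(~ 0 + factor(part))
    colnames(P) <- paste0("intercept_", unique(sort(part)))
    X <- cbind(P, X)
  } else {
    X <- cbind(intercept = 1, X)
  }
  # drop constant (zero after z-scoring) predictors, keeping intercepts
  keep <- apply(X, 2, function(col) stats::sd(col) > 0) |
    grepl("^intercept", colnames(X))
  if (any(!keep))
    warning("dropping constant predictor(s): ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
  X[, keep, drop = FALSE]
}

#' Sliding-window encoding regression
#'
#' At every timepoint, ordinary least squares of the neuromodulator
#' response across trials on z-scored coherence and distance condition
#' codes, their interaction, and choice accuracy and log choice RT as
#' nuisance variables. With multiple participants (or sessions) in the
#' tensor, one intercept per participant is included
#' (`group_mode = "pooled-intercepts"`). Returns the encoding profile:
#' per-timepoint coefficients with standard errors, t statistics and
#' uncorrected p values.
#'
#' @param tensor A preprocessed `snippet_tensor` (rows joined to
#'   `tensor$trial_meta`).
#' @param group_mode `"pooled-intercepts"` (default) or `"single"`.
#' @return An `encoding_profile`: list with `time_axis`, `predictors`,
#'   matrices `coef`, `se`, `t`, `p` (predictors x timepoints) and
#'   `n_trials`.
#' @export
sliding_encoding_regression <- function(tensor,
                                        group_mode = "pooled-intercepts") {
  X <- encoding_design(tensor$trial_meta, group_mode)
  Y <- tensor$values
  n <- nrow(X); p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) {
    drop_cols <- qx$pivot[(qx$rank + 1):p]
    warning("rank-deficient design; dropping: ",
            paste(colnames(X)[drop_cols], collapse = ", "), call. = FALSE)
    X <- X[, -drop_cols, drop = FALSE]
    p <- ncol(X)
  }
  xtx_inv <- chol2inv(chol(crossprod(X)))
  B <- xtx_inv %*% crossprod(X, Y)              # p x T
  resid <- Y - X %*% B
  sigma2 <- colSums(resid^2) / (n - p)
  se <- sqrt(outer(diag(xtx_inv), sigma2))
  tt <- ifelse(se > 0, B / se, 0)
  pv <- 2 * stats::pt(-abs(tt), n - p)
  rownames(B) <- rownames(se) <- rownames(tt) <- rownames(pv) <- colnames(X)
  structure(list(time_axis = tensor$time_axis, predictors = colnames(X),
                 coef = B, se = se, t = tt, p = pv, n_trials = n,
                 df = n - p),
            class = "encoding_profile")
}

#' @export
as.data.frame.encoding_profile <- function(x, ...) {
  do.call(rbind, lapply(x$predictors, function(pr) {
    data.frame(predictor = pr, time = x$time_axis,
               coef = x$coef[pr, ], se = x$se[pr, ],
               t = x$t[pr, ], p = x$p[pr, ], row.names = NULL)
  }))
}

#' Mean time courses by choice-RT tercile
#'
#' Trials are split at the 1/3 and 2/3 quantiles of raw choice RT (ties
#' resolved deterministically by rank with stable ordering) and each
#' group's mean time course is returned.
#'
#' @param tensor A `snippet_tensor` whose `trial_meta` carries `rt`.
#' @return List: `means` (3 x timepoints), `time_axis`, `group_sizes`,
#'   `tercile` (per-trial assignment).
#' @export
rt_tercile_profiles <- function(tensor) {
  rt <- tensor$trial_meta$rt
  n <- length(rt)
  if (n < 3) stop("need at least 3 trials for terciles", call. = FALSE)
  rk <- rank(rt, ties.method = "first")
  terc <- 1L + (rk > ceiling(n / 3)) + (rk > ceiling(2 * n / 3))
  means <- t(vapply(1:3, function(g)
    colMeans(tensor$values[terc == g, , drop = FALSE]),
    numeric(ncol(tensor$values))))
  rownames(means) <- c("fast", "medium", "slow")
  list(means = means, time_axis = tensor$time_axis,
       group_sizes = tabulate(terc, 3), tercile = terc)
}
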