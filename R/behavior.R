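#' Prepare pooled trial data for the behavioral regressions
#'
#' Log-transforms choice RT, then z-scores all analysis variables except
#' choice accuracy separately within each session: the coherence and
#' distance condition codes, their interaction, log RT, and confidence
#' (where present). Guarded against double application via the
#' `"scaled"` attribute.
#'
#' @param table A pooled trial table with a `participant` column (falls
#'   back to `session_id`).
#' @return The table with columns `zc`, `zd`, `zcd`, `zlogrt`, `zconf`
#'   added and attribute `scaled = TRUE`.
#' @export
prepare_behavior_data <- function(table) {
  if (isTRUE(attr(table, "scaled")))
    stop("table is already scaled; refusing to z-score twice",
         call. = FALSE)
  if (is.null(table$participant)) table$participant <- table$session_id
  out <- do.call(rbind, lapply(split(table, table$session_id), function(s) {
    s$zc <- zscore(as.numeric(s$coherence_level == "high"))
    s$zd <- zscore(as.numeric(s$distance_level == "high"))
    s$zcd <- zscore(s$zc * s$zd)
    s$zlogrt <- zscore(log(s$rt))
    s$zconf <- NA_real_
    has_conf <- !is.na(s$confidence)
    if (sum(has_conf) > 2)
      s$zconf[has_conf] <- zscore(s$confidence[has_conf])
    s
  }))
  rownames(out) <- NULL
  attr(out, "scaled") <- TRUE
  out
}

glue_fixef <- function(model, fit, normal_approx = TRUE) {
  s <- if (inherits(fit, "merMod")) stats::coef(summary(fit)) else
    summary(fit)$coefficients
  terms <- intersect(rownames(s), c("zc", "zd", "zcd"))
  stat_col <- if ("z value" %in% colnames(s)) "z value" else "t value"
  stat <- s[terms, stat_col]
  p <- if ("Pr(>|z|)" %in% colnames(s)) s[terms, "Pr(>|z|)"] else
    2 * stats::pnorm(-abs(stat))
  data.frame(model = model,
             term = c(zc = "coherence", zd = "distance",
                      zcd = "interaction")[terms],
             estimate = s[terms, "Estimate"], stat = stat, p = p,
             row.names = NULL)
}

#' Hierarchical behavioral regressions
#'
#' Mixed-effects regressions over pooled sessions predicting choice
#' accuracy (logistic), z-scored log choice RT (linear), and z-scored
#' confidence (linear) from the z-scored coherence and distance condition
#' codes and their interaction, with participant-level slopes and
#' intercepts. Group-level fixed effects are reported with their test
#' statistic and p value (normal approximation for the linear models,
#' appropriate at these trial counts). A single-participant table falls
#' back to ordinary regression with a warning.
#'
#' @param table A pooled trial table (raw; scaling is applied internally
#'   via [prepare_behavior_data()]).
#' @return A `behavior_fit` list: `coefficients` (long data.frame),
#'   `fits` (the underlying model objects).
#' @export
fit_behavior_models <- function(table) {
  dat <- prepare_behavior_data(table)
  multi <- length(unique(dat$participant)) > 1
  fits <- list(); rows <- list()
  conf_dat <- dat[!is.na(dat$zconf), , drop = FALSE]
  if (multi) {
    re <- "(1 + zc + zd + zcd | participant)"
    fits$accuracy <- suppressMessages(suppressWarnings(
      lme4::glmer(stats::as.formula(paste("accuracy ~ zc + zd + zcd +", re)),
                  data = dat, family = stats::binomial())))
    fits$rt <- suppressMessages(suppressWarnings(
      lme4::lmer(stats::as.formula(paste("zlogrt ~ zc + zd + zcd +", re)),
                 data = dat)))
    fits$confidence <- suppressMessages(suppressWarnings(
      lme4::lmer(stats::as.formula(paste("zconf ~ zc + zd + zcd +", re)),
                 data = conf_dat)))
  } else {
    warning("single participant: falling back to ordinary regression",
            call. = FALSE)
    fits$accuracy <- stats::glm(accuracy ~ zc + zd + zcd, data = dat,
                                family = stats::binomial())
    fits$rt <- stats::lm(zlogrt ~ zc + zd + zcd, data = dat)
    fits$confidence <- stats::lm(zconf ~ zc + zd + zcd, data = conf_dat)
  }
  coefs <- rbind(glue_fixef("accuracy", fits$accuracy),
                 glue_fixef("rt", fits$rt),
                 glue_fixef("confidence", fits$confidence))
  structure(list(coefficients = coefs, fits = fits),
            class = "behavior_fit")
}
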