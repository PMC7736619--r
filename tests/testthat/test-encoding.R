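test_that("identical groups give t = 0 and p = 1 at every timepoint", {
  x <- matrix(rnorm(20 * 61), 20)
  a <- fake_tensor(x); b <- fake_tensor(x)
  res <- timepoint_two_sample(a, b)
  expect_true(all(res$t == 0))
  expect_true(all(res$p == 1))
  expect_false(any(res$sig))
  expect_error(timepoint_two_sample(fake_tensor(x[1, , drop = FALSE]), b),
               "at least 2")
})

test_that("a localized mean offset is detected in and around its columns", {
  set.seed(31)
  a <- matrix(rnorm(200 * 61), 200)
  b <- matrix(rnorm(200 * 61), 200)
  b[, 10:15] <- b[, 10:15] + 0.8
  res <- timepoint_two_sample(fake_tensor(a), fake_tensor(b))
  expect_true(all(res$sig[10:15]))
  expect_lt(mean(res$sig[-(8:17)]), 0.15)
})

test_that("the one-sample t statistic matches its closed form", {
  z <- fake_tensor(matrix(0, 10, 61))
  res0 <- timepoint_one_sample(z)
  expect_true(all(res0$t == 0 & res0$p == 1))

  set.seed(32)
  c0 <- 0.4; sigma <- 1.3; n <- 100
  x <- matrix(rnorm(n * 61, c0, sigma), n)
  res <- timepoint_one_sample(fake_tensor(x))
  expect_equal(mean(res$t), c0 * sqrt(n) / sigma, tolerance = 0.1)
})

test_that("per-trial z-scored tensors have near-zero grand mean", {
  set.seed(33)
  raw <- fake_tensor(matrix(rnorm(50 * 61, 5, 2), 50))
  raw$zscored <- FALSE
  z <- znorm_per_trial(raw)
  expect_lt(abs(mean(z$values)), 1e-12)
})

make_design_tensor <- function(n = 120, beta = NULL, seed = 1) {
  set.seed(seed)
  meta <- data.frame(
    trial_index = seq_len(n) - 1L, session_id = "s1",
    coherence_level = sample(c("low", "high"), n, TRUE),
    distance_level = sample(c("low", "high"), n, TRUE),
    accuracy = rbinom(n, 1, 0.7), rt = rlnorm(n, 0, 0.3))
  vals <- matrix(rnorm(n * 61), n)
  if (!is.null(beta)) {
    zc <- scale(as.numeric(meta$coherence_level == "high"))[, 1]
    vals[, 15:25] <- vals[, 15:25] + beta * zc
  }
  fake_tensor(vals, meta = meta)
}

test_that("the sliding regression equals a direct per-timepoint solve", {
  tens <- make_design_tensor(100, beta = 0.5)
  prof <- sliding_encoding_regression(tens)
  # oracle: plain lm at a single timepoint on the same design
  m <- tens$trial_meta
  zc <- scale(as.numeric(m$coherence_level == "high"))[, 1]
  zd <- scale(as.numeric(m$distance_level == "high"))[, 1]
  zx <- scale(zc * zd)[, 1]
  za <- scale(m$accuracy)[, 1]
  zr <- scale(log(m$rt))[, 1]
  for (tp in c(1, 20, 61)) {
    fit <- lm(tens$values[, tp] ~ zc + zd + zx + za + zr)
    expect_lt(max(abs(coef(fit)[-1] -
                        prof$coef[c("coherence", "distance", "interaction",
                                    "accuracy", "log_rt"), tp])), 1e-8)
  }
  expect_equal(prof$df, 100 - 6)
})

test_that("an injected coherence effect is recovered where it was placed", {
  tens <- make_design_tensor(300, beta = 0.6, seed = 7)
  prof <- sliding_encoding_regression(tens)
  sig <- prof$p["coherence", ] < 0.05 & prof$coef["coherence", ] > 0
  expect_true(all(sig[16:24]))
  expect_lt(mean(sig[-(14:26)]), 0.15)
})

test_that("a null design produces ~5% spurious significance", {
  set.seed(8)
  hits <- vapply(1:60, function(k) {
    prof <- sliding_encoding_regression(make_design_tensor(60, seed = k))
    mean(prof$p["coherence", ] < 0.05)
  }, numeric(1))
  expect_gt(mean(hits), 0.02)
  expect_lt(mean(hits), 0.09)
})

test_that("a per-participant offset is absorbed by that intercept only", {
  tens <- make_design_tensor(160, beta = 0.5, seed = 3)
  tens$trial_meta$participant <-
    rep(c("p1", "p2"), length.out = 160)
  base <- sliding_encoding_regression(tens)
  shifted <- tens
  shifted$values[shifted$trial_meta$participant == "p2", ] <-
    shifted$values[shifted$trial_meta$participant == "p2", ] + 5
  prof <- sliding_encoding_regression(shifted)
  shared <- c("coherence", "distance", "interaction", "accuracy", "log_rt")
  expect_equal(prof$coef[shared, ], base$coef[shared, ], tolerance = 1e-8)
  expect_equal(mean(prof$coef["intercept_p2", ] -
                      base$coef["intercept_p2", ]), 5, tolerance = 1e-8)
})

test_that("constant predictors are dropped with a warning", {
  tens <- make_design_tensor(80, seed = 4)
  tens$trial_meta$accuracy <- 1
  expect_warning(prof <- sliding_encoding_regression(tens),
                 "constant predictor")
  expect_false("accuracy" %in% prof$predictors)
})

test_that("RT terciles split 33/33/33 with deterministic tie handling", {
  tens <- make_design_tensor(99, seed = 5)
  tens$trial_meta$rt <- 1:99
  tp <- rt_tercile_profiles(tens)
  expect_equal(tp$group_sizes, c(33, 33, 33))

  tens$trial_meta$rt <- rep(1, 99)  # full ties: stable rank order
  tp2 <- rt_tercile_profiles(tens)
  expect_equal(tp2$group_sizes, c(33, 33, 33))
  expect_equal(tp2$tercile[1:33], rep(1L, 33))
  small <- tens; small$values <- small$values[1:2, ]
  small$trial_meta <- small$trial_meta[1:2, ]
  expect_error(rt_tercile_profiles(small), "at least 3")
})

test_that("choice-locked ramps peak at the choice in every tercile", {
  axis <- seq(-4, 4, by = 0.1)
  n <- 90
  set.seed(6)
  ramp <- exp(-(axis)^2 / (2 * 0.3^2))   # peak at 0 s (choice)
  vals <- matrix(rep(ramp, n), n, byrow = TRUE) +
    matrix(rnorm(n * 81, 0, 0.05), n)
  tens <- fake_tensor(vals, lock = "choice")
  tens$trial_meta$rt <- rlnorm(n)
  tp <- rt_tercile_profiles(tens)
  for (g in 1:3)
    expect_lte(abs(axis[which.max(tp$means[g, ])]), 0.1 + 1e-9)
})
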