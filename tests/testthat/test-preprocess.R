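test_that("RT outliers and session endpoints are excluded with reasons", {
  tab <- fake_trial_table(100)
  tab$rt <- rep(1, 100)
  tab$rt[50] <- 1 + 10 * 0.1
  tab$rt <- tab$rt + rnorm(100, 0, 0.1)  # base variability
  tab$rt[50] <- mean(tab$rt[-50]) + 10 * sd(tab$rt[-50])
  out <- exclude_trials(tab)
  log <- attr(out, "exclusion_log")
  expect_equal(nrow(out), 97)
  expect_setequal(log$trial_index, c(0L, 49L, 99L))
  expect_true(any(grepl("RT", log$reason)))
})

test_that("degenerate RT spread excludes only the endpoints", {
  tab <- fake_trial_table(20)
  tab$rt <- rep(0.8, 20)
  out <- exclude_trials(tab)
  expect_equal(nrow(out), 18)
  expect_setequal(attr(out, "exclusion_log")$trial_index, c(0L, 19L))
})

test_that("exclusion is idempotent when recomputation is disabled", {
  tab <- fake_trial_table(60)
  once <- exclude_trials(tab)
  again <- exclude_trials(once, recompute = FALSE)
  expect_identical(again, once)
  # recomputing does re-apply the endpoint rule to the filtered table
  twice <- exclude_trials(once)
  expect_equal(nrow(twice), nrow(once) - 2)
  expect_error(exclude_trials(fake_trial_table(5)[1:4, ]),
               "fewer than 4")
})

series_const <- function(v = 2.5, t_max = 600) {
  ts <- seq(0, t_max, by = 0.1)
  list(timestamps = ts, DA = rep(v, length(ts)),
       `5HT` = rep(v, length(ts)), pH = rep(7.4, length(ts)))
}

test_that("snippet windows have the fixed column counts", {
  tab <- fake_trial_table(12)
  st <- extract_snippets(series_const(), tab, "stimulus", "5HT")
  expect_equal(ncol(st$values), 61)
  expect_equal(range(st$time_axis), c(-1, 5))
  ch <- extract_snippets(series_const(), tab, "choice", "DA")
  expect_equal(ncol(ch$values), 81)
  expect_equal(range(ch$time_axis), c(-4, 4))
  expect_true(all(st$values == 2.5))  # constant series -> constant rows
})

test_that("trials whose windows leave the recording are dropped with a warning", {
  tab <- fake_trial_table(12)
  short <- series_const(t_max = 40)   # last trials fall outside
  expect_warning(st <- extract_snippets(short, tab, "stimulus", "5HT"),
                 "dropped")
  expect_lt(nrow(st$values), 12)
  expect_equal(nrow(st$values), nrow(st$trial_meta))
})

test_that("per-trial z-scoring normalizes rows and flags constants", {
  vals <- rbind(c(1, 2, 3), c(10, 10, 10), rnorm(3))
  tens <- fake_tensor(cbind(vals, matrix(rnorm(3 * 58), 3)))
  tens$zscored <- FALSE
  z <- znorm_per_trial(tens)
  expect_equal(unname(rowMeans(z$values)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(z$values, 1, sd)), rep(1, 3),
               tolerance = 1e-12)
  expect_error(znorm_per_trial(z), "already z-scored")

  const <- fake_tensor(matrix(7, 2, 61))
  const$zscored <- FALSE
  zc <- znorm_per_trial(const)
  expect_true(all(zc$values == 0))
  expect_equal(attr(zc, "constant_rows"), 1:2)
})

test_that("z-scoring is shape-invariant under affine transforms", {
  raw_tensor <- function(v) { t <- fake_tensor(v); t$zscored <- FALSE; t }
  x <- matrix(rnorm(4 * 61), 4)
  a <- znorm_per_trial(raw_tensor(x))
  b <- znorm_per_trial(raw_tensor(2.3 * x - 17))
  expect_equal(a$values, b$values, tolerance = 1e-10)
})

test_that("the running average is causal with the stated edge rule", {
  imp <- matrix(0, 1, 61); imp[1, 20] <- 1
  sm <- smooth_running(fake_tensor(imp))
  expect_equal(sm$values[1, 20:24], rep(0.2, 5))
  expect_equal(sum(sm$values[1, -(20:24)]), 0)

  const <- smooth_running(fake_tensor(matrix(3, 2, 61)))
  expect_true(all(const$values == 3))

  x <- matrix(rnorm(61), 1)
  sm2 <- smooth_running(fake_tensor(x))
  expect_equal(sm2$values[1, 1], x[1, 1])           # prefix of length 1
  expect_equal(sm2$values[1, 3], mean(x[1, 1:3]))   # growing prefix
  expect_equal(sm2$values[1, 61], mean(x[1, 57:61]))
  expect_error(smooth_running(fake_tensor(x), width = 0.13),
               "multiple of the sampling period")
})

test_that("smoothing commutes with averaging across trials", {
  x <- matrix(rnorm(30 * 61), 30)
  sm_then_mean <- colMeans(smooth_running(fake_tensor(x))$values)
  mean_then_sm <- smooth_running(fake_tensor(matrix(colMeans(x), 1)))$values
  expect_equal(sm_then_mean, drop(mean_then_sm), tolerance = 1e-10)
})

test_that("z-scoring before smoothing differs from the reverse order", {
  ts <- seq(0, 600, by = 0.1)
  series <- list(timestamps = ts,
                 `5HT` = 1000 + 300 * sin(ts / 3) + rnorm(length(ts), 0, 50),
                 DA = rep(0, length(ts)), pH = rep(7.4, length(ts)))
  tab <- fake_trial_table(10)
  z_then_s <- smooth_running(znorm_per_trial(
    extract_snippets(series, tab, "stimulus", "5HT")))
  s_then_z <- znorm_per_trial(smooth_running(
    extract_snippets(series, tab, "stimulus", "5HT")))
  expect_gt(max(abs(z_then_s$values - s_then_z$values)), 1e-6)
  # and preprocess_snippets applies the documented order
  std <- preprocess_snippets(series, tab, "stimulus", "5HT")
  expect_equal(std$values, z_then_s$values)
})
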