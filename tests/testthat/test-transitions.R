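test_that("a deterministic alternating sequence yields degenerate transitions", {
  n <- 40
  tab <- fake_trial_table(n)
  tab$coherence_level <- rep(c("low", "high"), n / 2)
  tab$distance_level <- "low"
  st <- transition_probabilities(tab)
  expect_equal(st$probabilities["lowC.lowD", "highC.lowD"], 1)
  expect_equal(st$probabilities["highC.lowD", "lowC.lowD"], 1)
  expect_equal(sum(st$counts), n - 1)
})

test_that("uniform sampling gives conditional probabilities near 0.25", {
  tab <- fake_trial_table(100000, seed = 9)
  st <- transition_probabilities(tab)
  expect_true(all(abs(st$probabilities - 0.25) < 0.01))
  expect_equal(unname(rowSums(st$probabilities)), rep(1, 4))
  expect_true(all(abs(st$marginals - 0.25) < 0.01))
})

test_that("pairs broken by excluded trials are dropped, not bridged", {
  tab <- fake_trial_table(10)
  tab$coherence_level <- "low"; tab$distance_level <- "low"
  kept <- tab[-c(1, 5, 10), ]   # breaks 4-6 adjacency
  st <- transition_probabilities(kept)
  expect_equal(st$n_pairs, 5)   # 2-3, 3-4, 6-7, 7-8, 8-9
})

test_that("transition responses average the stated window per pair", {
  tab <- fake_trial_table(60, seed = 10)
  vals <- matrix(2.5, 60, 61)
  tens <- fake_tensor(vals, meta = tab)
  tr <- transition_responses(tens)
  expect_equal(tr$window_samples, 16)  # 0.0 ... 1.5 s inclusive at 10 Hz
  occupied <- is.finite(tr$responses)
  expect_true(all(tr$responses[occupied] == 2.5))
  st <- transition_probabilities(tab)
  expect_error(transition_regression(
    list(responses = matrix(NA_real_, 4, 4),
         accuracy = matrix(NA_real_, 4, 4)), st),
    "fewer than 3")
})

test_that("responses constructed from probabilities are recovered with the right df", {
  tab <- fake_trial_table(4000, seed = 11)
  st <- transition_probabilities(tab)
  tp <- voltdecode:::transition_pairs(tab)
  # response on each trial = -2 * P(transition that produced it) + noise
  vals <- matrix(0, nrow(tab), 61)
  set.seed(12)
  ord <- order(tab$session_id, tab$trial_index)
  p_of <- st$probabilities[cbind(as.integer(tp$types[tp$prev]),
                                 as.integer(tp$types[tp$cur]))]
  vals[ord[tp$cur], ] <- -2 * p_of + rnorm(length(tp$cur), 0, 0.01)
  tens <- fake_tensor(vals, meta = tab)
  tr <- transition_responses(tens)
  # rank-inverse relation between responses and probabilities
  expect_lt(cor(as.vector(tr$responses), as.vector(st$probabilities),
                use = "complete.obs"), -0.9)
  reg <- transition_regression(tr, st)
  expect_equal(reg$simple$df, 14)       # 16 pairs, slope + intercept
  expect_equal(reg$controlled$df, 12)   # + marginal + accuracy controls
  expect_equal(reg$simple$slope, -2, tolerance = 0.15)
  expect_lt(reg$simple$p, 0.01)
})

test_that("an exactly linear relation recovers the generating slope", {
  resp <- list(responses = matrix(3 - 5 * (1:16) / 16, 4, 4),
               accuracy = matrix(0.7, 4, 4))
  st <- list(probabilities = matrix((1:16) / 16, 4, 4),
             marginals = rep(0.25, 4))
  class(st) <- "transition_stats"
  reg <- transition_regression(resp, st)
  expect_equal(reg$simple$slope, -5, tolerance = 1e-9)
  expect_true(is.finite(reg$simple$t))  # perfect fit capped, not NaN
})
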