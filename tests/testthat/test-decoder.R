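# Shared small fixtures: a reduced-scale pool and fitted grid (50-sample
# sweeps, 3 probes). Built once for the whole file.
twf <- tiny_waveform()
pool <- small_pool(waveform = twf, seed = 21)
grid <- grid_spec()
models <- fit_grid(pool, grid, alphas = c(0, 1), folds = 3, seed = 1,
                   nlambda = 20, waveform = twf)
mean_probe <- sample_probe_model(
  probe_population(waveform = twf, variation_scale = 0), 1)

test_that("differentiation produces first differences of width L - 1", {
  m <- matrix(rnorm(3000), 3, 1000)
  expect_equal(ncol(differentiate(m)), 999)
  expect_equal(differentiate(matrix(5, 2, 10)),
               matrix(0, 2, 9))
  ramp <- matrix(0.25 * (1:50), 1, 50)
  expect_equal(unique(as.vector(round(differentiate(ramp), 12))), 0.25)
  expect_error(differentiate(matrix(1, 2, 1)), "at least 2")
})

test_that("the training pool enforces counts and the third-quarter rule", {
  expect_equal(nrow(pool$features), 3 * (120 + 120 + 40))
  expect_equal(ncol(pool$features), twf$sweep_samples - 1L)
  expect_equal(unname(table(pool$analyte_of)["DA"]), 3 * 120)
  # re-drawing with another seed changes rows but not counts
  pool2 <- small_pool(waveform = twf, seed = 22)
  expect_equal(dim(pool2$features), dim(pool$features))
  expect_false(identical(pool$features, pool2$features))
  # a probe without enough third-quarter rows is named
  pr <- sample_probe_model(probe_population(waveform = twf), 77)
  tiny_sets <- list(generate_probe_datasets(
    pr, seed = 1, protocols = small_protocols(step = 1500, replicates = 1,
                                              dwell = 4)))
  expect_error(
    assemble_training_pool(tiny_sets, counts = c(DA = 120, `5HT` = 120,
                                                 pH = 40)),
    "third-quarter")
})

test_that("grid cells partition the monoamine rows and share pH rows", {
  expect_equal(grid$n_ranges, 5L)
  expect_true(all(abs(diff(grid$breaks) - 900) < 1e-9))
  expect_equal(grid$midpoints, c(450, 1350, 2250, 3150, 4050))

  da_total <- sum(pool$analyte_of == "DA")
  strata <- vapply(1:5, function(i) {
    cd <- build_cell_dataset(pool, grid, i, 1)
    sum(pool$analyte_of[cd$rows] == "DA")
  }, numeric(1))
  expect_equal(sum(strata), da_total)  # no loss, no overlap

  ph_rows <- which(pool$analyte_of == "pH")
  for (cell in list(c(1, 1), c(3, 4), c(5, 5))) {
    cd <- build_cell_dataset(pool, grid, cell[1], cell[2])
    expect_true(all(ph_rows %in% cd$rows))
    labs <- pool$labels[setdiff(cd$rows, ph_rows), ]
    da_in <- labs[pool$analyte_of[setdiff(cd$rows, ph_rows)] == "DA", "DA"]
    expect_true(all(da_in >= grid$breaks[cell[1]] &
                      da_in <= grid$breaks[cell[1] + 1]))
  }
})

test_that("the fitted grid has 25 cells with finite coefficients and recorded penalties", {
  expect_equal(dim(models$cells), c(5L, 5L))
  for (cell in models$cells) {
    expect_true(all(is.finite(cell$coefficients)))
    expect_true(cell$alpha %in% c(0, 1))
    expect_gt(cell$lambda, 0)
    expect_true(is.finite(cell$cv_error))
  }
  expect_equal(models$feature_width, twf$sweep_samples - 1L)
})

test_that("a noiseless linear pool is decoded almost perfectly out of sample", {
  pool0 <- small_pool(waveform = twf, noise_sd = 0, seed = 31)
  m0 <- fit_grid(pool0, grid, alphas = c(0, 1), folds = 3, seed = 1,
                 nlambda = 20, waveform = twf)
  pop0 <- probe_population(waveform = twf, noise_sd = 0,
                           drift_amplitude = 0)
  naive <- list(generate_probe_datasets(
    sample_probe_model(pop0, 991, probe_id = "naive"),
    seed = 991, protocols = small_protocols()))
  ev <- suppressWarnings(evaluate_on_naive_probes(m0, naive))
  expect_true(all(ev$single_analyte$r2 >= 0.99))
})

test_that("zero features predict the cell intercepts, deterministically", {
  z <- matrix(0, 4, twf$sweep_samples)
  preds <- predict_all_cells(models, z)
  for (i in 1:5) for (j in 1:5)
    expect_equal(preds[[i, j]][1, ],
                 models$cells[[i, j]]$intercepts)
  expect_identical(preds, predict_all_cells(models, z))
  expect_error(predict_all_cells(models, matrix(0, 2, 30)),
               "feature width")
})

test_that("each cell predicts its own concentration range best", {
  set.seed(44)
  wins <- vapply(1:20, function(r) {
    i <- sample(1:5, 1); j <- sample(1:5, 1)
    da <- grid$midpoints[i] + runif(30, -300, 300)
    ht <- grid$midpoints[j] + runif(30, -300, 300)
    cur <- synthesize_sweep_matrix(mean_probe, da, ht, 7.4,
                                   seq(0, 2.9, 0.1))
    preds <- predict_all_cells(models, cur)
    rmse <- matrix(NA_real_, 5, 5)
    for (a in 1:5) for (b in 1:5)
      rmse[a, b] <- sqrt(mean((preds[[a, b]][, "DA"] - da)^2 +
                                (preds[[a, b]][, "5HT"] - ht)^2))
    rmse[i, j] < mean(rmse[-((j - 1) * 5 + i)])
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("the e_ij selection rule follows the modal-sign and argmin conventions", {
  fake <- function(da, ht) cbind(DA = da, `5HT` = ht, pH = rep(7.4, 10))
  cells <- vector("list", 25); dim(cells) <- c(5, 5)
  for (i in 1:5) for (j in 1:5)
    cells[[i, j]] <- fake(rep(grid$midpoints[i], 10),
                          rep(grid$midpoints[j], 10))
  # majority-negative DA makes a cell inadmissible even with tiny error
  cells[[2, 2]] <- fake(c(rep(-1, 6), rep(1350, 4)), rep(1350, 10))
  sel <- select_prediction(cells, grid)
  expect_true(is.infinite(sel$cell_errors[2, 2]))
  # every admissible cell here has zero error; row-major tie break
  expect_equal(sel$chosen_cell, c(1, 1))

  # a single finite cell is selected regardless of magnitude
  for (i in 1:5) for (j in 1:5)
    cells[[i, j]] <- fake(rep(-5, 10), rep(-5, 10))
  cells[[4, 3]] <- fake(rep(4000, 10), rep(100, 10))
  sel2 <- select_prediction(cells, grid)
  expect_equal(sel2$chosen_cell, c(4, 3))
  expect_equal(sum(is.finite(sel2$cell_errors)), 1)

  # all cells inadmissible is an explicit error
  for (i in 1:5) for (j in 1:5)
    cells[[i, j]] <- fake(rep(-5, 10), rep(-5, 10))
  expect_error(select_prediction(cells, grid), "no admissible cell")

  # sign ties break toward admissible (zeros count as their own category)
  expect_false(voltdecode:::modal_sign_is_negative(c(-1, -1, 1, 1)))
  expect_false(voltdecode:::modal_sign_is_negative(c(-1, 0, 0, 1)))
  expect_true(voltdecode:::modal_sign_is_negative(c(-1, -1, -1, 1)))
})

test_that("decoded dopamine is monotone in true dopamine within a cell", {
  levels <- seq(1800, 2700, length.out = 10)  # inside DA range 3
  cur <- synthesize_sweep_matrix(mean_probe, rep(levels, each = 5), 2250,
                                 7.4, seq(0, 4.9, 0.1),
                                 noise_on = FALSE, drift_on = FALSE)
  preds <- predict_all_cells(models, cur)
  da_hat <- tapply(preds[[3, 3]][, "DA"], rep(levels, each = 5), mean)
  expect_true(all(diff(da_hat) > 0))
})

test_that("mixtures are recovered no worse than 1.5x the single-analyte error", {
  pop <- probe_population(waveform = twf)
  rel_err <- function(ds, a, true) {
    sel <- select_prediction(predict_all_cells(models, ds$current),
                             grid, analytes = a)
    abs(mean(sel[[a]]) - true) / true
  }
  errs <- vapply(1:8, function(r) {
    nv <- sample_probe_model(pop, 7000 + r, probe_id = "n")
    da_s <- generate_mixture_dataset(nv, 1200, 0, 60, seed = r)
    ht_s <- generate_mixture_dataset(nv, 0, 2000, 60, seed = 100 + r)
    mx <- generate_mixture_dataset(nv, 1200, 2000, 60, seed = 200 + r)
    c(da_single = rel_err(da_s, "DA", 1200),
      ht_single = rel_err(ht_s, "5HT", 2000),
      da_mix = rel_err(mx, "DA", 1200),
      ht_mix = rel_err(mx, "5HT", 2000))
  }, numeric(4))
  # compared in aggregate: a per-replicate ratio is unstable when the
  # single-analyte error happens to be near zero
  expect_lt(mean(errs["da_mix", ]), 1.5 * mean(errs["da_single", ]))
  expect_lt(mean(errs["ht_mix", ]), 1.5 * mean(errs["ht_single", ]))
})

test_that("affine gain miscalibration leaves z-scored snippets unchanged", {
  ts <- seq(0, 59.9, by = 0.1)
  x <- 1000 + 200 * sin(ts)
  mk <- function(v) list(timestamps = ts, DA = v, `5HT` = v, pH = 7.4)
  tab <- fake_trial_table(8)
  a <- znorm_per_trial(extract_snippets(mk(x), tab, "stimulus", "5HT"))
  b <- znorm_per_trial(extract_snippets(mk(3.7 * x + 250), tab,
                                        "stimulus", "5HT"))
  expect_equal(a$values, b$values, tolerance = 1e-10)
})
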