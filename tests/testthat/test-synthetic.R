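test_that("worlds are bit-identical under a seed and structurally stable", {
  a <- simulate_ie_world(n_chemicals = 15, n_conditions = 2, seed = 9)
  b <- simulate_ie_world(n_chemicals = 15, n_conditions = 2, seed = 9)
  expect_identical(a$data$measurements, b$data$measurements)
  expect_identical(a$world$descriptors, b$world$descriptors)
  c_ <- simulate_ie_world(n_chemicals = 15, n_conditions = 2, seed = 10)
  # same structure (chemical ids, conditions), different noise draws
  expect_identical(a$world$chemicals$compound_id,
                   c_$world$chemicals$compound_id)
  expect_false(identical(a$data$measurements$log_ie,
                         c_$data$measurements$log_ie))
  expect_error(simulate_ie_world(n_chemicals = 5), "at least 10")
  expect_error(simulate_ie_world(noise_sd = -1), "non-negative")
})

test_that("zero noise makes observations equal the true IE surface", {
  s <- simulate_ie_world(n_chemicals = 12, n_conditions = 2, noise_sd = 0,
                         seed = 2)
  expect_equal(s$data$measurements$log_ie, s$data$measurements$true_log_ie)
  # the oracle reproduces the truth from features
  x <- build_feature_matrix(s$data, s$world$provider)
  expect_equal(predict_log_ie(s$world$oracle, x),
               s$data$measurements$true_log_ie, tolerance = 1e-12)
})

test_that("empirical noise sd matches the requested level", {
  s <- simulate_ie_world(n_chemicals = 500, n_conditions = 5, noise_sd = 0.2,
                         n_descriptors = 6, seed = 33)
  resid <- s$data$measurements$log_ie - s$data$measurements$true_log_ie
  expect_equal(sd(resid), 0.2, tolerance = 0.05)
})

test_that("noiseless calibration recovers every true RF and the bridge", {
  s <- simulate_ie_world(n_chemicals = 15, n_conditions = 2, noise_sd = 0,
                         seed = 4)
  cal <- simulate_calibration(s$world, area_noise_cv = 0, seed = 4)
  for (cid in names(cal$series)) {
    fit <- fit_response_factor(cal$series[[cid]]$concentration,
                               cal$series[[cid]]$area)
    expect_equal(log10(fit$response_factor), cal$true_log_rf[[cid]],
                 tolerance = 1e-9)
  }
  ef <- eluent_features(cal$condition)
  ie <- vapply(names(cal$series), function(cid) {
    s$world$oracle$fun(c(molecular_features(cid, s$world$provider), ef))
  }, numeric(1))
  b <- fit_ie_rf_bridge(ie, cal$true_log_rf)
  expect_equal(b$slope, cal$bridge_slope, tolerance = 1e-9)
  expect_equal(b$intercept, cal$bridge_intercept, tolerance = 1e-9)
})

test_that("moderate area noise keeps median RF recovery tight", {
  s <- simulate_ie_world(n_chemicals = 100, n_conditions = 1, noise_sd = 0,
                         seed = 12)
  cal <- simulate_calibration(s$world, levels = 7, area_noise_cv = 0.05,
                              seed = 12)
  folds <- vapply(names(cal$series), function(cid) {
    fit <- fit_response_factor(cal$series[[cid]]$concentration,
                               cal$series[[cid]]$area)
    fold_error(fit$response_factor, 10^cal$true_log_rf[[cid]])
  }, numeric(1))
  expect_lt(median(folds), 1.05)
})

test_that("sample peaks conserve signal through splitting and dilution", {
  s <- simulate_ie_world(n_chemicals = 12, n_conditions = 1, noise_sd = 0,
                         seed = 21)
  cal <- simulate_calibration(s$world, area_noise_cv = 0, seed = 21)
  truth <- data.frame(sample_id = "S1",
                      compound_id = s$world$chemicals$compound_id[1:5],
                      conc_ng_g = c(10, 20, 50, 100, 7))
  peaks <- simulate_sample_peaks(s$world, truth, cal$true_log_rf,
                                 fragment_split = c(0.7, 0.3), seed = 21)
  for (i in seq_len(nrow(truth))) {
    cid <- truth$compound_id[i]
    sub <- peaks[peaks$compound_id == cid, ]
    meta <- s$world$chemicals[s$world$chemicals$compound_id == cid, ]
    got <- summed_signal(stats::setNames(sub$area, sub$ion_label),
                         meta$formula)
    molar <- truth$conc_ng_g[i] * 0.5 / (meta$mw * 1e9 * 2.5e-4)
    expect_equal(got, 10^cal$true_log_rf[[cid]] * molar, tolerance = 1e-9)
  }
})

test_that("EOF construction reproduces the requested unexplained fraction", {
  budgets <- data.frame(sample_id = c("A", "B"), sum_targets = c(100, 40),
                        sum_suspects = c(50, 0),
                        unexplained_fraction = c(0, 0.3))
  eof <- simulate_eof(budgets, sigma = 0, blank_mean = 5, blank_sd = 0,
                      seed = 3)
  bc <- blank_correct_and_loq(eof$samples$measured, eof$blanks)
  for (i in 1:2) {
    b <- compute_ueof(budgets$sample_id[i], bc$corrected$value[i],
                      budgets$sum_targets[i], budgets$sum_suspects[i])
    expect_equal(b$ueof_fraction, budgets$unexplained_fraction[i],
                 tolerance = 1e-12)
  }
})

test_that("recovered UEOF is unbiased across noisy replicates", {
  u_true <- 0.25
  est <- vapply(1:200, function(r) {
    budgets <- data.frame(sample_id = "A", sum_targets = 300,
                          sum_suspects = 300, unexplained_fraction = u_true)
    eof <- simulate_eof(budgets, sigma = 30, blank_mean = 5, blank_sd = 0.5,
                        seed = 5000 + r)
    bc <- blank_correct_and_loq(eof$samples$measured, eof$blanks)
    compute_ueof("A", bc$corrected$value[1], 300, 300)$ueof_fraction
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - u_true), 2 * se + 0.005)
})
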