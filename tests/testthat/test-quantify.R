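test_that("bridge recovers an exact log-log line", {
  # constructed from the anchor pair: log RF = log IE + 8.97
  log_ie <- c(0.5, 1.2, 2.59, 3.1)
  b <- fit_ie_rf_bridge(log_ie, log_ie + 8.97)
  expect_equal(b$slope, 1, tolerance = 1e-9)
  expect_equal(b$intercept, 8.97, tolerance = 1e-9)
  expect_equal(b$residual_sd, 0, tolerance = 1e-7)
  expect_equal(rf_from_ie(b, 2.59), 11.56, tolerance = 1e-9)
  expect_error(fit_ie_rf_bridge(c(1, 1, 1), c(2, 3, 4)), "zero variance")
  expect_error(fit_ie_rf_bridge(c(1, 2), c(2, 3)), ">= 3")
})

test_that("bridge is affine-equivariant and supports a fixed slope", {
  set.seed(6)
  ie <- rnorm(10, 2, 1)
  rf <- 0.9 * ie + 9 + rnorm(10, 0, 0.1)
  b1 <- fit_ie_rf_bridge(ie, rf)
  b2 <- fit_ie_rf_bridge(ie, rf + 2)
  expect_equal(b2$slope, b1$slope, tolerance = 1e-12)
  expect_equal(b2$intercept, b1$intercept + 2, tolerance = 1e-12)
  bf <- fit_ie_rf_bridge(ie, rf, fixed_slope = TRUE)
  expect_equal(bf$slope, 1)
  expect_equal(bf$intercept, mean(rf - ie), tolerance = 1e-12)
})

test_that("concentration round-trips through the response factor", {
  mw <- molecular_weight("C8HF17O3S")
  expect_equal(concentration_from_rf(0, 11.56, mw), 0)
  # inverse-function oracle: conc -> area -> conc
  conc <- 123.4
  molar <- conc * 0.5 / (mw * 1e9 * 2.5e-4)
  area <- molar * 10^11.56
  expect_equal(concentration_from_rf(area, 11.56, mw), conc,
               tolerance = 1e-9)
  # linear in area
  expect_equal(concentration_from_rf(2 * area, 11.56, mw), 2 * conc,
               tolerance = 1e-9)
  expect_error(concentration_from_rf(10, NA, mw), "is.finite")
})

test_that("model quantification recovers calibrant concentrations exactly
           on a noiseless world", {
  sim <- simulate_ie_world(n_chemicals = 20, n_conditions = 2, noise_sd = 0,
                           seed = 31)
  w <- sim$world
  cal <- simulate_calibration(w, area_noise_cv = 0, seed = 31)
  cond <- cal$condition
  # perfectly fitted bridge from true IE/RF pairs
  ef <- eluent_features(cond)
  true_ie <- vapply(w$chemicals$compound_id, function(cid) {
    w$oracle$fun(c(molecular_features(cid, w$provider), ef))
  }, numeric(1))
  bridge <- fit_ie_rf_bridge(true_ie, cal$true_log_rf)
  cid <- w$chemicals$compound_id[4]
  mw <- w$chemicals$mw[4]
  conc_true <- 57.3
  molar <- conc_true * 0.5 / (mw * 1e9 * 2.5e-4)
  area <- 10^cal$true_log_rf[[cid]] * molar
  hit <- suspect_hit("s1", "S1", cid, area)
  q <- quantify_suspect_model(hit, w$oracle, bridge, cond, w$provider, mw)
  expect_equal(q$concentration, conc_true, tolerance = 1e-9)
  expect_equal(q$method, "model")
  # concentration fold error equals RF fold error under a shifted RF
  off_bridge <- bridge; off_bridge$intercept <- bridge$intercept + 0.2
  q2 <- quantify_suspect_model(hit, w$oracle, off_bridge, cond, w$provider, mw)
  expect_equal(fold_error(q2$concentration, conc_true), 10^0.2,
               tolerance = 1e-9)
})

test_that("structure-free suspects cannot be model-quantified", {
  hit <- suspect_hit("unknown_class", "S1", NA_character_, 1000)
  expect_error(
    quantify_suspect_model(hit, NULL, NULL,
                           eluent_condition(50, 7, 6, 0.5, 30, TRUE),
                           provider_atom_counts(), 500),
    "requires a structure")
})

test_that("homologue quantification averages concentrations, not RFs", {
  reg <- target_registry()
  mw <- molecular_weight("C8HF15O2")
  rf <- c(PFHpA = 11.2, PFNA = 11.8)
  hit <- suspect_hit("pfoa_like", "S1", NA_character_, area = 5e6)
  q <- quantify_suspect_homologue(hit, "PFOA", reg, rf, mw = mw)
  oracle <- mean(c(concentration_from_rf(5e6, 11.2, mw),
                   concentration_from_rf(5e6, 11.8, mw)))
  expect_equal(q$concentration, oracle, tolerance = 1e-12)
  expect_setequal(q$provenance$homologues, c("PFHpA", "PFNA"))
  expect_false(q$provenance$one_sided)
  # one-sided when only the smaller neighbour has a measured RF
  q1 <- quantify_suspect_homologue(hit, "PFOA", reg, rf["PFHpA"], mw = mw)
  expect_equal(q1$concentration, concentration_from_rf(5e6, 11.2, mw))
  expect_true(q1$provenance$one_sided)
  # identical neighbour RFs degenerate to either alone
  q2 <- quantify_suspect_homologue(hit, "PFOA", reg,
                                   c(PFHpA = 11.5, PFNA = 11.5), mw = mw)
  expect_equal(q2$concentration, concentration_from_rf(5e6, 11.5, mw))
  expect_error(
    quantify_suspect_homologue(hit, "ADONA", reg, rf, mw = mw),
    "model-only")
})

test_that("isomer sensitivity reports the concentration spread", {
  sim <- simulate_ie_world(n_chemicals = 12, n_conditions = 1, noise_sd = 0,
                           seed = 77)
  w <- sim$world
  cond <- w$conditions[[1]]
  bridge <- structure(list(slope = 1, intercept = 8.97, n_calibrants = 33,
                           residual_sd = 0), class = "ie_rf_bridge")
  ids <- w$chemicals$compound_id
  # duplicated candidate: ratio exactly 1
  s_dup <- isomer_sensitivity(c(ids[1], ids[1]), 1e5, w$oracle, bridge, cond,
                              w$provider, mw = 400)
  expect_equal(s_dup$ratio, 1, tolerance = 1e-12)
  expect_true(s_dup$within_order_of_magnitude)
  # an IE gap of d log-units gives a concentration ratio of 10^d
  ef <- eluent_features(cond)
  ie <- vapply(ids, function(cid) {
    w$oracle$fun(c(molecular_features(cid, w$provider), ef))
  }, numeric(1))
  pick <- c(which.min(ie), which.max(ie))
  gap <- diff(range(ie))
  s <- isomer_sensitivity(ids[pick], 1e5, w$oracle, bridge, cond,
                          w$provider, mw = 400)
  expect_equal(s$ratio, 10^gap, tolerance = 1e-9)
  expect_equal(s$within_order_of_magnitude, gap <= 1)
  expect_error(isomer_sensitivity(ids[1], 1e5, w$oracle, bridge, cond,
                                  w$provider, mw = 400), ">= 2")
})
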