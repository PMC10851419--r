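sim <- simulate_ie_world(n_chemicals = 40, n_conditions = 3, noise_sd = 0.1,
                         seed = 101)
pfas_ids <- sim$world$chemicals$compound_id[
  sim$world$chemicals$class == "pfas_like"]
cfg <- training_config(seed = 101)

test_that("stratified split works at the chemical level and is reproducible", {
  sp <- stratified_group_split(sim$data, cfg, pfas_ids)
  expect_length(intersect(sp$train_chemicals, sp$test_chemicals), 0)
  expect_setequal(c(sp$train_chemicals, sp$test_chemicals),
                  sim$data$chemicals)
  # every measurement of a chemical on one side
  expect_true(all(sp$train$measurements$compound_id %in% sp$train_chemicals))
  expect_equal(sum(pfas_ids %in% sp$train_chemicals),
               round(0.8 * length(pfas_ids)))
  sp2 <- stratified_group_split(sim$data, cfg, pfas_ids)
  expect_identical(sp$train_chemicals, sp2$train_chemicals)
  expect_error(stratified_group_split(sim$data, cfg, "nope"), "subset")
})

test_that("a 33-chemical PFAS stratum splits 26/7 at 80%", {
  ids <- sprintf("p%02d", 1:33)
  other <- sprintf("o%02d", 1:10)
  ds <- ie_dataset(meas_rows(c(ids, other), rnorm(43)))
  sp <- stratified_group_split(ds, training_config(seed = 2), ids)
  expect_equal(sum(ids %in% sp$train_chemicals), 26L)
  expect_equal(sum(ids %in% sp$test_chemicals), 7L)
})

test_that("grouped CV folds partition chemicals with balanced sizes", {
  folds <- grouped_cv_folds(sim$data, k = 5, seed = 3)
  expect_length(folds, 5)
  expect_setequal(unlist(folds), sim$data$chemicals)
  expect_equal(sum(lengths(folds)), length(sim$data$chemicals))
  expect_lte(diff(range(lengths(folds))), 1)
  # replicate-grouping: all rows of a chemical in exactly one fold
  for (f in folds) {
    rows <- sim$data$measurements$compound_id %in% f
    expect_true(all(!sim$data$measurements$compound_id[!rows] %in% f))
  }
  expect_error(grouped_cv_folds(sim$data, k = 1000), "exceeds")
})

test_that("training is deterministic and has capacity for constant targets", {
  small_grid <- data.frame(eta = 0.1, max_depth = 2L, nrounds = 50L,
                           subsample = 1, colsample_bytree = 1,
                           min_child_weight = 1)
  c2 <- training_config(seed = 5, cv_groups = 3,
                        hyperparameter_grid = small_grid)
  x <- build_feature_matrix(sim$data, sim$world$provider)
  m1 <- tune_and_train(sim$data, x, c2)
  m2 <- tune_and_train(sim$data, x, c2)
  expect_identical(predict_log_ie(m1, x), predict_log_ie(m2, x))
  # constant target -> constant predictions
  dsc <- sim$data
  dsc$measurements$log_ie <- 1.7
  mc <- tune_and_train(dsc, x, c2)
  expect_equal(predict_log_ie(mc, x), rep(1.7, nrow(x)), tolerance = 1e-3)
})

test_that("prediction aligns features by name and rejects mismatches", {
  small_grid <- data.frame(eta = 0.1, max_depth = 2L, nrounds = 30L,
                           subsample = 1, colsample_bytree = 1,
                           min_child_weight = 1)
  x <- build_feature_matrix(sim$data, sim$world$provider)
  m <- tune_and_train(sim$data, x,
                      training_config(seed = 1, cv_groups = 3,
                                      hyperparameter_grid = small_grid))
  v <- x[1, ]
  perm <- sample(seq_along(v))
  expect_equal(predict_log_ie(m, v[perm]), predict_log_ie(m, v))
  expect_error(predict_log_ie(m, v[-1]), "missing")
  expect_error(predict_log_ie(m, c(v, extra = 1)), "extra")
})

test_that("leave-one-out excludes the target chemical and trains per target", {
  x <- build_feature_matrix(sim$data, sim$world$provider)
  targets <- sim$data$chemicals[1:3]
  res <- leave_one_out_eval(sim$data, x, targets, cfg)
  expect_setequal(unique(res$compound_id), targets)
  n_cond <- 3
  expect_equal(nrow(res), length(targets) * n_cond)
  expect_true(all(res$fold_error >= 1))
  expect_error(leave_one_out_eval(sim$data, x, "absent", cfg),
               "no measurements")
})

test_that("fold error is symmetric, scale-invariant and 1 iff equal", {
  expect_equal(fold_error(5, 5), 1.0)
  expect_equal(fold_error(10, 1), 10.0)
  expect_equal(fold_error(1, 10), 10.0)
  expect_equal(fold_error(10^0.3, 1), 1.995, tolerance = 1e-3)
  expect_error(fold_error(-1, 2), "positive")
  set.seed(13)
  a <- 10^runif(200, -3, 3); b <- 10^runif(200, -3, 3); k <- 10^runif(200, -2, 2)
  expect_equal(fold_error(a, b), fold_error(b, a))
  expect_equal(fold_error(k * a, k * b), fold_error(a, b), tolerance = 1e-9)
  expect_true(all(fold_error(a, b) >= 1))
})

test_that("error summary matches hand-computed arithmetic", {
  s0 <- error_summary(c(1, 2, 3), c(1, 2, 3))
  expect_equal(s0$rmse, 0)
  expect_equal(s0$mean_fold, 1)
  s1 <- error_summary(0, 1)   # one pair off by 10x
  expect_equal(s1$rmse, 1)
  expect_equal(s1$median_fold, 10)
  obs <- c(1.0, 2.0, 0.5, 3.0, 1.5)
  pred <- c(1.2, 1.7, 0.9, 3.0, 1.0)
  s <- error_summary(obs, pred)
  r <- pred - obs
  folds <- 10^abs(r)
  expect_equal(s$rmse, sqrt(mean(r^2)), tolerance = 1e-12)
  expect_equal(s$mean_fold, mean(folds), tolerance = 1e-12)
  expect_equal(s$geometric_mean_fold, exp(mean(log(folds))),
               tolerance = 1e-12)
  expect_equal(s$median_fold, median(folds), tolerance = 1e-12)
  expect_lte(s$geometric_mean_fold, s$mean_fold)   # AM-GM
  expect_error(error_summary(numeric(0), numeric(0)), "empty")
})

test_that("paired Wilcoxon behaves at the edge cases", {
  x <- c(1.1, 1.3, 2.0, 1.7, 2.4, 1.2, 3.0)
  expect_equal(paired_error_test(x, x), 1)
  p <- paired_error_test(x, x * 10)
  expect_lt(p, 0.05)
  expect_equal(paired_error_test(x, x * 10),
               paired_error_test(x * 10, x))
  expect_error(paired_error_test(x, x[-1]), "equal length")
})

test_that("a class present in training is predicted better than when absent", {
  # congener augmentation: with half the PFAS-like class in training, the
  # class's held-out members are predicted better than by a model that
  # never saw the class
  world <- simulate_ie_world(n_chemicals = 60, n_conditions = 3,
                             noise_sd = 0.15, seed = 202)
  cls <- world$world$chemicals$class
  ids <- world$world$chemicals$compound_id
  pf <- ids[cls == "pfas_like"]
  eval_ids <- pf[1:6]
  keep_in <- setdiff(ids, eval_ids)
  keep_out <- setdiff(ids, pf)
  grid1 <- data.frame(eta = 0.1, max_depth = 2L, nrounds = 300L,
                      subsample = 0.8, colsample_bytree = 0.8,
                      min_child_weight = 5)
  cfg2 <- training_config(seed = 202, cv_groups = 2,
                          hyperparameter_grid = grid1)
  sub <- function(ids_keep) {
    ie_dataset(world$data$measurements[
      world$data$measurements$compound_id %in% ids_keep, ])
  }
  fitrmse <- function(train_ids) {
    tr <- sub(train_ids)
    m <- tune_and_train(tr, build_feature_matrix(tr, world$world$provider),
                        cfg2)
    ev <- sub(eval_ids)
    pr <- predict_log_ie(m, build_feature_matrix(ev, world$world$provider))
    sqrt(mean((pr - ev$measurements$log_ie)^2))
  }
  expect_lt(fitrmse(keep_in), fitrmse(keep_out))
})
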