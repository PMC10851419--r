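# Gradient-boosted log IE regression with chemical-grouped resampling.
# Chemicals appear under several eluent conditions, so every split and every
# cross-validation fold is made at the chemical level: all measurements of
# one chemical stay on one side, otherwise the model would be evaluated on
# chemicals it has memorized.

#' Training configuration for the IE model
#'
#' @param test_fraction Fraction of chemicals held out for testing
#'   (default 0.2).
#' @param cv_groups Number of grouped cross-validation sets (default 5).
#' @param tuning_resamples Number of repeated grouped-CV passes during
#'   hyperparameter tuning (default 1).
#' @param hyperparameter_grid Data.frame of candidate settings with columns
#'   `eta`, `max_depth`, `nrounds`, `subsample`, `colsample_bytree`,
#'   `min_child_weight`. Defaults to a small fast grid.
#' @param seed Integer seed controlling every random choice.
#' @return An object of class `training_config`.
#' @export
training_config <- function(test_fraction = 0.2, cv_groups = 5,
                            tuning_resamples = 1,
                            hyperparameter_grid = default_hyperparameter_grid(),
                            seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1, cv_groups >= 2,
            tuning_resamples >= 1)
  if (!is.data.frame(hyperparameter_grid) || nrow(hyperparameter_grid) == 0) {
    stop("hyperparameter grid must be a nonempty data.frame")
  }
  structure(list(test_fraction = test_fraction, cv_groups = cv_groups,
                 tuning_resamples = tuning_resamples,
                 hyperparameter_grid = hyperparameter_grid,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Default hyperparameter grid
#'
#' @return Data.frame of candidate gradient-boosting settings.
#' @export
default_hyperparameter_grid <- function() {
  expand.grid(eta = 0.05, max_depth = c(1L, 2L, 3L), nrounds = 1200L,
              subsample = 0.8, colsample_bytree = 0.8, min_child_weight = 5,
              KEEP.OUT.ATTRS = FALSE)
}

#' Stratified chemical-level train/test split
#'
#' Splits chemicals (never individual measurements) into train and test so
#' that approximately `1 - test_fraction` of all chemicals land in train,
#' with the PFAS stratum satisfied first: `round((1 - test_fraction) *
#' n_pfas)` PFAS chemicals go to train, then non-PFAS chemicals fill the
#' remaining train slots.
#'
#' @param data An `ie_dataset`.
#' @param config A `training_config`.
#' @param pfas_ids Character vector of chemical ids forming the PFAS stratum
#'   (subset of the dataset's chemicals).
#' @return List with `train` and `test` `ie_dataset`s and the chemical id
#'   vectors `train_chemicals`, `test_chemicals`.
#' @export
stratified_group_split <- function(data, config, pfas_ids) {
  stopifnot(inherits(data, "ie_dataset"), inherits(config, "training_config"))
  if (!all(pfas_ids %in% data$chemicals)) {
    stop("pfas_ids must be a subset of the dataset's chemicals")
  }
  if (length(pfas_ids) < 2) stop("need at least 2 PFAS chemicals to stratify")
  other_ids <- setdiff(data$chemicals, pfas_ids)
  train_frac <- 1 - config$test_fraction
  n_train_total <- round(train_frac * length(data$chemicals))
  n_train_pfas <- round(train_frac * length(pfas_ids))
  n_train_other <- max(0L, min(length(other_ids),
                               n_train_total - n_train_pfas))
  rng <- local_rng(config$seed)
  train_pfas <- rng_sample(rng, pfas_ids, n_train_pfas)
  train_other <- rng_sample(rng, other_ids, n_train_other)
  train_chem <- c(train_pfas, train_other)
  test_chem <- setdiff(data$chemicals, train_chem)
  subset_ds <- function(ids) {
    ie_dataset(data$measurements[data$measurements$compound_id %in% ids, ,
                                 drop = FALSE])
  }
  list(train = subset_ds(train_chem), test = subset_ds(test_chem),
       train_chemicals = train_chem, test_chemicals = test_chem)
}

#' Grouped cross-validation folds
#'
#' Partitions the chemicals of a dataset into `k` folds of near-equal size
#' (differing by at most one chemical); every measurement of a chemical
#' falls in exactly one fold.
#'
#' @param data An `ie_dataset`.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List of `k` character vectors of chemical ids.
#' @export
grouped_cv_folds <- function(data, k = 5, seed = 1L) {
  stopifnot(inherits(data, "ie_dataset"))
  chems <- data$chemicals
  if (k > length(chems)) stop("k exceeds the number of chemicals")
  rng <- local_rng(seed)
  shuffled <- rng_sample(rng, chems, length(chems))
  split(shuffled, rep_len(seq_len(k), length(shuffled)))
}

# Align a feature matrix with dataset rows and run one xgboost fit.
fit_booster <- function(x, y, params, nrounds, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  xgboost::xgb.train(
    params = c(params, list(objective = "reg:squarederror", nthread = 1,
                            seed = as.integer(seed))),
    data = dtrain, nrounds = nrounds, verbose = 0)
}

#' Tune and train the log IE model
#'
#' Grid search over `config$hyperparameter_grid`, scored by mean grouped-CV
#' RMSE over `config$cv_groups` folds (repeated `config$tuning_resamples`
#' times with distinct fold seeds); the best setting is refit on all
#' provided rows. Fully reproducible given `config$seed`.
#'
#' @param data An `ie_dataset` (the training portion).
#' @param features Numeric matrix of cleaned features, one row per
#'   measurement row of `data`, with column names.
#' @param config A `training_config`.
#' @return An object of class `ie_model`: the boosted ensemble plus
#'   `feature_names`, `training_chemicals`, `config`, `best_params`,
#'   `cv_rmse` and a version stamp.
#' @export
tune_and_train <- function(data, features, config) {
  stopifnot(inherits(data, "ie_dataset"), inherits(config, "training_config"))
  features <- as.matrix(features)
  if (nrow(features) != nrow(data$measurements)) {
    stop("feature matrix rows must align with dataset measurements")
  }
  if (any(!is.finite(features))) stop("non-finite feature values")
  grid <- config$hyperparameter_grid
  y <- data$measurements$log_ie
  ids <- data$measurements$compound_id
  cv_rmse <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    errs <- c()
    for (r in seq_len(config$tuning_resamples)) {
      folds <- grouped_cv_folds(data, config$cv_groups,
                                seed = config$seed + 1000L * r)
      for (fold in folds) {
        hold <- ids %in% fold
        if (!any(hold) || all(hold)) next
        m <- fit_booster(features[!hold, , drop = FALSE], y[!hold],
                         as.list(grid[g, setdiff(names(grid), "nrounds")]),
                         grid$nrounds[g], config$seed)
        pred <- predict(m, features[hold, , drop = FALSE])
        errs <- c(errs, (pred - y[hold])^2)
      }
    }
    cv_rmse[g] <- sqrt(mean(errs))
  }
  best <- which.min(cv_rmse)
  final <- fit_booster(features, y,
                       as.list(grid[best, setdiff(names(grid), "nrounds")]),
                       grid$nrounds[best], config$seed)
  structure(list(booster = final, feature_names = colnames(features),
                 training_chemicals = unique(ids), config = config,
                 best_params = grid[best, , drop = FALSE],
                 cv_rmse = stats::setNames(cv_rmse, seq_len(nrow(grid))),
                 version = tryCatch(
                   as.character(utils::packageVersion("iequant")),
                   error = function(e) "dev")),
            class = "ie_model")
}

#' @export
print.ie_model <- function(x, ...) {
  cat("<ie_model> ", length(x$training_chemicals), " chemicals, ",
      length(x$feature_names), " features, CV RMSE ",
      signif(min(x$cv_rmse), 3), " log IE units\n", sep = "")
  invisible(x)
}

#' Predict log IE
#'
#' @param model An `ie_model` (or an `ie_oracle` from a synthetic world).
#' @param x Named numeric vector, or matrix/data.frame with named columns.
#'   Must carry exactly the model's feature names; order is aligned by name.
#' @return Numeric vector of predicted log10 IE values.
#' @export
predict_log_ie <- function(model, x) UseMethod("predict_log_ie")

align_features <- function(x, feature_names) {
  if (is.numeric(x) && !is.matrix(x)) x <- t(as.matrix(x))
  x <- as.matrix(x)
  missing <- setdiff(feature_names, colnames(x))
  extra <- setdiff(colnames(x), feature_names)
  if (length(missing) || length(extra)) {
    stop("feature mismatch; missing: [",
         paste(missing, collapse = ", "), "], extra: [",
         paste(extra, collapse = ", "), "]")
  }
  x[, feature_names, drop = FALSE]
}

#' @export
predict_log_ie.ie_model <- function(model, x) {
  x <- align_features(x, model$feature_names)
  unname(predict(model$booster, x))
}

#' Evaluate prediction for chemicals by leaving each out of training
#'
#' For every target chemical, a model is trained on all measurements except
#' that chemical's own rows and then predicts them, giving paired
#' predicted/observed values for a chemical the model has never seen. One
#' model is trained per target. Hyperparameters are fixed (no per-model
#' retuning): `params` defaults to the first grid row of `config`.
#'
#' @param data An `ie_dataset`.
#' @param features Feature matrix aligned with `data` rows.
#' @param targets Chemical ids to evaluate (subset of the dataset's
#'   chemicals, each with at least one row).
#' @param config A `training_config`.
#' @param params Optional single-row data.frame of hyperparameters (e.g. the
#'   `best_params` of a tuned model).
#' @return Data.frame `compound_id`, `observed_log_ie`, `predicted_log_ie`,
#'   `fold_error` with one row per measurement of each target.
#' @export
leave_one_out_eval <- function(data, features, targets, config,
                               params = NULL) {
  stopifnot(inherits(data, "ie_dataset"))
  features <- as.matrix(features)
  if (is.null(params)) params <- config$hyperparameter_grid[1, , drop = FALSE]
  ids <- data$measurements$compound_id
  y <- data$measurements$log_ie
  out <- list()
  for (tg in targets) {
    hold <- ids == tg
    if (!any(hold)) stop("target has no measurements: ", tg)
    m <- fit_booster(features[!hold, , drop = FALSE], y[!hold],
                     as.list(params[, setdiff(names(params), "nrounds")]),
                     params$nrounds[1], config$seed)
    pred <- predict(m, features[hold, , drop = FALSE])
    out[[tg]] <- data.frame(compound_id = tg, observed_log_ie = y[hold],
                            predicted_log_ie = pred,
                            fold_error = 10^abs(pred - y[hold]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fold prediction error
#'
#' `max(predicted/observed, observed/predicted)` for positive linear-scale
#' quantities: symmetric, scale-invariant, and 1 iff the two agree.
#'
#' @param predicted,observed Positive numeric vectors.
#' @return Fold error(s) `>= 1`.
#' @export
fold_error <- function(predicted, observed) {
  if (any(predicted <= 0) || any(observed <= 0)) {
    stop("fold error requires positive quantities")
  }
  pmax(predicted / observed, observed / predicted)
}

#' Summary of prediction errors
#'
#' RMSE over log10 residuals plus the mean, geometric mean and median of the
#' linear-scale fold errors.
#'
#' @param observed_log,predicted_log Paired log10 values (e.g. log IE).
#' @return An object of class `error_summary`: list with `rmse`,
#'   `mean_fold`, `geometric_mean_fold`, `median_fold`, `n`.
#' @export
error_summary <- function(observed_log, predicted_log) {
  stopifnot(length(observed_log) == length(predicted_log))
  if (!length(observed_log)) stop("empty input")
  resid <- predicted_log - observed_log
  folds <- 10^abs(resid)
  structure(list(rmse = sqrt(mean(resid^2)), mean_fold = mean(folds),
                 geometric_mean_fold = exp(mean(log(folds))),
                 median_fold = stats::median(folds), n = length(folds)),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat("<error_summary> n = ", x$n, ", RMSE = ", signif(x$rmse, 3),
      " log units; fold errors mean ", signif(x$mean_fold, 3),
      "x, geometric mean ", signif(x$geometric_mean_fold, 3),
      "x, median ", signif(x$median_fold, 3), "x\n", sep = "")
  invisible(x)
}

#' Paired comparison of two error vectors
#'
#' Two-sided paired Wilcoxon signed-rank test on fold errors from two
#' quantification approaches, paired by compound. Fold-error distributions
#' are asymmetric and non-normal, which motivates the rank test. Zero
#' differences are dropped; when every difference is zero there is no
#' signal and `p = 1` is returned.
#'
#' @param errors_a,errors_b Equal-length (`>= 5`) paired fold-error vectors.
#' @return Two-sided p-value.
#' @export
paired_error_test <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b)) {
    stop("paired error vectors must have equal length")
  }
  stopifnot(length(errors_a) >= 5)
  if (all(errors_a == errors_b)) return(1)
  suppressWarnings(
    stats::wilcox.test(errors_a, errors_b, paired = TRUE,
                       alternative = "two.sided")$p.value)
}

#' Build the feature matrix for an IE dataset
#'
#' Joins per-chemical molecular descriptors (from the provider, keyed by the
#' dataset's `smiles` column when present, else by `compound_id`) with the
#' per-row eluent descriptors.
#'
#' @param data An `ie_dataset`.
#' @param provider A `descriptor_provider`.
#' @return Numeric matrix, one row per measurement.
#' @export
build_feature_matrix <- function(data, provider) {
  stopifnot(inherits(data, "ie_dataset"))
  m <- data$measurements
  key <- if ("smiles" %in% names(m) && !anyNA(m$smiles)) m$smiles
         else m$compound_id
  uniq <- unique(key)
  desc <- lapply(uniq, function(k) molecular_features(k, provider))
  names(desc) <- uniq
  elu_cols <- c("aqueous_pH", "polarity_index", "viscosity",
                "surface_tension", "nh4_present", "organic_modifier_pct")
  out <- t(vapply(seq_len(nrow(m)), function(i) {
    c(desc[[key[i]]],
      stats::setNames(as.numeric(m[i, elu_cols]), elu_cols))
  }, numeric(length(desc[[1]]) + length(elu_cols))))
  rownames(out) <- NULL
  out
}
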