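# Orchestration of the full workflow in the order the method prescribes:
# calibrate -> anchor -> train -> bridge -> quantify -> mass balance.
# Stages are individually invokable through the exported functions; the
# runner only sequences them, records bookkeeping counts, and fails with
# the stage name and cause.

#' Assemble a pipeline run configuration
#'
#' @param registry `compound_registry` of target (calibrant) compounds.
#' @param calibration Named list (by registry id) of calibration data.frames
#'   with `concentration` (mol/L) and corrected `area` — e.g. the output of
#'   [read_calibration()] or [simulate_calibration()]`$series`.
#' @param anchor_id Registry id of the anchor compound shared with the
#'   reference IE dataset.
#' @param anchor_log_ie Reference log10 IE of the anchor compound.
#' @param condition `eluent_condition` of the calibration/sample sequence.
#' @param provider `descriptor_provider` resolving every structure that will
#'   be predicted (calibrants and suspects).
#' @param suspects Data.frame `sample_id`, `suspect_id`, `smiles`
#'   (`;`-separated candidates, first = representative), `area`, `formula`,
#'   and optionally `confidence_level`, `rt_min`.
#' @param target_peaks Optional data.frame `sample_id`, `compound_id`,
#'   `area` of target compounds detected in samples (quantified with their
#'   own calibration RFs).
#' @param eof_samples Optional data.frame `sample_id`, `measured` raw
#'   fluoride measurements (ng F/g, blank included).
#' @param eof_blanks Numeric vector of `>= 3` procedural blanks (required
#'   with `eof_samples`).
#' @param ie_data Optional reference `ie_dataset` merged with the anchored
#'   calibrant measurements before training.
#' @param predictor `"train"` (fit the gradient-boosted model) or any object
#'   with a [predict_log_ie()] method.
#' @param training `training_config` used when `predictor = "train"`.
#' @param bridge_mode `"free"` (default) or `"fixed"` (slope fixed at 1).
#' @param bridge_linear_only Use only linearity-passing calibrants for the
#'   bridge (default `TRUE`).
#' @param sample_mass_g,extract_volume_l Unit-chain constants.
#' @param outdir Optional directory: stage outputs written as CSV/JSON.
#' @param seed Integer seed recorded in the report and used for training.
#' @return An object of class `run_config`.
#' @export
run_config <- function(registry, calibration, anchor_id, anchor_log_ie,
                       condition, provider, suspects,
                       target_peaks = NULL, eof_samples = NULL,
                       eof_blanks = NULL, ie_data = NULL,
                       predictor = "train", training = training_config(),
                       bridge_mode = c("free", "fixed"),
                       bridge_linear_only = TRUE, sample_mass_g = 0.5,
                       extract_volume_l = 2.5e-4, outdir = NULL, seed = 1L) {
  bridge_mode <- match.arg(bridge_mode)
  stopifnot(inherits(registry, "compound_registry"),
            anchor_id %in% names(calibration),
            anchor_id %in% registry$id,
            inherits(condition, "eluent_condition"),
            inherits(provider, "descriptor_provider"))
  if (!is.null(eof_samples) && (is.null(eof_blanks) || length(eof_blanks) < 3)) {
    stop("eof_samples requires >= 3 eof_blanks")
  }
  structure(list(registry = registry, calibration = calibration,
                 anchor_id = anchor_id, anchor_log_ie = anchor_log_ie,
                 condition = condition, provider = provider,
                 suspects = suspects, target_peaks = target_peaks,
                 eof_samples = eof_samples, eof_blanks = eof_blanks,
                 ie_data = ie_data, predictor = predictor,
                 training = training, bridge_mode = bridge_mode,
                 bridge_linear_only = bridge_linear_only,
                 sample_mass_g = sample_mass_g,
                 extract_volume_l = extract_volume_l, outdir = outdir,
                 seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the quantification pipeline
#'
#' Executes, in order: (1) calibration — per-compound weighted RF fits with
#' the linearity rule; (2) anchoring — calibrant RFs translated onto the
#' relative log IE scale through the anchor compound; (3) model — either a
#' gradient-boosted IE model trained on the merged dataset or a supplied
#' predictor; (4) bridge — predicted log IE vs measured log RF over
#' calibrants; (5) quantification — model-based concentrations for all
#' suspects (plus homologue-based where a same-class neighbour carries a
#' measured RF), and target concentrations from their own RFs; (6) fluorine
#' mass balance with and without the suspect contribution.
#'
#' @param config A `run_config`.
#' @return A `run_report` list: per-stage outputs, bookkeeping counts, and
#'   the seed.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  reg <- config$registry

  ## 1. calibrate ----------------------------------------------------------
  fits <- stage("calibrate", {
    lapply(config$calibration, function(s) {
      fit_response_factor(s$concentration, s$area)
    })
  })
  rf_table <- vapply(fits, function(f) log10(f$response_factor), numeric(1))
  linear <- vapply(fits, function(f) f$linear, logical(1))

  ## 2. anchor -------------------------------------------------------------
  anchored <- stage("anchor", {
    log_rf_anchor <- rf_table[[config$anchor_id]]
    data.frame(compound_id = names(rf_table),
               smiles = reg$smiles[match(names(rf_table), reg$id)],
               log_ie = vapply(rf_table, anchor_rf_to_ie, numeric(1),
                               log_rf_anchor = log_rf_anchor,
                               log_ie_anchor = config$anchor_log_ie),
               as.data.frame(as.list(eluent_features(config$condition))),
               source = "calibrants", stringsAsFactors = FALSE,
               row.names = NULL)
  })

  ## 3. model --------------------------------------------------------------
  model_info <- list(kind = "supplied")
  model <- config$predictor
  feature_cols <- NULL
  if (identical(config$predictor, "train")) {
    model <- stage("train", {
      cal_ds <- ie_dataset(anchored)
      full <- if (is.null(config$ie_data)) cal_ds
              else merge_ie_datasets(config$ie_data, cal_ds)
      x <- build_feature_matrix(full, config$provider)
      cleaned <- clean_feature_matrix(x)
      tune_and_train(full, cleaned$matrix, config$training)
    })
    feature_cols <- model$feature_names
    model_info <- list(kind = "trained",
                       cv_rmse = unname(min(model$cv_rmse)),
                       n_chemicals = length(model$training_chemicals))
  }

  ## 4. bridge -------------------------------------------------------------
  bridge_ids <- if (config$bridge_linear_only) names(rf_table)[linear]
                else names(rf_table)
  bridge <- stage("bridge", {
    pred <- vapply(bridge_ids, function(cid) {
      smi <- reg$smiles[match(cid, reg$id)]
      key <- if (is.na(smi) || !nzchar(smi)) cid else smi
      x <- c(molecular_features(key, config$provider),
             eluent_features(config$condition))
      if (!is.null(feature_cols)) x <- x[feature_cols]
      predict_log_ie(model, x)
    }, numeric(1))
    fit_ie_rf_bridge(pred, rf_table[bridge_ids],
                     fixed_slope = config$bridge_mode == "fixed")
  })

  ## 5. quantify -----------------------------------------------------------
  targets_quant <- NULL
  if (!is.null(config$target_peaks)) {
    targets_quant <- stage("quantify_targets", {
      tp <- config$target_peaks
      conc <- vapply(seq_len(nrow(tp)), function(i) {
        cid <- tp$compound_id[i]
        if (!cid %in% names(rf_table)) stop("no RF for target ", cid)
        concentration_from_rf(tp$area[i], rf_table[[cid]],
                              molecular_weight(
                                reg$formula[match(cid, reg$id)]),
                              config$sample_mass_g, config$extract_volume_l)
      }, numeric(1))
      cbind(tp, concentration_ng_g = conc)
    })
  }
  suspects_quant <- stage("quantify_suspects", {
    sp <- config$suspects
    out <- lapply(seq_len(nrow(sp)), function(i) {
      cands <- strsplit(sp$smiles[i], ";", fixed = TRUE)[[1]]
      hit <- suspect_hit(sp$suspect_id[i], sp$sample_id[i], cands,
                         sp$area[i],
                         if ("confidence_level" %in% names(sp))
                           sp$confidence_level[i] else "3")
      mw <- molecular_weight(sp$formula[i])
      q <- quantify_suspect_model(hit, model, bridge, config$condition,
                                  config$provider, mw,
                                  sample_mass_g = config$sample_mass_g,
                                  extract_volume_l = config$extract_volume_l)
      data.frame(sample_id = sp$sample_id[i], suspect_id = sp$suspect_id[i],
                 method = "model", concentration_ng_g = q$concentration,
                 predicted_log_ie = q$provenance$predicted_log_ie,
                 predicted_log_rf = q$provenance$predicted_log_rf,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })

  ## 6. mass balance -------------------------------------------------------
  budgets <- NULL
  loq <- NA_real_
  if (!is.null(config$eof_samples)) {
    budgets <- stage("mass_balance", {
      bc <- blank_correct_and_loq(config$eof_samples$measured,
                                  config$eof_blanks)
      loq <<- bc$loq
      lapply(seq_len(nrow(config$eof_samples)), function(i) {
        sid <- config$eof_samples$sample_id[i]
        sum_t <- if (is.null(targets_quant)) 0 else {
          tq <- targets_quant[targets_quant$sample_id == sid, ]
          if (!nrow(tq)) 0 else sum_fluorine(
            stats::setNames(tq$concentration_ng_g, tq$compound_id), reg)
        }
        sq <- suspects_quant[suspects_quant$sample_id == sid, ]
        sum_s <- if (!nrow(sq)) 0 else sum(vapply(seq_len(nrow(sq)),
          function(j) {
            f <- config$suspects$formula[
              config$suspects$suspect_id == sq$suspect_id[j] &
                config$suspects$sample_id == sid][1]
            fluorine_equivalent(sq$concentration_ng_g[j], f)
          }, numeric(1)))
        below <- bc$corrected$below_loq[i]
        list(with_suspects = compute_ueof(sid, bc$corrected$value[i], sum_t,
                                          sum_s, eof_below_loq = below,
                                          loq = bc$loq),
             targets_only = compute_ueof(sid, bc$corrected$value[i], sum_t,
                                         0, eof_below_loq = below,
                                         loq = bc$loq))
      })
    })
  }

  report <- structure(list(
    rf_table = rf_table, linear = linear, anchored = anchored,
    model = model_info, bridge = bridge, targets = targets_quant,
    suspects = suspects_quant, budgets = budgets, loq = loq,
    counts = list(
      n_calibrants = length(rf_table),
      n_calibrants_linear = sum(linear),
      n_bridge_calibrants = bridge$n_calibrants,
      n_suspects = nrow(suspects_quant),
      n_targets_quantified = if (is.null(targets_quant)) 0L
                             else length(unique(targets_quant$compound_id))),
    seed = config$seed), class = "run_report")

  if (!is.null(config$outdir)) write_run_report(report, config$outdir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> ", x$counts$n_calibrants, " calibrants (",
      x$counts$n_calibrants_linear, " linear), ",
      x$counts$n_suspects, " suspect rows quantified; model: ",
      x$model$kind, "\n", sep = "")
  if (!is.null(x$budgets)) {
    for (b in x$budgets) print(b$with_suspects)
  }
  invisible(x)
}

#' Write the pipeline report to disk
#'
#' @param report A `run_report`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_run_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(compound_id = names(report$rf_table),
                              log_rf = unname(report$rf_table),
                              linear = unname(report$linear)),
                   file.path(outdir, "response_factors.csv"),
                   row.names = FALSE)
  utils::write.csv(report$anchored, file.path(outdir, "anchored_ie.csv"),
                   row.names = FALSE)
  if (!is.null(report$suspects)) {
    utils::write.csv(report$suspects,
                     file.path(outdir, "suspect_quantification.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$targets)) {
    utils::write.csv(report$targets,
                     file.path(outdir, "target_quantification.csv"),
                     row.names = FALSE)
  }
  if (!is.null(report$budgets)) {
    rows <- lapply(report$budgets, function(b) {
      w <- b$with_suspects
      data.frame(sample_id = w$sample_id, eof = w$eof,
                 sum_targets = w$sum_targets, sum_suspects = w$sum_suspects,
                 ueof_fraction = w$ueof_fraction,
                 ueof_fraction_targets_only = b$targets_only$ueof_fraction,
                 eof_below_loq = w$eof_below_loq,
                 overclosure = w$overclosure)
    })
    utils::write.csv(do.call(rbind, rows),
                     file.path(outdir, "fluorine_budget.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(counts = report$counts, seed = report$seed,
         model = report$model,
         bridge = report$bridge[c("slope", "intercept", "n_calibrants",
                                  "residual_sd")]),
    file.path(outdir, "run_report.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
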