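# From predicted log IE to concentration. Predicted IE values are
# instrument-independent; response factors are not. The in-run target
# calibrants provide the linear log IE -> log RF bridge that transfers
# predictions onto the measurement's own response scale, after which
# concentration estimation is ordinary inverse calibration. The homologue
# comparator quantifies with the response factor of a chain-length
# neighbour instead.

#' Fit the IE-to-RF bridge on in-run calibrants
#'
#' Ordinary least squares of measured log10 RF on predicted log10 IE over
#' the target calibrants measured together with the suspects. The residual
#' standard deviation is reported for uncertainty propagation. A
#' fixed-slope-1 mode constrains the map to a pure translation.
#'
#' @param predicted_log_ie,measured_log_rf Paired values for `>= 3`
#'   calibrants.
#' @param fixed_slope If `TRUE`, the slope is fixed at 1 and only the
#'   intercept fitted.
#' @return An object of class `ie_rf_bridge`: list with `slope`,
#'   `intercept`, `n_calibrants`, `residual_sd`.
#' @export
fit_ie_rf_bridge <- function(predicted_log_ie, measured_log_rf,
                             fixed_slope = FALSE) {
  stopifnot(length(predicted_log_ie) == length(measured_log_rf))
  if (length(predicted_log_ie) < 3) stop("bridge needs >= 3 calibrants")
  if (stats::var(predicted_log_ie) == 0) {
    stop("zero variance in predicted log IE: bridge design is degenerate")
  }
  if (fixed_slope) {
    slope <- 1
    intercept <- mean(measured_log_rf - predicted_log_ie)
    resid <- measured_log_rf - (predicted_log_ie + intercept)
    dfree <- length(resid) - 1
  } else {
    fit <- stats::lm(measured_log_rf ~ predicted_log_ie)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    resid <- stats::residuals(fit)
    dfree <- length(resid) - 2
  }
  structure(list(slope = slope, intercept = intercept,
                 n_calibrants = length(resid),
                 residual_sd = sqrt(sum(resid^2) / max(dfree, 1))),
            class = "ie_rf_bridge")
}

#' @export
print.ie_rf_bridge <- function(x, ...) {
  cat("<ie_rf_bridge> log RF = ", signif(x$slope, 4), " * log IE + ",
      signif(x$intercept, 4), " (n = ", x$n_calibrants, ", residual sd ",
      signif(x$residual_sd, 3), ")\n", sep = "")
  invisible(x)
}

#' Predicted log RF from predicted log IE
#'
#' @param bridge An `ie_rf_bridge`.
#' @param log_ie Predicted log10 IE value(s).
#' @return Predicted log10 RF value(s).
#' @export
rf_from_ie <- function(bridge, log_ie) {
  stopifnot(inherits(bridge, "ie_rf_bridge"))
  bridge$slope * log_ie + bridge$intercept
}

#' Concentration from a response factor
#'
#' Inverse calibration: molar concentration in the extract is
#' `area / 10^log_rf` (mol/L), converted to a wet-weight mass concentration
#' with the molecular weight and the sample-preparation constants.
#'
#' @param area Corrected peak area, `>= 0`.
#' @param log_rf log10 response factor (area per mol/L).
#' @param mw Molecular weight, g/mol.
#' @param sample_mass_g Wet sample mass extracted, g.
#' @param extract_volume_l Final extract volume, L.
#' @return Concentration in ng/g wet weight.
#' @export
concentration_from_rf <- function(area, log_rf, mw, sample_mass_g = 0.5,
                                  extract_volume_l = 2.5e-4) {
  stopifnot(area >= 0, is.finite(log_rf), mw > 0, sample_mass_g > 0,
            extract_volume_l > 0)
  molar <- area / 10^log_rf                    # mol/L in extract
  molar * mw * 1e9 * extract_volume_l / sample_mass_g
}

#' A suspect hit
#'
#' @param suspect_id Identifier of the detected feature.
#' @param sample_id Sample it was detected in.
#' @param candidates Character vector of candidate SMILES (or provider
#'   keys); at least one is required for model quantification.
#' @param area Summed, isotope-corrected peak area.
#' @param confidence_level Schymanski-style level (`"1"`,`"2a"`,`"2b"`,
#'   `"3"`,`"4"`,`"5"`).
#' @return An object of class `suspect_hit`.
#' @export
suspect_hit <- function(suspect_id, sample_id, candidates, area,
                        confidence_level = "3") {
  stopifnot(area >= 0)
  structure(list(suspect_id = suspect_id, sample_id = sample_id,
                 candidates = as.character(candidates), area = area,
                 confidence_level = confidence_level),
            class = "suspect_hit")
}

quant_result <- function(concentration, method, provenance) {
  stopifnot(concentration >= 0)
  structure(list(concentration = concentration, method = method,
                 provenance = provenance), class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat("<quant_result> ", signif(x$concentration, 4), " ng/g (", x$method,
      ")\n", sep = "")
  invisible(x)
}

#' Model-based suspect quantification
#'
#' Predicts log IE for the representative candidate structure under the
#' sample's elution condition, converts it to a measurement-specific RF
#' through the bridge, and estimates the concentration. Suspects without a
#' parsable structure (e.g. formula-only classes) cannot be model-quantified
#' and raise an error.
#'
#' @param hit A `suspect_hit` with at least one candidate structure.
#' @param model An object understood by [predict_log_ie()].
#' @param bridge An `ie_rf_bridge`.
#' @param condition The sample's `eluent_condition`.
#' @param provider A `descriptor_provider` for the candidate structures.
#' @param mw Molecular weight of the (representative) candidate, g/mol.
#' @param representative Index of the representative candidate (default 1;
#'   callers order candidates so the representative-structure policy —
#'   linear chain, terminal Cl, ether between first and second carbon —
#'   puts the chosen isomer first).
#' @param sample_mass_g,extract_volume_l Unit-chain constants, see
#'   [concentration_from_rf()].
#' @return A `quant_result` with `method = "model"`; provenance records the
#'   structure used and the predicted log IE / log RF.
#' @export
quantify_suspect_model <- function(hit, model, bridge, condition, provider,
                                   mw, representative = 1,
                                   sample_mass_g = 0.5,
                                   extract_volume_l = 2.5e-4) {
  stopifnot(inherits(hit, "suspect_hit"))
  cands <- hit$candidates[!is.na(hit$candidates) & nzchar(hit$candidates)]
  if (!length(cands)) {
    stop("suspect ", hit$suspect_id,
         " has no parsable candidate structure; model quantification ",
         "requires a structure")
  }
  structure_used <- cands[[min(representative, length(cands))]]
  x <- c(molecular_features(structure_used, provider),
         eluent_features(condition))
  # columns removed by feature cleaning at training time are dropped here
  # too; a genuinely missing feature still errors inside predict_log_ie
  if (!is.null(model$feature_names) &&
      all(model$feature_names %in% names(x))) {
    x <- x[model$feature_names]
  }
  log_ie <- predict_log_ie(model, x)
  log_rf <- rf_from_ie(bridge, log_ie)
  conc <- concentration_from_rf(hit$area, log_rf, mw, sample_mass_g,
                                extract_volume_l)
  quant_result(conc, "model",
               list(structure = structure_used, predicted_log_ie = log_ie,
                    predicted_log_rf = log_rf))
}

#' Homologue-series suspect quantification
#'
#' Quantifies with the measured response factor of the suspect's same-class
#' chain-length neighbour(s): the RF of a structurally similar PFAS is
#' assumed not to differ meaningfully. When both the smaller and the larger
#' homologue carry measured RFs, the suspect is quantified with each and the
#' two concentrations (not the RFs) are averaged.
#'
#' @param hit A `suspect_hit`.
#' @param compound_id Registry id of the suspect (or of the registry entry
#'   representing it).
#' @param registry A `compound_registry`.
#' @param rf_table Named numeric vector of measured log10 RFs by registry id.
#' @param delta `"CF2"` or `"C2F4"`, passed to [find_homologues()].
#' @param mw Molecular weight of the suspect, g/mol.
#' @param sample_mass_g,extract_volume_l Unit-chain constants.
#' @return A `quant_result` with `method = "homologue"`; provenance lists
#'   the homologue ids used and whether the estimate is one-sided.
#' @export
quantify_suspect_homologue <- function(hit, compound_id, registry, rf_table,
                                       delta = "CF2", mw,
                                       sample_mass_g = 0.5,
                                       extract_volume_l = 2.5e-4) {
  stopifnot(inherits(hit, "suspect_hit"))
  h <- find_homologues(compound_id, registry, delta)
  used <- c(h$smaller, h$larger)
  used <- used[used %in% names(rf_table)]
  if (!length(used)) {
    stop("no homologue with a measured RF for ", compound_id,
         ": model-only quantifiable")
  }
  concs <- vapply(used, function(id) {
    concentration_from_rf(hit$area, rf_table[[id]], mw, sample_mass_g,
                          extract_volume_l)
  }, numeric(1))
  quant_result(mean(concs), "homologue",
               list(homologues = used, one_sided = length(used) == 1L))
}

#' Sensitivity of the predicted concentration to the assumed isomer
#'
#' Quantifies every candidate structure of a suspect and summarises the
#' spread. A max/min ratio of at most 10 is flagged as "within one order of
#' magnitude".
#'
#' @param candidates Character vector of `>= 2` candidate structures.
#' @param model,bridge,condition,provider,mw,sample_mass_g,extract_volume_l
#'   As in [quantify_suspect_model()].
#' @param area Corrected peak area.
#' @return List with `concentrations` (named by candidate), `min`, `max`,
#'   `ratio` and `within_order_of_magnitude`.
#' @export
isomer_sensitivity <- function(candidates, area, model, bridge, condition,
                               provider, mw, sample_mass_g = 0.5,
                               extract_volume_l = 2.5e-4) {
  stopifnot(length(candidates) >= 2)
  concs <- vapply(candidates, function(smi) {
    hit <- suspect_hit("isomer", "isomer", smi, area)
    tryCatch(
      quantify_suspect_model(hit, model, bridge, condition, provider, mw,
                             sample_mass_g = sample_mass_g,
                             extract_volume_l = extract_volume_l)$concentration,
      error = function(e) stop("candidate '", smi, "' failed: ",
                               conditionMessage(e)))
  }, numeric(1))
  ratio <- max(concs) / min(concs)
  list(concentrations = concs, min = min(concs), max = max(concs),
       ratio = ratio, within_order_of_magnitude = ratio <= 10)
}
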