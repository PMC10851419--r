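# Per-compound response factors from calibration series: summed ion
# signals, isotope correction, 1/concentration-weighted linear fit, and the
# relative-residual linearity rule.

#' Summed, isotope-corrected signal for one calibration level
#'
#' Adds the peak areas of the deprotonated molecular ion and its in-source
#' fragments (all ions formed through the same ionization mechanism belong
#' to one signal budget), then multiplies by the monoisotopic correction
#' factor of the compound's formula to account for isotopologue peaks not
#' integrated.
#'
#' @param ion_areas Named numeric vector of peak areas (ion label -> area).
#' @param f `molformula` or formula string of the compound.
#' @return Corrected total area.
#' @export
summed_signal <- function(ion_areas, f) {
  if (!length(ion_areas)) stop("empty ion area map")
  stopifnot(is.numeric(ion_areas), all(ion_areas >= 0))
  sum(ion_areas) * monoisotopic_correction_factor(f)
}

#' Fit a response factor from a calibration series
#'
#' Weighted least squares of corrected area on molar concentration with
#' weights 1/concentration and a free intercept. The response factor is the
#' slope. Relative residuals are computed in area space against the observed
#' area, `(fitted - observed) / observed`; levels with zero observed area
#' enter the fit but are excluded from the residual list.
#'
#' @param concentration Molar concentrations (mol/L), `> 0`, at least 3
#'   distinct values.
#' @param area Corrected areas (one per level), `>= 0`.
#' @param linearity_threshold Maximum tolerated absolute relative residual
#'   (default 0.20, inclusive).
#' @return An object of class `calibration_fit`: list with `response_factor`
#'   (area per mol/L), `intercept`, `relative_residuals`, `linear`,
#'   `linearity_threshold`, `n_levels`.
#' @export
fit_response_factor <- function(concentration, area,
                                linearity_threshold = 0.20) {
  stopifnot(length(concentration) == length(area),
            all(concentration > 0), all(area >= 0))
  if (length(unique(concentration)) < 3L) {
    stop("calibration needs >= 3 distinct concentrations")
  }
  fit <- stats::lm(area ~ concentration, weights = 1 / concentration)
  fitted <- stats::fitted(fit)
  nz <- area > 0
  rel <- (fitted[nz] - area[nz]) / area[nz]
  out <- structure(list(
    response_factor = unname(stats::coef(fit)[["concentration"]]),
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    relative_residuals = unname(rel),
    linearity_threshold = linearity_threshold,
    n_levels = length(area)
  ), class = "calibration_fit")
  out$linear <- check_linearity(out, linearity_threshold)
  out
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit> RF = ", signif(x$response_factor, 6),
      ", intercept = ", signif(x$intercept, 4),
      ", linear = ", x$linear, " (max |rel resid| ",
      signif(max(abs(x$relative_residuals)), 3), ")\n", sep = "")
  invisible(x)
}

#' Relative-residual linearity check
#'
#' A calibration is acceptable when the relative residual with the highest
#' absolute value is at most `threshold` (inclusive).
#'
#' @param fit A `calibration_fit`.
#' @param threshold Fraction, default 0.20.
#' @return Logical.
#' @export
check_linearity <- function(fit, threshold = 0.20) {
  stopifnot(inherits(fit, "calibration_fit"))
  max(abs(fit$relative_residuals)) <= threshold
}

#' Read a long-format calibration CSV
#'
#' Columns: `compound_id,level_index,concentration_mol_per_L,ion_label,area`;
#' one ion per row. Areas of all ions at a level are summed and
#' isotope-corrected using the registry formula of the compound.
#'
#' @param path CSV path.
#' @param registry A `compound_registry` supplying formulas.
#' @return Named list (by compound id) of data.frames with `concentration`
#'   and corrected `area` per level.
#' @export
read_calibration <- function(path, registry) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "level_index", "concentration_mol_per_L",
            "ion_label", "area")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("calibration CSV missing column(s): ",
                            paste(missing, collapse = ", "))
  out <- list()
  for (cid in unique(df$compound_id)) {
    i <- match(cid, registry$id)
    if (is.na(i)) stop("calibration compound not in registry: ", cid)
    f <- parse_formula(registry$formula[i])
    sub <- df[df$compound_id == cid, ]
    levels <- sort(unique(sub$level_index))
    out[[cid]] <- data.frame(
      concentration = vapply(levels, function(l) {
        sub$concentration_mol_per_L[sub$level_index == l][1]
      }, numeric(1)),
      area = vapply(levels, function(l) {
        summed_signal(stats::setNames(sub$area[sub$level_index == l],
                                      sub$ion_label[sub$level_index == l]), f)
      }, numeric(1))
    )
  }
  out
}
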