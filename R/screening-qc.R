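# Suspect-evidence checks: retention-time monotonicity along a homologue
# series, chlorine isotopologue abundance, and a Schymanski-style confidence
# level decision table. The narrative identification rules are frozen as an
# explicit, editable table so any deviation is visible and testable.

#' Retention-time monotonicity across a homologue series
#'
#' Members of a homologue series elute in chain-length order on a
#' reversed-phase column; a series whose retention times strictly increase
#' with chain length supports the assignment.
#'
#' @param chain_length Integer chain lengths, strictly increasing.
#' @param rt_min Retention times in minutes, one per member.
#' @return `TRUE` iff retention time strictly increases with chain length.
#' @export
rt_monotonicity <- function(chain_length, rt_min) {
  stopifnot(length(chain_length) == length(rt_min), length(rt_min) >= 2)
  if (any(diff(chain_length) <= 0)) {
    stop("chain lengths must be strictly increasing")
  }
  all(diff(rt_min) > 0)
}

#' Natural 37Cl/35Cl abundance ratio
#'
#' @return The expected area ratio of the 37Cl isotopologue to the 35Cl
#'   peak for a single chlorine (~0.320).
#' @export
natural_cl37_ratio <- function() {
  iso <- .isotope_table[["Cl"]]
  iso$abundance[2] / iso$abundance[1]
}

#' Chlorine isotopologue abundance check
#'
#' Confirms a chlorine substitution by comparing the observed area ratio of
#' the 37Cl isotopologue to the 35Cl peak against the natural abundance
#' ratio (~30%).
#'
#' @param area_35cl Area of the 35Cl (monoisotopic) peak, `> 0`.
#' @param area_37cl Area of the 37Cl isotopologue peak.
#' @param expected_ratio Expected ratio; defaults to [natural_cl37_ratio()].
#' @param tolerance Absolute tolerance on the ratio (default 0.10).
#' @return `TRUE` iff `|area_37cl/area_35cl - expected_ratio| <= tolerance`.
#' @export
cl_isotopologue_check <- function(area_35cl, area_37cl,
                                  expected_ratio = natural_cl37_ratio(),
                                  tolerance = 0.10) {
  if (area_35cl <= 0) stop("main (35Cl) peak area must be positive")
  stopifnot(area_37cl >= 0)
  abs(area_37cl / area_35cl - expected_ratio) <= tolerance
}

# Decision table: evidence flag -> level, strongest first. Shipped as data
# so deviations from the default policy are explicit.
.cl_rules <- data.frame(
  flag = c("standard_match", "ms2_matches_literature",
           "characteristic_fragment_present", "rt_fits_series",
           "probable_structure_only", "formula_only"),
  level = c("1", "2a", "2b", "2b", "3", "4"),
  stringsAsFactors = FALSE
)

.cl_order <- c("1", "2a", "2b", "3", "4", "5")

#' The confidence-level decision table
#'
#' @return Data.frame mapping evidence flags to identification confidence
#'   levels (editable copy).
#' @export
confidence_rules <- function() .cl_rules

#' Assign an identification confidence level from evidence
#'
#' Maps per-suspect evidence flags to a Schymanski-style confidence level:
#' a reference-standard match gives level 1; an MS2 match to literature
#' spectra gives 2a; a characteristic fragment and/or a retention-time fit
#' to the homologue series without a full MS2 match gives 2b; a probable
#' structure without MS2 support gives 3; a formula-only detection gives 4.
#' With several flags set, the strongest applies, so adding evidence never
#' lowers the level.
#'
#' @param evidence Named logical vector (or list) over the flags in
#'   [confidence_rules()]; missing flags count as `FALSE`.
#' @param rules Decision table; defaults to [confidence_rules()].
#' @return Confidence level as a character scalar (`"1"`, `"2a"`, `"2b"`,
#'   `"3"`, `"4"`); errors when no evidence flag is set.
#' @export
assign_confidence <- function(evidence, rules = confidence_rules()) {
  evidence <- unlist(evidence)
  stopifnot(is.logical(evidence), !is.null(names(evidence)))
  unknown <- setdiff(names(evidence), rules$flag)
  if (length(unknown)) {
    stop("unknown evidence flag(s): ", paste(unknown, collapse = ", "))
  }
  active <- names(evidence)[evidence]
  if (!length(active)) stop("empty evidence: no flag set")
  levels <- rules$level[match(active, rules$flag)]
  .cl_order[min(match(levels, .cl_order))]
}
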