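# The transferable relative log IE scale. Lab-specific response factors are
# anchored to the shared scale through one compound measured in both systems
# (PFOS in the reference data), and IE datasets from different sources are
# merged at the chemical level.

#' Anchor a log response factor onto the relative log IE scale
#'
#' In linear space `IE_M = (RF_M / RF_anchor) * IE_anchor`; everything here
#' is handled in log10 units, where the conversion is the translation
#' `log IE_M = log RF_M - log RF_anchor + log IE_anchor`. The anchor RF must
#' come from the same measurement sequence as `log_rf_m`.
#'
#' @param log_rf_m log10 response factor of the compound being converted.
#' @param log_rf_anchor log10 response factor of the anchor compound.
#' @param log_ie_anchor Reference log10 IE of the anchor compound.
#' @return log10 IE on the anchor's scale.
#' @examples
#' anchor_rf_to_ie(11.56, 11.56, 2.59)  # the anchor maps to itself: 2.59
#' @export
anchor_rf_to_ie <- function(log_rf_m, log_rf_anchor, log_ie_anchor) {
  stopifnot(is.finite(log_rf_m), is.finite(log_rf_anchor),
            is.finite(log_ie_anchor))
  log_rf_m - log_rf_anchor + log_ie_anchor
}

.ie_measurement_cols <- c("compound_id", "log_ie", "organic_modifier_pct",
                          "aqueous_pH", "polarity_index", "viscosity",
                          "surface_tension", "nh4_present", "source")

#' An IE dataset
#'
#' One row per (chemical, eluent condition) log IE observation, with
#' provenance. `smiles` is optional and used to detect id collisions with
#' conflicting structures on merge.
#'
#' @param measurements Data.frame with columns `compound_id`, `log_ie`, the
#'   six eluent descriptor columns, and `source`; optionally `smiles`.
#' @return An object of class `ie_dataset`.
#' @export
ie_dataset <- function(measurements) {
  missing <- setdiff(.ie_measurement_cols, names(measurements))
  if (length(missing)) stop("ie dataset missing column(s): ",
                            paste(missing, collapse = ", "))
  stopifnot(all(is.finite(measurements$log_ie)))
  structure(list(measurements = as.data.frame(measurements),
                 chemicals = unique(measurements$compound_id)),
            class = "ie_dataset")
}

#' @export
print.ie_dataset <- function(x, ...) {
  cat("<ie_dataset> ", nrow(x$measurements), " measurements, ",
      length(x$chemicals), " unique chemicals\n", sep = "")
  invisible(x)
}

#' Merge two IE datasets
#'
#' Union of measurements; unique chemicals are the union of the two chemical
#' sets and provenance is preserved per measurement. When both datasets carry
#' SMILES for a shared id, conflicting structures are an error. Because the
#' scale assumes comparable eluent regimes, a warning is emitted when the
#' mean organic modifier percentage of a shared chemical differs between
#' sources by more than `modifier_warn_pct`.
#'
#' @param a,b `ie_dataset` objects with harmonized compound ids.
#' @param modifier_warn_pct Warn threshold on organic modifier difference
#'   for shared chemicals (percentage points, default 30).
#' @return The merged `ie_dataset`.
#' @export
merge_ie_datasets <- function(a, b, modifier_warn_pct = 30) {
  stopifnot(inherits(a, "ie_dataset"), inherits(b, "ie_dataset"))
  shared <- intersect(a$chemicals, b$chemicals)
  if ("smiles" %in% names(a$measurements) &&
      "smiles" %in% names(b$measurements)) {
    for (cid in shared) {
      sa <- unique(a$measurements$smiles[a$measurements$compound_id == cid])
      sb <- unique(b$measurements$smiles[b$measurements$compound_id == cid])
      sa <- sa[!is.na(sa)]; sb <- sb[!is.na(sb)]
      if (length(sa) && length(sb) && !any(sa %in% sb)) {
        stop("id collision with conflicting structures: ", cid)
      }
    }
  }
  for (cid in shared) {
    ma <- mean(a$measurements$organic_modifier_pct[
      a$measurements$compound_id == cid])
    mb <- mean(b$measurements$organic_modifier_pct[
      b$measurements$compound_id == cid])
    if (abs(ma - mb) > modifier_warn_pct) {
      warning("chemical ", cid, ": organic modifier differs by ",
              round(abs(ma - mb), 1), " percentage points between sources")
    }
  }
  cols <- union(names(a$measurements), names(b$measurements))
  fill <- function(df) {
    for (cn in setdiff(cols, names(df))) df[[cn]] <- NA
    df[, cols]
  }
  ie_dataset(rbind(fill(a$measurements), fill(b$measurements)))
}

#' Read an IE dataset CSV
#'
#' Columns: `compound_id,smiles,log_ie,organic_modifier_pct,aqueous_pH,`
#' `polarity_index,viscosity,surface_tension,nh4_present,source`.
#'
#' @param path CSV path.
#' @return An `ie_dataset`.
#' @export
read_ie_dataset <- function(path) {
  ie_dataset(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_ie_dataset
#' @param dataset An `ie_dataset`.
#' @export
write_ie_dataset <- function(dataset, path) {
  utils::write.csv(dataset$measurements, path, row.names = FALSE)
}
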