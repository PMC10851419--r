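# Descriptor providers and the feature matrix the IE model consumes.
# The pipeline is provider-agnostic: a provider is just a named, versioned
# function from SMILES to a named numeric vector, so tests can use a small
# deterministic provider and real workflows the OpenBabel-backed one.

#' Define a molecular descriptor provider
#'
#' @param name Provider name.
#' @param compute Function taking one SMILES string and returning a named
#'   numeric vector of descriptors.
#' @param version Version stamp recorded with every feature vector.
#' @return An object of class `descriptor_provider`.
#' @export
descriptor_provider <- function(name, compute, version = "1") {
  stopifnot(is.character(name), is.function(compute))
  structure(list(name = name, compute = compute, version = version),
            class = "descriptor_provider")
}

#' OpenBabel-backed descriptor provider
#'
#' Computes physicochemical descriptors (MW, logP, TPSA, molar refractivity,
#' H-bond donor/acceptor counts) with OpenBabel via ChemmineR, plus element
#' counts from the derived molecular formula.
#'
#' @return A `descriptor_provider`.
#' @export
provider_openbabel <- function() {
  descriptor_provider("openbabel", function(smiles) {
    sdf <- ChemmineR::smiles2sdf(smiles)
    p <- ChemmineR::propOB(sdf)
    f <- parse_formula(p$formula[1])
    counts <- stats::setNames(rep(0, length(supported_elements())),
                              paste0("n_", supported_elements()))
    counts[paste0("n_", names(f))] <- as.numeric(f)
    c(MW = p$MW[1], logP = p$logP[1], TPSA = p$TPSA[1], MR = p$MR[1],
      HBA = p$HBA2[1], HBD = p$HBD[1], counts)
  }, version = as.character(utils::packageVersion("ChemmineR")))
}

#' Formula-count test provider
#'
#' A small deterministic provider whose features are exactly the element
#' counts and molecular weight of the structure — useful where ground truth
#' must be known by construction.
#'
#' @return A `descriptor_provider`.
#' @export
provider_atom_counts <- function() {
  descriptor_provider("atom_counts", function(smiles) {
    f <- smiles_formula(smiles)
    counts <- stats::setNames(rep(0, length(supported_elements())),
                              paste0("n_", supported_elements()))
    counts[paste0("n_", names(f))] <- as.numeric(f)
    c(counts, MW = molecular_weight(f))
  }, version = "1")
}

#' Lookup descriptor provider
#'
#' Serves precomputed descriptor vectors keyed by an identifier (synthetic
#' worlds store descriptors, not structures; their "SMILES" slot carries the
#' key).
#'
#' @param table Data.frame with a `key` column and numeric descriptor columns.
#' @return A `descriptor_provider`.
#' @export
provider_lookup <- function(table) {
  stopifnot("key" %in% names(table))
  cols <- setdiff(names(table), "key")
  descriptor_provider("lookup", function(smiles) {
    i <- match(smiles, table$key)
    if (is.na(i)) stop("no descriptors stored for key: ", smiles)
    unlist(table[i, cols, drop = FALSE])
  }, version = "1")
}

#' Molecular features of a structure
#'
#' @param smiles SMILES string (or provider-specific key).
#' @param provider A `descriptor_provider`.
#' @return Named numeric vector; errors if the provider returns any
#'   non-finite value, naming the offending descriptor.
#' @export
molecular_features <- function(smiles, provider) {
  stopifnot(inherits(provider, "descriptor_provider"))
  v <- provider$compute(smiles)
  if (!is.numeric(v) || is.null(names(v))) {
    stop("provider '", provider$name, "' must return a named numeric vector")
  }
  bad <- names(v)[!is.finite(v)]
  if (length(bad)) {
    stop("provider '", provider$name, "' returned non-finite descriptor(s): ",
         paste(bad, collapse = ", "))
  }
  v
}

#' An eluent condition at time of elution
#'
#' The five mobile-phase descriptors used for IE modeling (aqueous pH,
#' polarity index, viscosity, surface tension, ammonium presence) plus the
#' organic modifier percentage.
#'
#' @param organic_modifier_pct Organic modifier content, % v/v in `[0, 100]`.
#' @param aqueous_pH pH of the aqueous phase, in `[0, 14]`.
#' @param polarity_index Dimensionless eluent polarity index.
#' @param viscosity mPa s.
#' @param surface_tension mN/m.
#' @param nh4_present Logical: ammonium additive present.
#' @return An object of class `eluent_condition`.
#' @export
eluent_condition <- function(organic_modifier_pct, aqueous_pH, polarity_index,
                             viscosity, surface_tension, nh4_present) {
  if (!is.finite(organic_modifier_pct) || organic_modifier_pct < 0 ||
      organic_modifier_pct > 100) {
    stop("organic_modifier_pct must lie in [0, 100]")
  }
  if (!is.finite(aqueous_pH) || aqueous_pH < 0 || aqueous_pH > 14) {
    stop("aqueous_pH must lie in [0, 14]")
  }
  stopifnot(is.finite(polarity_index), is.finite(viscosity),
            viscosity > 0, is.finite(surface_tension), surface_tension > 0,
            is.logical(nh4_present))
  structure(list(organic_modifier_pct = organic_modifier_pct,
                 aqueous_pH = aqueous_pH, polarity_index = polarity_index,
                 viscosity = viscosity, surface_tension = surface_tension,
                 nh4_present = nh4_present),
            class = "eluent_condition")
}

#' Eluent feature vector
#'
#' @param cond An `eluent_condition`.
#' @return Named numeric vector with the five eluent descriptors and the
#'   organic modifier percentage (`nh4_present` encoded 0/1).
#' @export
eluent_features <- function(cond) {
  stopifnot(inherits(cond, "eluent_condition"))
  c(aqueous_pH = cond$aqueous_pH, polarity_index = cond$polarity_index,
    viscosity = cond$viscosity, surface_tension = cond$surface_tension,
    nh4_present = as.numeric(cond$nh4_present),
    organic_modifier_pct = cond$organic_modifier_pct)
}

#' Clean a feature matrix before modeling
#'
#' Removes columns that would invite overtraining: any missing value,
#' near-zero variance (variance below `var_threshold` or fewer than two
#' unique values), or pairwise absolute Pearson correlation above
#' `cor_threshold` (the first column of each correlated pair, in column
#' order, is kept). Rows are never touched and surviving column order is
#' preserved; cleaning is idempotent.
#'
#' @param m Numeric matrix or data.frame (rows = observations).
#' @param cor_threshold Absolute Pearson correlation above which the later
#'   column of a pair is dropped (default 0.95).
#' @param var_threshold Variance below which a column counts as
#'   noninformative (default 1e-12).
#' @return List with `matrix` (the reduced matrix) and `report` (data.frame
#'   `column`,`reason` for every dropped column).
#' @export
clean_feature_matrix <- function(m, cor_threshold = 0.95,
                                 var_threshold = 1e-12) {
  m <- as.matrix(m)
  stopifnot(nrow(m) >= 2, !is.null(colnames(m)))
  dropped <- character(0); reason <- character(0)
  keepable <- colnames(m)
  for (cn in colnames(m)) {
    x <- m[, cn]
    if (anyNA(x)) {
      dropped <- c(dropped, cn); reason <- c(reason, "missing_values")
      keepable <- setdiff(keepable, cn)
    } else if (length(unique(x)) < 2L || stats::var(x) < var_threshold) {
      dropped <- c(dropped, cn); reason <- c(reason, "near_zero_variance")
      keepable <- setdiff(keepable, cn)
    }
  }
  kept <- character(0)
  for (cn in keepable) {
    correlated <- NULL
    for (kc in kept) {
      r <- stats::cor(m[, cn], m[, kc])
      if (is.finite(r) && abs(r) > cor_threshold) { correlated <- kc; break }
    }
    if (is.null(correlated)) {
      kept <- c(kept, cn)
    } else {
      dropped <- c(dropped, cn)
      reason <- c(reason, paste0("correlated_with:", correlated))
    }
  }
  if (!length(kept)) stop("cleaning removed every column")
  list(matrix = m[, kept, drop = FALSE],
       report = data.frame(column = dropped, reason = reason,
                           stringsAsFactors = FALSE))
}
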