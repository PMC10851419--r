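# Isotopologue distributions by polynomial expansion of per-element
# abundances. Signals integrated on the monoisotopic peak under-count the
# compound; the distribution gives the correction.

# Convolve two (mass, abundance) tables. Peaks are binned on a 1e-4 Da grid
# (well below the ~2 mDa spacing of distinct isotopologue compositions) and
# each bin keeps its abundance-weighted mean mass, so accumulated rounding
# never splits one composition into two peaks.
convolve_patterns <- function(a, b, prune = 0) {
  mass <- as.numeric(outer(a$mass, b$mass, `+`))
  ab <- as.numeric(outer(a$abundance, b$abundance))
  key <- round(mass, 4)
  agg_ab <- tapply(ab, key, sum)
  agg_m <- tapply(mass * ab, key, sum) / agg_ab
  out <- list(mass = as.numeric(agg_m), abundance = as.numeric(agg_ab))
  if (prune > 0) {
    keep <- out$abundance > prune
    out <- list(mass = out$mass[keep], abundance = out$abundance[keep])
  }
  out
}

# Merge peaks closer than `tol` Da (guards the rare bin-boundary split).
merge_close_peaks <- function(pat, tol = 2e-4) {
  ord <- order(pat$mass)
  m <- pat$mass[ord]; a <- pat$abundance[ord]
  grp <- cumsum(c(TRUE, diff(m) > tol))
  ab <- as.numeric(tapply(a, grp, sum))
  mm <- as.numeric(tapply(m * a, grp, sum)) / ab
  list(mass = mm, abundance = ab)
}

# Distribution of n atoms of one element, by binary exponentiation.
element_pattern <- function(symbol, n, prune = 0) {
  base <- .isotope_table[[symbol]]
  if (is.null(base)) stop("no tabulated isotope data for element: ", symbol)
  acc <- NULL
  cur <- list(mass = base$mass, abundance = base$abundance)
  while (n > 0) {
    if (n %% 2L == 1L) {
      acc <- if (is.null(acc)) cur else convolve_patterns(acc, cur, prune)
    }
    n <- n %/% 2L
    if (n > 0) cur <- convolve_patterns(cur, cur, prune)
  }
  acc
}

#' Isotopologue pattern of a molecular formula
#'
#' Expands the natural isotopic abundances of every element into the full
#' isotopologue distribution of the molecule, then truncates peaks below
#' `min_abundance`. The monoisotopic fraction — the share of total signal in
#' the all-principal-isotope peak — is always computed on the full expansion,
#' before truncation.
#'
#' @param f A `molformula` or formula string.
#' @param min_abundance Peaks with relative abundance below this fraction are
#'   dropped from the reported peak list (default `1e-4`). Must lie in
#'   `[0, 1)`.
#' @return An object of class `isotope_pattern`: a list with `peaks`
#'   (data.frame of `mass` in Da and `abundance` summing to 1 before
#'   truncation) and `monoisotopic_fraction`.
#' @examples
#' isotope_pattern("C8HF17O3S")$monoisotopic_fraction  # ~0.865 for PFOS
#' @export
isotope_pattern <- function(f, min_abundance = 1e-4) {
  f <- as_molformula(f)
  stopifnot(min_abundance >= 0, min_abundance < 1)
  # Pruning far below any reportable abundance keeps the expansion exact to
  # ~1e-12 while bounding its size.
  prune <- 1e-15
  pat <- NULL
  for (s in names(f)) {
    ep <- element_pattern(s, f[[s]], prune)
    pat <- if (is.null(pat)) ep else convolve_patterns(pat, ep, prune)
  }
  pat <- merge_close_peaks(pat)
  # All-principal-isotope peak: exact product of principal abundances.
  mono <- prod(vapply(names(f), function(s) {
    .isotope_table[[s]]$abundance[1]^f[[s]]
  }, numeric(1)))
  keep <- pat$abundance >= min_abundance
  structure(list(
    peaks = data.frame(mass = pat$mass[keep], abundance = pat$abundance[keep]),
    monoisotopic_fraction = mono
  ), class = "isotope_pattern")
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat("<isotope_pattern> ", nrow(x$peaks), " peaks, monoisotopic fraction ",
      signif(x$monoisotopic_fraction, 5), "\n", sep = "")
  invisible(x)
}

#' Isotope correction factor for a monoisotopic peak area
#'
#' Reciprocal of the monoisotopic fraction: multiplying the detected
#' monoisotopic peak area by this factor estimates the total isotopologue
#' signal of the compound. Always `>= 1`.
#'
#' @param f A `molformula` or formula string.
#' @return Correction factor (dimensionless, `>= 1`).
#' @examples
#' monoisotopic_correction_factor("C8HF17O3S")  # ~1.156 for PFOS
#' @export
monoisotopic_correction_factor <- function(f) {
  f <- as_molformula(f)
  mono <- prod(vapply(names(f), function(s) {
    .isotope_table[[s]]$abundance[1]^f[[s]]
  }, numeric(1)))
  1 / mono
}
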