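#' Parse a molecular formula string
#'
#' Reads an element-count string such as `"C8HF17O3S"` into a named vector of
#' element counts. Element symbols must carry tabulated atomic-weight data
#' (see [supported_elements()]); an unrecognised token is an error. A count of
#' `0` is allowed in the text but dropped from the result.
#'
#' @param text Formula string, e.g. `"C8HF15O2"`.
#' @return An object of class `molformula`: a named integer vector of
#'   element counts.
#' @examples
#' parse_formula("C8HF17O3S")   # PFOS
#' parse_formula("C8HF15O2")    # PFOA
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula string")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    covered <- unlist(regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text)))
    bad <- text
    for (tok in covered) bad <- sub(tok, "", bad, fixed = TRUE)
    stop("malformed formula string; offending token: '", bad, "'")
  }
  syms <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(syms, supported_elements())
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  out <- tapply(counts, syms, sum)
  out <- out[out > 0L]
  if (!length(out)) stop("formula has no atoms: '", text, "'")
  molformula(stats::setNames(as.integer(out), names(out)))
}

#' Construct a molecular formula from element counts
#'
#' @param counts Named integer vector (names are element symbols).
#' @return A `molformula` object.
#' @export
molformula <- function(counts) {
  stopifnot(is.numeric(counts), !is.null(names(counts)), all(counts >= 0))
  unknown <- setdiff(names(counts), supported_elements())
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  counts <- counts[counts > 0]
  if (!length(counts)) stop("formula must contain at least one atom")
  counts <- stats::setNames(as.integer(counts), names(counts))
  counts <- counts[hill_order(names(counts))]
  structure(counts, class = "molformula")
}

# Hill convention: C first, then H, then remaining elements alphabetically;
# when no carbon is present, everything alphabetical.
hill_order <- function(symbols) {
  if ("C" %in% symbols) {
    rest <- sort(setdiff(symbols, c("C", "H")))
    intersect(c("C", "H", rest), symbols)
  } else {
    sort(symbols)
  }
}

#' @export
format.molformula <- function(x, ...) {
  paste0(names(x), ifelse(unclass(x) > 1L, unclass(x), ""), collapse = "")
}

#' @export
print.molformula <- function(x, ...) {
  cat("<molformula> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Add two molecular formulas element-wise
#'
#' @param a,b `molformula` objects.
#' @return The combined `molformula`.
#' @export
formula_add <- function(a, b) {
  syms <- union(names(a), names(b))
  molformula(stats::setNames(
    vapply(syms, function(s) sum(a[s], b[s], na.rm = TRUE), numeric(1)), syms))
}

#' Subtract a molecular formula element-wise
#'
#' Returns `NULL` when the subtraction would drive any element negative or
#' empty the formula, which callers use to signal "not a sub-formula".
#'
#' @param a,b `molformula` objects; `b` is removed from `a`.
#' @return A `molformula`, or `NULL` when `b` is not contained in `a`.
#' @export
formula_subtract <- function(a, b) {
  res <- stats::setNames(as.integer(a), names(a))
  for (s in names(b)) {
    have <- if (s %in% names(res)) res[[s]] else 0L
    if (have < b[[s]]) return(NULL)
    res[s] <- have - b[[s]]
  }
  res <- res[res > 0L]
  if (!length(res)) return(NULL)
  molformula(res)
}

#' Multiply a molecular formula by an integer
#'
#' @param f A `molformula`.
#' @param k Non-negative integer multiplier.
#' @return A `molformula` (errors when `k = 0`).
#' @export
formula_multiply <- function(f, k) {
  stopifnot(k >= 0, k == round(k))
  if (k == 0) stop("cannot scale a formula to zero atoms")
  molformula(stats::setNames(as.integer(f) * as.integer(k), names(f)))
}

as_molformula <- function(x) {
  if (inherits(x, "molformula")) x else parse_formula(x)
}

#' Average molecular weight of a formula
#'
#' Sum of standard (IUPAC conventional) atomic weights times counts, in g/mol.
#'
#' @param f A `molformula` or formula string.
#' @return Molecular weight in g/mol.
#' @examples
#' molecular_weight("C8HF17O3S")  # ~500.13 for PFOS
#' @export
molecular_weight <- function(f) {
  f <- as_molformula(f)
  sum(.atomic_weights[names(f)] * as.numeric(f))
}

#' Number of fluorine atoms in a formula
#'
#' @param f A `molformula` or formula string.
#' @return Integer count of F atoms (0 when absent).
#' @export
fluorine_count <- function(f) {
  f <- as_molformula(f)
  if ("F" %in% names(f)) as.integer(f[["F"]]) else 0L
}
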