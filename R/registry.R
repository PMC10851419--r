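# The compound registry: chemical identities (structure, formula, class,
# fluorinated chain length) shared by every stage of the workflow, plus
# homologue-relation discovery over it.

.pfas_classes <- c("PFCA", "PFSA", "FTCA", "FTSA", "FASA", "FASAA",
                   "diPAP", "Cl-PFESA", "Cl-PFCA", "PFESA", "other")

#' Assemble a compound registry
#'
#' @param id Character vector of unique opaque identifiers.
#' @param name Compound names.
#' @param smiles SMILES strings (may be `NA` when only the formula is known).
#' @param formula Formula strings (Hill notation element counts).
#' @param pfas_class One of `r paste(.pfas_classes, collapse=", ")`.
#' @param fluorinated_carbon_count Total number of CF2/CF3 chain carbons;
#'   summed over both chains for diesters.
#' @param is_target Logical: measured with an analytical standard.
#' @return A data.frame of class `compound_registry`.
#' @export
compound_registry <- function(id, name, smiles, formula, pfas_class,
                              fluorinated_carbon_count, is_target) {
  stopifnot(!anyDuplicated(id), all(fluorinated_carbon_count >= 0))
  bad <- setdiff(unique(pfas_class), .pfas_classes)
  if (length(bad)) stop("unknown pfas_class: ", paste(bad, collapse = ", "))
  # formula strings must parse
  invisible(lapply(formula, parse_formula))
  out <- data.frame(
    id = as.character(id), name = as.character(name),
    smiles = as.character(smiles), formula = as.character(formula),
    pfas_class = as.character(pfas_class),
    fluorinated_carbon_count = as.integer(fluorinated_carbon_count),
    is_target = as.logical(is_target),
    stringsAsFactors = FALSE
  )
  class(out) <- c("compound_registry", "data.frame")
  out
}

#' Read / write a compound registry CSV
#'
#' Columns: `id,name,smiles,formula,pfas_class,fluorinated_carbon_count,is_target`
#' (UTF-8, header required).
#'
#' @param path File path.
#' @return `read_registry` returns a `compound_registry`.
#' @export
read_registry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("id", "name", "smiles", "formula", "pfas_class",
            "fluorinated_carbon_count", "is_target")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("registry CSV missing column(s): ",
                            paste(missing, collapse = ", "))
  compound_registry(df$id, df$name, df$smiles, df$formula, df$pfas_class,
                    df$fluorinated_carbon_count, df$is_target)
}

#' @rdname read_registry
#' @param registry A `compound_registry`.
#' @export
write_registry <- function(registry, path) {
  utils::write.csv(as.data.frame(registry), path, row.names = FALSE)
}

#' Molecular formula from a SMILES string
#'
#' Parses the structure with OpenBabel (via ChemmineR/ChemmineOB) and returns
#' its molecular formula, including implicit hydrogens.
#'
#' @param smiles One SMILES string.
#' @return A `molformula`.
#' @export
smiles_formula <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  sdf <- ChemmineR::smiles2sdf(smiles)
  props <- ChemmineR::propOB(sdf)
  parse_formula(props$formula[1])
}

#' Validate registry structure/formula consistency
#'
#' For every compound with a SMILES, checks that the formula derived from the
#' structure equals the stored formula.
#'
#' @param registry A `compound_registry`.
#' @return Invisibly `TRUE`; errors naming the first inconsistent compound.
#' @export
validate_registry <- function(registry) {
  for (i in seq_len(nrow(registry))) {
    smi <- registry$smiles[i]
    if (is.na(smi) || !nzchar(smi)) next
    derived <- smiles_formula(smi)
    stored <- parse_formula(registry$formula[i])
    if (format(derived) != format(stored)) {
      stop("compound ", registry$id[i], ": SMILES-derived formula ",
           format(derived), " != stored formula ", format(stored))
    }
  }
  invisible(TRUE)
}

# --- construction helpers for linear perfluorinated chains -----------------

perfluoro_tail <- function(n) paste0(strrep("C(F)(F)", n), "F")

#' The 33-compound target registry
#'
#' Builds the registry of target PFASs measured with analytical standards:
#' 11 perfluoroalkyl carboxylic acids (PFCAs, C5-14,16), 4 perfluoroalkyl
#' sulfonic acids (PFSAs, C4,6,8,10), 3 fluorotelomer carboxylic acids
#' (3:3, 5:3, 7:3 FTCAs), 3 fluorotelomer sulfonic acids (4:2, 6:2, 8:2
#' FTSAs), FOSA/MeFOSA/EtFOSA, FOSAA/MeFOSAA/EtFOSAA, 3 polyfluoroalkyl
#' phosphoric acid diesters (6:2, 6:2/8:2, 8:2 diPAP), the chlorinated
#' perfluoroether sulfonates 9Cl-PF3ONS and 11Cl-PF3OUdS, and ADONA.
#' Linear-isomer SMILES are generated programmatically.
#'
#' @return A `compound_registry` with 33 rows.
#' @export
target_registry <- function() {
  rows <- list()
  add <- function(id, name, smiles, formula, cls, nfc) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, name = name, smiles = smiles, formula = formula,
      pfas_class = cls, fluorinated_carbon_count = nfc, is_target = TRUE,
      stringsAsFactors = FALSE)
  }
  # PFCAs, total carbons n (n-1 fluorinated): C5-14 and C16
  pfca_names <- c("5" = "PFPeA", "6" = "PFHxA", "7" = "PFHpA", "8" = "PFOA",
                  "9" = "PFNA", "10" = "PFDA", "11" = "PFUnDA",
                  "12" = "PFDoDA", "13" = "PFTriDA", "14" = "PFTeDA",
                  "16" = "PFHxDA")
  for (n in c(5:14, 16)) {
    add(pfca_names[[as.character(n)]], pfca_names[[as.character(n)]],
        paste0("OC(=O)", perfluoro_tail(n - 1)),
        sprintf("C%dHF%dO2", n, 2 * n - 1), "PFCA", n - 1L)
  }
  # PFSAs, n fully fluorinated carbons: C4, C6, C8, C10
  pfsa_names <- c("4" = "PFBS", "6" = "PFHxS", "8" = "PFOS", "10" = "PFDS")
  for (n in c(4, 6, 8, 10)) {
    add(pfsa_names[[as.character(n)]], pfsa_names[[as.character(n)]],
        paste0("OS(=O)(=O)", perfluoro_tail(n)),
        sprintf("C%dHF%dO3S", n, 2 * n + 1), "PFSA", n)
  }
  # n:3 FTCAs: F(CF2)n-CH2CH2-COOH
  for (n in c(3, 5, 7)) {
    add(sprintf("FTCA_%d_3", n), sprintf("%d:3 FTCA", n),
        paste0("OC(=O)CC", perfluoro_tail(n)),
        sprintf("C%dH5F%dO2", n + 3, 2 * n + 1), "FTCA", n)
  }
  # n:2 FTSAs: F(CF2)n-CH2CH2-SO3H
  for (n in c(4, 6, 8)) {
    add(sprintf("FTSA_%d_2", n), sprintf("%d:2 FTSA", n),
        paste0("OS(=O)(=O)CC", perfluoro_tail(n)),
        sprintf("C%dH5F%dO3S", n + 2, 2 * n + 1), "FTSA", n)
  }
  # (N-alkyl) perfluorooctane sulfonamides
  add("FOSA", "FOSA", paste0("NS(=O)(=O)", perfluoro_tail(8)),
      "C8H2F17NO2S", "FASA", 8L)
  add("MeFOSA", "MeFOSA", paste0("CNS(=O)(=O)", perfluoro_tail(8)),
      "C9H4F17NO2S", "FASA", 8L)
  add("EtFOSA", "EtFOSA", paste0("CCNS(=O)(=O)", perfluoro_tail(8)),
      "C10H6F17NO2S", "FASA", 8L)
  # (N-alkyl) perfluorooctane sulfonamidoacetic acids
  add("FOSAA", "FOSAA", paste0("OC(=O)CNS(=O)(=O)", perfluoro_tail(8)),
      "C10H4F17NO4S", "FASAA", 8L)
  add("MeFOSAA", "MeFOSAA", paste0("OC(=O)CN(C)S(=O)(=O)", perfluoro_tail(8)),
      "C11H6F17NO4S", "FASAA", 8L)
  add("EtFOSAA", "EtFOSAA", paste0("OC(=O)CN(CC)S(=O)(=O)", perfluoro_tail(8)),
      "C12H8F17NO4S", "FASAA", 8L)
  # polyfluoroalkyl phosphoric acid diesters; chain lengths summed
  dipap_smiles <- function(n, m) {
    paste0("OP(=O)(OCC", perfluoro_tail(n), ")OCC", perfluoro_tail(m))
  }
  add("diPAP_6_2", "6:2 diPAP", dipap_smiles(6, 6),
      "C16H9F26O4P", "diPAP", 12L)
  add("diPAP_6_2_8_2", "6:2/8:2 diPAP", dipap_smiles(6, 8),
      "C18H9F30O4P", "diPAP", 14L)
  add("diPAP_8_2", "8:2 diPAP", dipap_smiles(8, 8),
      "C20H9F34O4P", "diPAP", 16L)
  # chlorinated perfluoroether sulfonates: Cl(CF2)m-O-(CF2)2-SO3H
  clpfesa_smiles <- function(m) {
    paste0("OS(=O)(=O)C(F)(F)C(F)(F)O", strrep("C(F)(F)", m - 1), "C(F)(F)Cl")
  }
  add("ClPF3ONS_9", "9Cl-PF3ONS", clpfesa_smiles(6),
      "C8HClF16O4S", "Cl-PFESA", 8L)
  add("ClPF3OUdS_11", "11Cl-PF3OUdS", clpfesa_smiles(8),
      "C10HClF20O4S", "Cl-PFESA", 10L)
  # ADONA: CF3-O-(CF2)3-O-CHF-CF2-COOH
  add("ADONA", "ADONA",
      "OC(=O)C(F)(F)C(F)OC(F)(F)C(F)(F)C(F)(F)OC(F)(F)F",
      "C7H2F12O4", "other", 5L)
  df <- do.call(rbind, rows)
  compound_registry(df$id, df$name, df$smiles, df$formula, df$pfas_class,
                    df$fluorinated_carbon_count, df$is_target)
}

# Head-group residual: formula minus fluorinated_carbon_count x CF2.
# Two compounds of the same class are homologues iff their residuals are
# identical, so N-alkyl variants (a CH2 difference) never pair up and
# diester chains are compared as sums.
head_group_residual <- function(formula, nfc) {
  f <- parse_formula(formula)
  if (nfc == 0L) return(format(f))
  res <- formula_subtract(f, formula_multiply(parse_formula("CF2"), nfc))
  if (is.null(res)) NA_character_ else format(res)
}

#' Find the nearest same-class homologues of a compound
#'
#' A homologue shares the compound's class and head group (identical formula
#' after removing the fluorinated CF2 backbone) and differs by exactly one
#' (`delta = "CF2"`) or two (`delta = "C2F4"`) fluorinated carbons. Diester
#' chain lengths are compared as the sum over both chains. Either slot may be
#' empty; absence is a valid result.
#'
#' @param compound_id Registry id of the query compound.
#' @param registry A `compound_registry`.
#' @param delta `"CF2"` (one CF2 unit) or `"C2F4"` (two).
#' @return List with elements `smaller` and `larger`: registry ids or `NULL`.
#' @examples
#' reg <- target_registry()
#' find_homologues("PFOA", reg)                   # PFHpA / PFNA
#' find_homologues("PFHxS", reg, delta = "C2F4")  # PFBS / PFOS
#' @export
find_homologues <- function(compound_id, registry, delta = c("CF2", "C2F4")) {
  delta <- match.arg(delta)
  step <- if (delta == "CF2") 1L else 2L
  stopifnot(nrow(registry) > 0)
  i <- match(compound_id, registry$id)
  if (is.na(i)) stop("compound not in registry: ", compound_id)
  res_i <- head_group_residual(registry$formula[i],
                               registry$fluorinated_carbon_count[i])
  pick <- function(target_n) {
    for (j in seq_len(nrow(registry))) {
      if (j == i) next
      if (registry$pfas_class[j] != registry$pfas_class[i]) next
      if (registry$fluorinated_carbon_count[j] != target_n) next
      res_j <- head_group_residual(registry$formula[j],
                                   registry$fluorinated_carbon_count[j])
      if (identical(res_i, res_j) && !is.na(res_i)) return(registry$id[j])
    }
    NULL
  }
  list(smaller = pick(registry$fluorinated_carbon_count[i] - step),
       larger = pick(registry$fluorinated_carbon_count[i] + step))
}

#' Count registry compounds possessing a homologue
#'
#' @param registry A `compound_registry`.
#' @param delta Passed to [find_homologues()].
#' @return Integer: number of compounds whose smaller or larger slot is
#'   nonempty.
#' @export
count_with_homologue <- function(registry, delta = c("CF2", "C2F4")) {
  delta <- match.arg(delta)
  sum(vapply(registry$id, function(id) {
    h <- find_homologues(id, registry, delta)
    !is.null(h$smaller) || !is.null(h$larger)
  }, logical(1)))
}
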