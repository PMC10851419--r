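# Embedded elemental data so results are bit-stable across environments.
# Atomic weights: IUPAC/CIAAW 2021 conventional values.
# Isotopic masses and abundances: NIST Atomic Weights and Isotopic
# Compositions (2021 cut), principal isotope listed first.

.atomic_weights <- c(
  H  = 1.008,
  C  = 12.011,
  N  = 14.007,
  O  = 15.999,
  F  = 18.998403163,
  Na = 22.98976928,
  P  = 30.973761998,
  S  = 32.06,
  Cl = 35.45,
  K  = 39.0983,
  Br = 79.904,
  I  = 126.90447
)

.isotope_table <- list(
  H = list(mass = c(1.00782503207, 2.01410177785),
           abundance = c(0.999885, 0.000115)),
  C = list(mass = c(12.0, 13.00335483507),
           abundance = c(0.9893, 0.0107)),
  N = list(mass = c(14.00307400443, 15.00010889888),
           abundance = c(0.99636, 0.00364)),
  O = list(mass = c(15.99491461957, 16.99913175650, 17.99915961286),
           abundance = c(0.99757, 0.00038, 0.00205)),
  F = list(mass = 18.99840316273, abundance = 1.0),
  Na = list(mass = 22.9897692820, abundance = 1.0),
  P = list(mass = 30.97376199842, abundance = 1.0),
  S = list(mass = c(31.9720711744, 32.9714589098, 33.967867004, 35.96708071),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  Cl = list(mass = c(34.968852682, 36.965902602),
            abundance = c(0.7577, 0.2423)),
  K = list(mass = c(38.9637064864, 39.963998166, 40.9618252579),
           abundance = c(0.932581, 0.000117, 0.067302)),
  Br = list(mass = c(78.9183376, 80.9162897),
            abundance = c(0.5069, 0.4931)),
  I = list(mass = 126.9044719, abundance = 1.0)
)

#' Elements with embedded atomic-weight and isotope data
#'
#' @return Character vector of supported element symbols.
#' @export
supported_elements <- function() names(.atomic_weights)
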