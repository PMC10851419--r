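# Shared fixture builders. Everything is generated in code; no files.

# One IE measurement row with a complete eluent description.
meas_rows <- function(compound_id, log_ie, source = "a",
                      organic_modifier_pct = 80, smiles = NA_character_) {
  n <- length(compound_id)
  data.frame(compound_id = compound_id, smiles = rep_len(smiles, n),
             log_ie = log_ie,
             organic_modifier_pct = rep_len(organic_modifier_pct, n),
             aqueous_pH = rep_len(7.8, n), polarity_index = rep_len(6.2, n),
             viscosity = rep_len(0.5, n), surface_tension = rep_len(32, n),
             nh4_present = rep_len(TRUE, n), source = rep_len(source, n),
             stringsAsFactors = FALSE)
}

# Brute-force isotopologue oracle: naive atom-at-a-time full convolution,
# no pruning, no exponentiation tricks — independent of the package path.
# Uses the same 1e-4 Da binning semantics (weighted-mean mass per bin,
# final proximity merge) so peaks of one composition coincide.
naive_isotope_pattern <- function(f) {
  tab <- iequant:::.isotope_table
  dist <- data.frame(mass = 0, ab = 1)
  for (s in names(f)) {
    iso <- tab[[s]]
    for (i in seq_len(f[[s]])) {
      mass <- as.vector(outer(dist$mass, iso$mass, `+`))
      ab <- as.vector(outer(dist$ab, iso$abundance))
      key <- round(mass, 4)
      agg_ab <- tapply(ab, key, sum)
      agg_m <- tapply(mass * ab, key, sum) / agg_ab
      dist <- data.frame(mass = as.numeric(agg_m), ab = as.numeric(agg_ab))
    }
  }
  dist <- dist[order(dist$mass), ]
  grp <- cumsum(c(TRUE, diff(dist$mass) > 2e-4))
  ab <- as.numeric(tapply(dist$ab, grp, sum))
  m <- as.numeric(tapply(dist$mass * dist$ab, grp, sum)) / ab
  data.frame(mass = m, ab = ab)
}

# Spectral equivalence at isotopologue-cluster resolution: clusters sit
# ~1 Da apart, so both spectra are aggregated per integer mass shift from
# the lightest peak and compared on cluster abundance and abundance-weighted
# mean mass. (Row-by-row comparison is ill-posed: near-degenerate
# compositions inside a cluster merge in one convolution order and not the
# other.)
pattern_discrepancy <- function(got, oracle) {
  base <- min(got$mass, oracle$mass)
  agg <- function(mass, ab) {
    k <- round(mass - base)
    s <- tapply(ab, k, sum)
    m <- tapply(mass * ab, k, sum) / s
    list(k = as.integer(names(s)), ab = as.numeric(s), m = as.numeric(m))
  }
  g <- agg(got$mass, got$abundance)
  o <- agg(oracle$mass, oracle$ab)
  ks <- sort(union(g$k, o$k))
  gab <- ifelse(ks %in% g$k, g$ab[match(ks, g$k)], 0)
  oab <- ifelse(ks %in% o$k, o$ab[match(ks, o$k)], 0)
  d_ab <- max(abs(gab - oab))
  shared <- intersect(g$k, o$k)
  big <- shared[o$ab[match(shared, o$k)] > 1e-9]
  d_m <- max(abs(g$m[match(big, g$k)] - o$m[match(big, o$k)]))
  max(d_ab, d_m * 1e-3)  # mean-mass agreement to 1e-6 Da scores below 1e-9
}

# Closed-form weighted least squares (centred normal equations), the
# independent oracle for the calibration fit.
wls_oracle <- function(conc, area, w) {
  xw <- sum(w * conc) / sum(w)
  yw <- sum(w * area) / sum(w)
  slope <- sum(w * (conc - xw) * (area - yw)) / sum(w * (conc - xw)^2)
  c(intercept = yw - slope * xw, slope = slope)
}

# Random small molecular formulas over elements with isotope data.
random_formula <- function(max_atoms = 30) {
  syms <- c("C", "H", "N", "O", "S", "Cl", "F", "Br")
  n_el <- sample(1:4, 1)
  chosen <- sample(syms, n_el)
  counts <- integer(0)
  left <- max_atoms
  for (s in chosen) {
    k <- sample(1:max(1, min(left, 10)), 1)
    counts[s] <- k
    left <- left - k
    if (left <= 0) break
  }
  molformula(counts[counts > 0])
}

# A complete noiseless pipeline scenario built from a synthetic world:
# calibrants with exact calibration series, suspects with known true
# concentrations, and an EOF budget with a constructed unexplained fraction.
noiseless_scenario <- function(seed = 5, unexplained_fraction = 0.3) {
  sim <- simulate_ie_world(n_chemicals = 30, n_conditions = 2, noise_sd = 0,
                           seed = seed)
  w <- sim$world
  chems <- w$chemicals$compound_id
  targets <- chems[1:12]
  susp <- chems[13:20]
  cal_all <- simulate_calibration(w, compounds = chems, area_noise_cv = 0,
                                  seed = seed)
  reg <- compound_registry(w$chemicals$compound_id, w$chemicals$compound_id,
                           NA_character_, w$chemicals$formula, "PFCA",
                           w$chemicals$fluorinated_carbon_count,
                           w$chemicals$compound_id %in% targets)
  truth <- data.frame(
    sample_id = "S1", compound_id = c(targets[1:3], susp),
    conc_ng_g = c(50, 80, 20, 10, 20, 30, 40, 50, 60, 70, 80))
  peaks <- simulate_sample_peaks(w, truth, cal_all$true_log_rf, seed = seed)
  areas <- vapply(split(peaks, peaks$compound_id), function(df) {
    f <- w$chemicals$formula[match(df$compound_id[1], chems)]
    summed_signal(stats::setNames(df$area, df$ion_label), f)
  }, numeric(1))
  tp <- data.frame(sample_id = "S1", compound_id = targets[1:3],
                   area = areas[targets[1:3]])
  sp <- data.frame(sample_id = "S1", suspect_id = susp, smiles = susp,
                   area = areas[susp],
                   formula = w$chemicals$formula[match(susp, chems)],
                   stringsAsFactors = FALSE)
  fe <- function(i) fluorine_equivalent(
    truth$conc_ng_g[i], reg$formula[match(truth$compound_id[i], reg$id)])
  sum_t <- sum(vapply(1:3, fe, numeric(1)))
  sum_s <- sum(vapply(4:nrow(truth), fe, numeric(1)))
  eof <- simulate_eof(data.frame(sample_id = "S1", sum_targets = sum_t,
                                 sum_suspects = sum_s,
                                 unexplained_fraction = unexplained_fraction),
                      sigma = 0, blank_sd = 0, seed = seed)
  cal_targets <- cal_all$series[targets]
  config <- run_config(
    reg, cal_targets, anchor_id = targets[1], anchor_log_ie = 2.59,
    condition = cal_all$condition, provider = w$provider, suspects = sp,
    target_peaks = tp, eof_samples = eof$samples[, c("sample_id", "measured")],
    eof_blanks = eof$blanks, predictor = w$oracle, seed = seed)
  config$suspects_world_data <- sim$data$measurements
  # the anchor's true IE at the calibration condition: anchoring with this
  # reference puts calibrant labels on the same scale as the world data
  config$anchor_true_ie <- w$oracle$fun(
    c(molecular_features(targets[1], w$provider),
      eluent_features(cal_all$condition)))
  list(config = config, truth = truth, world = w,
       unexplained_fraction = unexplained_fraction)
}
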