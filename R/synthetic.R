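# Seeded generators for every input the workflow consumes. The synthetic
# world has a known descriptor-dependent log IE function, calibration series
# with heteroscedastic (multiplicative) noise tied to the IE scale through
# an exact bridge, sample peak tables routed through true response factors,
# and EOF budgets assembled as targets + suspects + unexplained fluorine —
# so parameter recovery is testable end to end and every stage has a
# noise-zero configuration that makes its happy path exact.

#' Simulate a synthetic IE world and dataset
#'
#' Chemicals carry named synthetic descriptors (a chain-length proxy, an
#' acidity proxy, a polarizability proxy, a class indicator, and inert
#' filler descriptors drawn N(0,1)). True log IE is a sparse linear function
#' of the informative descriptors plus an additive eluent effect
#' (organic-modifier driven), and one chemical class — a PFAS-like stratum —
#' has a distinct IE regime (an offset plus its own chain-length slope), so
#' class-augmentation behaviour is constructible. Observations add
#' N(0, `noise_sd`). Every chemical also gets a linear perfluorocarboxylate
#' formula so isotope and fluorine-equivalent arithmetic are exercised.
#'
#' @param n_chemicals Number of chemicals (`>= 10`; default 120).
#' @param n_conditions Number of eluent conditions (default 4).
#' @param n_descriptors Total molecular descriptors (default 20).
#' @param noise_sd Observation noise, log10 IE units (default 0.2, the
#'   order of a well-trained model's residual error).
#' @param pfas_fraction Fraction of chemicals in the PFAS-like class
#'   (default 0.25).
#' @param class_shift log IE offset of the PFAS-like regime (default 1.0).
#' @param seed Integer seed; regeneration with the same seed is
#'   bit-identical.
#' @return List with `world` (chemicals, conditions, truth, provider,
#'   oracle, noise_sd, seed) and `data` (an `ie_dataset`).
#' @export
simulate_ie_world <- function(n_chemicals = 120, n_conditions = 4,
                              n_descriptors = 20, noise_sd = 0.2,
                              pfas_fraction = 0.25, class_shift = 1.0,
                              seed = 1L) {
  if (n_chemicals < 10) stop("need at least 10 chemicals")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  stopifnot(n_descriptors >= 5, n_conditions >= 1)
  rng <- local_rng(seed)
  ids <- sprintf("chem%03d", seq_len(n_chemicals))
  n_pfas <- round(pfas_fraction * n_chemicals)
  cls <- c(rep("pfas_like", n_pfas), rep("other", n_chemicals - n_pfas))
  desc <- matrix(rng_rnorm(rng, n_chemicals * (n_descriptors - 1L)),
                 nrow = n_chemicals)
  colnames(desc) <- c("chain_proxy", "acidity_proxy", "polarizability_proxy",
                      sprintf("filler_%02d", seq_len(n_descriptors - 4L)))
  desc <- cbind(desc, class_indicator = as.numeric(cls == "pfas_like"))
  # PFCA-like formulas from the chain proxy rank: C4..C17 acids
  chain_c <- 4L + as.integer(round(13 * (rank(desc[, "chain_proxy"],
                                              ties.method = "first") - 1) /
                                     (n_chemicals - 1)))
  formulas <- sprintf("C%dHF%dO2", chain_c, 2L * chain_c - 1L)
  truth <- list(
    intercept = 0.5,
    beta = c(chain_proxy = 0.8, acidity_proxy = 0.5,
             polarizability_proxy = 0.3),
    class_shift = class_shift,
    class_chain_slope = 0.4,     # extra chain slope inside the PFAS regime
    modifier_slope = 0.8         # log IE gain over 0 -> 100 % modifier
  )
  om_levels <- seq(20, 80, length.out = n_conditions)
  conditions <- lapply(seq_len(n_conditions), function(i) {
    eluent_condition(organic_modifier_pct = om_levels[i],
                     aqueous_pH = 2.7 + 5.1 * (i - 1) /
                       max(1, n_conditions - 1),
                     polarity_index = 5.8 + 0.4 * i, viscosity = 0.4 + 0.1 * i,
                     surface_tension = 30 + 2 * i,
                     nh4_present = i %% 2L == 0L)
  })
  true_fun <- function(x) {
    unname(truth$intercept +
             sum(truth$beta * x[names(truth$beta)]) +
             x[["class_indicator"]] *
               (truth$class_shift +
                  truth$class_chain_slope * x[["chain_proxy"]]) +
             truth$modifier_slope * x[["organic_modifier_pct"]] / 100)
  }
  chem_df <- data.frame(compound_id = ids, class = cls, formula = formulas,
                        mw = vapply(formulas, molecular_weight, numeric(1)),
                        fluorinated_carbon_count = chain_c - 1L,
                        stringsAsFactors = FALSE)
  lookup <- cbind(data.frame(key = ids, stringsAsFactors = FALSE),
                  as.data.frame(desc))
  provider <- provider_lookup(lookup)
  rows <- list()
  for (ci in seq_along(conditions)) {
    ef <- eluent_features(conditions[[ci]])
    for (k in seq_len(n_chemicals)) {
      x <- c(desc[k, ], ef)
      tr <- true_fun(x)
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = ids[k], smiles = ids[k], true_log_ie = tr,
        log_ie = NA_real_, organic_modifier_pct = ef[["organic_modifier_pct"]],
        aqueous_pH = ef[["aqueous_pH"]],
        polarity_index = ef[["polarity_index"]],
        viscosity = ef[["viscosity"]],
        surface_tension = ef[["surface_tension"]],
        nh4_present = ef[["nh4_present"]], source = "synthetic",
        stringsAsFactors = FALSE)
    }
  }
  meas <- do.call(rbind, rows)
  meas$log_ie <- meas$true_log_ie + rng_rnorm(rng, nrow(meas), 0, noise_sd)
  oracle <- structure(list(fun = true_fun,
                           feature_names = c(colnames(desc),
                                             names(eluent_features(
                                               conditions[[1]])))),
                      class = "ie_oracle")
  world <- list(chemicals = chem_df, descriptors = lookup,
                descriptor_names = colnames(desc), conditions = conditions,
                truth = truth, provider = provider, oracle = oracle,
                noise_sd = noise_sd, seed = as.integer(seed))
  list(world = world, data = ie_dataset(meas))
}

#' @export
predict_log_ie.ie_oracle <- function(model, x) {
  x <- align_features(x, model$feature_names)
  vapply(seq_len(nrow(x)), function(i) model$fun(x[i, ]), numeric(1))
}

#' Simulate calibration series tied to the IE scale
#'
#' Every compound's true log RF is an exact linear bridge of its true log IE
#' at the calibration condition (`log RF = slope * log IE + intercept`), so
#' bridge recovery is testable. Areas follow
#' `area = RF * conc * (1 + eps)` with multiplicative noise of coefficient
#' of variation `area_noise_cv` — the heteroscedastic regime 1/concentration
#' weighting is designed for.
#'
#' @param world A world from [simulate_ie_world()].
#' @param compounds Chemical ids to calibrate (default: all).
#' @param levels Number of concentration levels (`>= 3`, default 7),
#'   log-spaced over `conc_range`.
#' @param conc_range Molar concentration range (default `1e-9` to `1e-6`).
#' @param area_noise_cv Coefficient of variation of the multiplicative area
#'   noise (default 0.05).
#' @param bridge_slope,bridge_intercept The generating IE-to-RF bridge
#'   (defaults 1 and 8.97).
#' @param condition_index Which world condition the calibration was run
#'   under (default 1).
#' @param seed Integer seed.
#' @return List with `series` (named list of `concentration`/`area`
#'   data.frames), `true_log_rf` (named vector), `bridge_slope`,
#'   `bridge_intercept`, `condition`.
#' @export
simulate_calibration <- function(world, compounds = world$chemicals$compound_id,
                                 levels = 7, conc_range = c(1e-9, 1e-6),
                                 area_noise_cv = 0.05, bridge_slope = 1,
                                 bridge_intercept = 8.97,
                                 condition_index = 1, seed = 1L) {
  stopifnot(levels >= 3)
  rng <- local_rng(seed)
  cond <- world$conditions[[condition_index]]
  ef <- eluent_features(cond)
  conc <- 10^seq(log10(conc_range[1]), log10(conc_range[2]),
                 length.out = levels)
  series <- list(); true_log_rf <- numeric(0)
  for (cid in compounds) {
    x <- c(molecular_features(cid, world$provider), ef)
    log_ie <- world$oracle$fun(x)
    log_rf <- bridge_slope * log_ie + bridge_intercept
    eps <- if (area_noise_cv > 0) rng_rnorm(rng, levels, 0, area_noise_cv)
           else rep(0, levels)
    series[[cid]] <- data.frame(concentration = conc,
                                area = 10^log_rf * conc * (1 + eps))
    true_log_rf[cid] <- log_rf
  }
  list(series = series, true_log_rf = true_log_rf,
       bridge_slope = bridge_slope, bridge_intercept = bridge_intercept,
       condition = cond)
}

#' Simulate sample peak tables through true response factors
#'
#' Converts true wet-weight concentrations to extract molarity with the
#' sample-preparation constants, generates the total ion signal through the
#' compound's true RF, optionally dilutes it to the monoisotopic peak using
#' the formula's isotope distribution, and splits it across in-source
#' fragment labels — so the summed-signal reconstruction is exercised by
#' construction.
#'
#' @param world A synthetic world.
#' @param true_concentrations Data.frame `sample_id`, `compound_id`,
#'   `conc_ng_g` (`>= 0`).
#' @param true_log_rf Named vector of true log10 RFs (from
#'   [simulate_calibration()]).
#' @param fragment_split Numeric vector summing to 1: share of the signal in
#'   the molecular ion and each in-source fragment (default `c(0.7, 0.3)`).
#' @param isotope_dilution If `TRUE` (default), areas are monoisotopic and
#'   must be corrected with [monoisotopic_correction_factor()].
#' @param area_noise_cv Multiplicative area noise CV (default 0).
#' @param sample_mass_g,extract_volume_l Unit-chain constants.
#' @param seed Integer seed.
#' @return Long data.frame `sample_id`, `compound_id`, `ion_label`, `area`.
#' @export
simulate_sample_peaks <- function(world, true_concentrations, true_log_rf,
                                  fragment_split = c(0.7, 0.3),
                                  isotope_dilution = TRUE,
                                  area_noise_cv = 0,
                                  sample_mass_g = 0.5,
                                  extract_volume_l = 2.5e-4, seed = 1L) {
  stopifnot(all(true_concentrations$conc_ng_g >= 0),
            abs(sum(fragment_split) - 1) < 1e-12)
  rng <- local_rng(seed)
  labels <- c("[M-H]-", sprintf("frag%d", seq_len(length(fragment_split) - 1)))
  rows <- list()
  for (i in seq_len(nrow(true_concentrations))) {
    cid <- true_concentrations$compound_id[i]
    meta <- world$chemicals[world$chemicals$compound_id == cid, ]
    if (!nrow(meta)) stop("unknown compound in concentration table: ", cid)
    molar <- true_concentrations$conc_ng_g[i] * sample_mass_g /
      (meta$mw * 1e9 * extract_volume_l)
    total <- 10^true_log_rf[[cid]] * molar
    if (isotope_dilution) {
      total <- total / monoisotopic_correction_factor(meta$formula)
    }
    noise <- if (area_noise_cv > 0) 1 + rng_rnorm(rng, 1, 0, area_noise_cv)
             else 1
    rows[[i]] <- data.frame(
      sample_id = true_concentrations$sample_id[i], compound_id = cid,
      ion_label = labels, area = total * noise * fragment_split,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Simulate EOF and procedural blank tables
#'
#' Builds each sample's true EOF as
#' `(sum_targets + sum_suspects) / (1 - unexplained_fraction)` — i.e. the
#' quantifiable fluorine plus the constructed unexplained share — adds
#' measurement noise, offsets by the blank level, and draws procedural
#' blanks for the LOQ logic.
#'
#' @param budgets Data.frame `sample_id`, `sum_targets`, `sum_suspects`
#'   (ng F/g) and `unexplained_fraction` in `[0, 1)`.
#' @param sigma Measurement noise sd on EOF, ng F/g (default 0).
#' @param n_blanks Number of procedural blanks (default 3).
#' @param blank_mean,blank_sd Blank fluoride level and spread, ng F/g.
#' @param seed Integer seed.
#' @return List with `samples` (data.frame `sample_id`, `measured` raw
#'   fluoride incl. blank, `true_eof`, `true_ueof_fraction`) and `blanks`.
#' @export
simulate_eof <- function(budgets, sigma = 0, n_blanks = 3, blank_mean = 5,
                         blank_sd = 0, seed = 1L) {
  stopifnot(all(budgets$unexplained_fraction >= 0),
            all(budgets$unexplained_fraction < 1))
  rng <- local_rng(seed)
  true_eof <- (budgets$sum_targets + budgets$sum_suspects) /
    (1 - budgets$unexplained_fraction)
  blanks <- blank_mean + rng_rnorm(rng, n_blanks, 0, blank_sd)
  measured <- true_eof + rng_rnorm(rng, length(true_eof), 0, sigma) +
    mean(blanks)
  list(samples = data.frame(sample_id = budgets$sample_id,
                            measured = measured, true_eof = true_eof,
                            true_ueof_fraction = budgets$unexplained_fraction,
                            stringsAsFactors = FALSE),
       blanks = blanks)
}
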