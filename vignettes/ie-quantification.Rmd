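---
title: "Ionization-efficiency-based quantification and the fluorine mass balance"
author: "iequant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ionization-efficiency-based quantification and the fluorine mass balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iequant)
```

## Scope and model

`iequant` quantifies LC-ESI(−)-HRMS suspects that lack analytical standards.
The chain of reasoning is:

1. a compound's **response factor** (RF, signal per mol/L) is instrument- and
   lab-specific, but its **relative ionization efficiency** (IE) is not;
2. RFs measured in one sequence can be translated onto a shared relative
   log IE scale through a single anchor compound present in both systems
   (`anchor_rf_to_ie()`: a pure translation in log10 space);
3. log IE is learnable from molecular structure plus eluent composition,
   here with gradient-boosted regression trees (`tune_and_train()`);
4. predicted log IE is converted back to a measurement-specific log RF by an
   ordinary least-squares **bridge** fitted on the in-run target calibrants
   (`fit_ie_rf_bridge()`), after which concentration estimation is ordinary
   inverse calibration (`concentration_from_rf()`);
5. quantified targets and suspects, expressed as fluorine equivalents
   (`fluorine_equivalent()`), are compared against extractable
   organofluorine to yield the unidentified fraction (`compute_ueof()`).

The assumptions worth stating: ionization happens through the deprotonated
molecular ion whose in-source fragments are summed into one signal budget;
eluent regimes of the reference IE data and the local sequence are similar
enough that no condition correction is applied beyond the descriptors the
model sees (a warning is raised on merge when organic-modifier content
differs strongly for a shared chemical); and the bridge is linear in
log–log space over the calibrants' IE range.

## Parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| calibration weighting | 1/concentration | — | heteroscedastic areas: relative noise is roughly constant, so low levels must not be drowned by high ones |
| linearity threshold | 0.20 (inclusive) | fraction | a calibration is acceptable when its worst relative residual is within ±20% |
| relative residual space | area, vs observed | — | `(fitted − observed)/observed`; configurable, documented here because conventions differ |
| correlation cut in cleaning | 0.95 | \|Pearson r\| | drop the later of a correlated descriptor pair to limit overtraining |
| near-zero variance cut | 1e-12 / <2 unique | — | constant descriptors carry no information |
| test fraction | 0.2 | chemicals | held-out chemicals, stratified so ~80% of the PFAS stratum trains |
| CV groups | 5 | folds | grouped on chemical identity — the leakage control |
| hyperparameter grid | depth 1–3, eta 0.05, 1200 rounds, min_child_weight 5 | — | small additive-leaning grid; grouped CV picks the depth |
| isotope truncation | 1e-4 | abundance | reported peak list only; the monoisotopic fraction is always computed before truncation |
| bridge mode | free slope | — | fixed-slope-1 mode available when calibrant IE span is narrow |
| sample mass / extract volume | 0.5 g / 250 µL | g, L | unit chain from extract molarity to ng/g wet weight; explicit config, not hard-coded science |
| LOQ rule | 3 × sd(blanks), n−1 | ng F/g | procedural-blank based; sample (n−1) sd adopted |
| Cl isotopologue tolerance | ±0.10 | ratio | "approximately 30%" operationalised around the natural 37Cl/35Cl ratio 0.320 |

Atomic weights and isotopic abundances are embedded (IUPAC/CIAAW 2021
conventional values, NIST isotopic compositions) so results are bit-stable
across environments.

## Design choices where the design was open

* **Homologue definition.** Two registry compounds are homologues when they
  share the class *and* the head-group residual — the formula left after
  removing `fluorinated_carbon_count × CF2` — and differ by exactly one
  (CF₂) or two (C₂F₄) fluorinated carbons, with diester chains summed.
  The residual rule needs no extra metadata, and it makes N-alkyl
  sulfonamide variants (a CH₂ difference) non-homologues. "Chain
  difference" is read in fluorinated carbons; this reading reproduces the
  10 (±CF₂) and 26 (±C₂F₄) counts over the 33-target registry.
* **Descriptor providers are pluggable.** The model is descriptor-set
  agnostic: `descriptor_provider()` defines the contract, with an
  OpenBabel-backed default (`provider_openbabel()`), a formula-count test
  provider, and a lookup provider for synthetic worlds. Tests therefore
  never depend on any particular descriptor software.
* **Resampling.** Hyperparameters are scored by grouped k-fold CV repeated
  `tuning_resamples` times (default 1); the repeated-grouped-CV reading was
  chosen over bootstrap-pair resampling because group integrity is the
  non-negotiable part.
* **Leave-one-out evaluation** retrains one model per target chemical with
  *fixed* hyperparameters (caller-supplied, e.g. the tuned `best_params`) —
  per-target retuning would be slow and would blur what is being measured.
* **Wilcoxon zero differences** are dropped; two identical error vectors
  return p = 1 by convention (no signal).
* **Bridge calibrants** default to linearity-passing targets only.
* **Representative structure for multi-candidate suspects**: candidates are
  ordered by the caller and the first is used — linear chain, terminal Cl
  for chloro-substituted classes, ether between first and second carbon for
  ether-sulfonates. Structure-free classes (formula only) raise an error in
  model quantification: that is a statement about the method, not a bug.
* **Below-LOQ EOF** stays flagged (never zeroed or imputed); budgets then
  report the LOQ value in place of EOF and leave the UEOF fraction
  undefined.

## What the synthetic generators emulate

`simulate_ie_world()` builds chemicals with named descriptors (chain-length,
acidity and polarizability proxies plus inert filler), four eluent
conditions spanning 20–80% organic modifier, and a true log IE surface that
is sparse-linear in the informative descriptors with an additive
organic-modifier effect. One class ("pfas_like", 25% of chemicals by
default) carries a distinct regime — a +1.0 log offset and an extra chain
slope of 0.4 — so the question *does adding congeners of a class improve
predictions for that class?* is constructible. Observation noise defaults
to 0.2 log units, the order of a well-trained model's residual error;
calibration areas carry 5% multiplicative noise by default
(`simulate_calibration()`), true RFs are tied to true IE by an exact bridge
(slope 1, intercept 8.97) so bridge recovery is testable, and
`simulate_sample_peaks()` routes concentrations through true RFs with
in-source fragment splitting and isotope dilution so the summed-signal
reconstruction is exercised. `simulate_eof()` composes EOF as
targets + suspects + a constructed unexplained fraction.

What the generators do **not** emulate: real descriptor collinearity
structure, retention behaviour, matrix effects, censoring at detection
limits, and non-additive IE chemistry. Passing tests on these worlds
demonstrate that the machinery recovers known structure under stated noise
— not that any particular real-world accuracy is guaranteed.

Problem sizes used in the recovery checks: 120 chemicals × 4 conditions
with noise 0.2 over three seeds for held-out and leave-one-out evaluation;
30-chemical noiseless worlds for the end-to-end identities. These sizes
give stable estimates while keeping the whole suite comfortably fast.

## Numerical choices and degenerate inputs

* Isotopologue expansion uses per-element binary exponentiation with
  convolution on a 1e-4 Da grid; each bin keeps its abundance-weighted mean
  mass, and peaks closer than 2e-4 Da are merged at the end. Components
  below 1e-15 abundance are pruned (total error ≪ 1e-9). The monoisotopic
  fraction is the exact product of principal-isotope abundances, never a
  truncated sum.
* Calibration fits refuse fewer than three distinct concentrations
  (singular design); zero-area levels fit but are excluded from relative
  residuals (division by zero).
* The bridge refuses fewer than three calibrants or zero IE variance.
* `fold_error()` is only defined for positive quantities and errors
  otherwise; `error_summary()` refuses empty input.
* All randomness flows through seed-scoped generators that save and restore
  the caller's RNG state; the same seed reproduces a synthetic world
  bit-identically.

## The noiseless identity, and why an oracle predictor exists

`run_pipeline()` accepts either `"train"` (fit the gradient-boosted model)
or any object with a `predict_log_ie()` method. Synthetic worlds export
their true IE surface as such an object (`world$oracle`). On a noiseless
world with the oracle as predictor, the pipeline is an exact identity:
calibration slopes equal true RFs, the bridge refits its generating line,
every concentration's fold error is exactly 1, and the UEOF fraction equals
the constructed unexplained share. This split deliberately isolates the
plumbing (signal summation, isotope correction, weighted fits, anchoring,
bridging, unit chain, budget arithmetic) from model error, which is
assessed separately on noisy worlds.

On those noisy worlds (σ = 0.2), held-out RMSE for new chemicals sits near
0.3 log units — between the noise floor and 2× the floor, as expected when
tree ensembles interpolate a smooth surface. Leave-one-out evaluation is
reported over a seeded representative sample of chemicals: for members at
the extreme chain lengths of the distinct-regime class, a left-out chemical
lies outside the training support and tree models cannot extrapolate, which
is an applicability-domain limitation (visible in PCA-style coverage
checks), not a failure of surface recovery; the class-level question is
answered by the congener-augmentation comparison instead.

## Known limitations

* Tree ensembles do not extrapolate: predictions outside the descriptor
  range of the training chemicals revert toward constants. Applicability-
  domain scoring is out of scope; inspect coverage before trusting a
  prediction.
* Anchoring assumes one shared compound and comparable eluent regimes; no
  cross-instrument transfer model beyond the single-anchor translation is
  provided.
* Branched isomers are not enumerated; the isomer-sensitivity helper
  (`isomer_sensitivity()`) quantifies linear-isomer spread only.
* Adducts beyond [M−H]⁻ and charge states above 1 are out of scope, as are
  peak detection, retention-time alignment and matrix-effect correction.
* The homologue comparator requires a measured RF in the registry class;
  suspects without one are "model-only quantifiable" by design.

## A compact end-to-end run

```{r pipeline, eval = FALSE}
sim <- simulate_ie_world(n_chemicals = 30, n_conditions = 2,
                         noise_sd = 0, seed = 5)
w <- sim$world
targets <- w$chemicals$compound_id[1:12]
cal <- simulate_calibration(w, compounds = w$chemicals$compound_id,
                            area_noise_cv = 0, seed = 5)
reg <- compound_registry(w$chemicals$compound_id, w$chemicals$compound_id,
                         NA_character_, w$chemicals$formula, "PFCA",
                         w$chemicals$fluorinated_carbon_count,
                         w$chemicals$compound_id %in% targets)
# ... assemble suspects/target peaks/EOF as in tests/testthat/helper-fixtures.R
cfg <- run_config(reg, cal$series[targets], anchor_id = targets[1],
                  anchor_log_ie = 2.59, condition = cal$condition,
                  provider = w$provider, suspects = sp, target_peaks = tp,
                  eof_samples = eof$samples[, c("sample_id", "measured")],
                  eof_blanks = eof$blanks, predictor = w$oracle, seed = 5)
report <- run_pipeline(cfg)
report$budgets[[1]]$with_suspects   # UEOF equals the constructed fraction
```
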