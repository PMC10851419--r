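count_provider <- provider_atom_counts()

test_that("descriptor providers are deterministic and validated", {
  v1 <- molecular_features("C(F)(F)(F)F", count_provider)
  v2 <- molecular_features("C(F)(F)(F)F", count_provider)
  expect_identical(v1, v2)
  expect_equal(unname(v1["n_F"]), 4)
  expect_equal(unname(v1["n_C"]), 1)
  bad <- descriptor_provider("bad", function(s) c(x = NaN))
  expect_error(molecular_features("C", bad), "non-finite descriptor")
})

test_that("canonical and non-canonical SMILES of one structure agree", {
  a <- molecular_features("OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F",
                          count_provider)
  b <- molecular_features("FC(F)(C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F)C(F)(F)C(O)=O",
                          count_provider)
  expect_equal(a, b)
})

test_that("eluent features carry the five mobile-phase descriptors", {
  # reference-dataset condition: pH 7.8, 80% acetonitrile, ammonium present
  cond <- eluent_condition(80, 7.8, 6.2, 0.5, 32, TRUE)
  v <- eluent_features(cond)
  expect_named(v, c("aqueous_pH", "polarity_index", "viscosity",
                    "surface_tension", "nh4_present",
                    "organic_modifier_pct"))
  expect_equal(unname(v[c("aqueous_pH", "organic_modifier_pct")]),
               c(7.8, 80))
  expect_equal(unname(eluent_features(
    eluent_condition(52, 7, 6.2, 0.5, 32, FALSE))["nh4_present"]), 0)
  expect_error(eluent_condition(80, 15, 6.2, 0.5, 32, TRUE), "aqueous_pH")
  expect_error(eluent_condition(120, 7, 6.2, 0.5, 32, TRUE),
               "organic_modifier_pct")
})

test_that("cleaning drops constant, duplicated and correlated columns", {
  set.seed(3)
  x <- rnorm(50)
  m <- cbind(a = x, const = rep(2, 50), dup = x, b = rnorm(50),
             hasna = c(NA, rnorm(49)))
  out <- clean_feature_matrix(m, cor_threshold = 0.95)
  expect_identical(colnames(out$matrix), c("a", "b"))
  expect_setequal(out$report$column, c("const", "dup", "hasna"))
  expect_equal(out$report$reason[out$report$column == "const"],
               "near_zero_variance")
  expect_equal(out$report$reason[out$report$column == "hasna"],
               "missing_values")
  expect_match(out$report$reason[out$report$column == "dup"],
               "correlated_with:a")
})

test_that("correlation rule matches an explicit correlation-matrix oracle", {
  set.seed(9)
  x <- rnorm(200)
  y <- x + rnorm(200, sd = 0.1)   # r ~ 0.99
  z <- rnorm(200)
  m <- cbind(f1 = x, f2 = y, f3 = z)
  r_oracle <- cor(m)
  expect_gt(abs(r_oracle["f1", "f2"]), 0.95)
  out <- clean_feature_matrix(m, cor_threshold = 0.95)
  # first of the pair kept, in column order
  expect_identical(colnames(out$matrix), c("f1", "f3"))
  # below the threshold nothing is dropped
  out2 <- clean_feature_matrix(m, cor_threshold = 0.999)
  expect_identical(colnames(out2$matrix), c("f1", "f2", "f3"))
})

test_that("cleaning is idempotent and preserves rows and column order", {
  set.seed(4)
  m <- matrix(rnorm(200), 20, dimnames = list(NULL, paste0("c", 1:10)))
  m[, 4] <- m[, 2] * 1.0001
  once <- clean_feature_matrix(m)
  twice <- clean_feature_matrix(once$matrix)
  expect_identical(once$matrix, twice$matrix)
  expect_equal(nrow(twice$report), 0L)
  expect_equal(nrow(once$matrix), nrow(m))
  expect_identical(colnames(once$matrix),
                   intersect(colnames(m), colnames(once$matrix)))
  expect_error(clean_feature_matrix(cbind(k = rep(1, 5))), "every column")
})
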