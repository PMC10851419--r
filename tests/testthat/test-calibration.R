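test_that("summed signal adds all ions and applies the isotope correction", {
  # monoisotopic-only formula: correction factor 1
  expect_equal(summed_signal(c(`M-H` = 80, frag1 = 20), molformula(c(F = 10))),
               100)
  expect_equal(summed_signal(c(`M-H` = 100), "C8HF17O3S"),
               100 * monoisotopic_correction_factor("C8HF17O3S"))
  expect_equal(summed_signal(c(`M-H` = 100), "C8HF17O3S"), 115.6,
               tolerance = 1e-3)
  expect_equal(summed_signal(c(a = 0, b = 0), "C8HF17O3S"), 0)
  expect_error(summed_signal(numeric(0), "C8HF17O3S"), "empty ion area")
})

test_that("noiseless lines are recovered exactly", {
  conc <- c(1, 2, 5, 10, 20) * 1e-9
  f1 <- fit_response_factor(conc, 5e9 * conc)
  expect_equal(f1$response_factor, 5e9, tolerance = 1e-9)
  expect_equal(f1$intercept, 0, tolerance = 1e-3)
  expect_true(all(abs(f1$relative_residuals) < 1e-9))
  expect_true(f1$linear)
  f2 <- fit_response_factor(conc, 5e9 * conc + 7)
  expect_equal(f2$response_factor, 5e9, tolerance = 1e-9)
  expect_equal(f2$intercept, 7, tolerance = 1e-6)
  expect_error(fit_response_factor(rep(1e-9, 4), c(1, 2, 3, 4)),
               ">= 3 distinct")
})

test_that("weighted slope matches the closed-form normal-equations oracle", {
  set.seed(21)
  for (i in 1:25) {
    conc <- sort(runif(6, 1e-9, 1e-6))
    area <- 3e9 * conc * (1 + rnorm(6, 0, 0.1)) + rnorm(6, 0, 5)
    area <- pmax(area, 0)
    fit <- fit_response_factor(conc, area)
    oracle <- wls_oracle(conc, area, 1 / conc)
    expect_equal(fit$response_factor, unname(oracle["slope"]),
                 tolerance = 1e-10)
    expect_equal(fit$intercept, unname(oracle["intercept"]),
                 tolerance = 1e-10)
  }
})

test_that("area scaling scales RF and leaves relative residuals unchanged", {
  set.seed(5)
  conc <- c(1, 3, 10, 30, 100) * 1e-9
  area <- 2e9 * conc * (1 + rnorm(5, 0, 0.05))
  f1 <- fit_response_factor(conc, area)
  f2 <- fit_response_factor(conc, area * 7)
  expect_equal(f2$response_factor, 7 * f1$response_factor)
  expect_equal(f2$relative_residuals, f1$relative_residuals,
               tolerance = 1e-12)
  # permutation invariance
  p <- c(3, 1, 5, 2, 4)
  f3 <- fit_response_factor(conc[p], area[p])
  expect_equal(f3$response_factor, f1$response_factor, tolerance = 1e-12)
})

test_that("linearity rule uses the worst relative residual, inclusive", {
  fit <- structure(list(relative_residuals = c(0, 0.1, -0.2)),
                   class = "calibration_fit")
  expect_true(check_linearity(fit))           # exactly 0.20 passes
  fit$relative_residuals <- c(0.05, -0.25)
  expect_false(check_linearity(fit))          # 25% fails
  fit$relative_residuals <- rep(0, 5)
  expect_true(check_linearity(fit))
})

test_that("RF recovery improves with more calibration levels", {
  # Monte-Carlo property: median fold error of the fitted RF shrinks as
  # levels increase under fixed multiplicative noise
  set.seed(77)
  med_err <- sapply(c(4, 12), function(L) {
    errs <- replicate(60, {
      conc <- 10^seq(-9, -6, length.out = L)
      area <- 4e9 * conc * (1 + rnorm(L, 0, 0.15))
      fold_error(fit_response_factor(conc, area)$response_factor, 4e9)
    })
    median(errs)
  })
  expect_lt(med_err[2], med_err[1])
})

test_that("long-format calibration CSVs sum ions per level", {
  reg <- target_registry()
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(compound_id = "PFOS", level_index = rep(1:3, each = 2),
                   concentration_mol_per_L = rep(c(1e-9, 1e-8, 1e-7), each = 2),
                   ion_label = rep(c("[M-H]-", "frag1"), 3),
                   area = c(80, 20, 800, 200, 8000, 2000))
  write.csv(df, path, row.names = FALSE)
  cal <- read_calibration(path, reg)
  expect_equal(cal$PFOS$area,
               c(100, 1000, 10000) * monoisotopic_correction_factor("C8HF17O3S"))
})
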