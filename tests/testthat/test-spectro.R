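refs <- asymfold:::reference_spectra()

test_that("deconvolution recovers exact and mixed spectra", {
  # exact member of the basis
  raw <- refs$liposome
  raw$absorbance <- 2 * raw$absorbance
  d <- deconvolute_spectrum(raw, refs)
  expect_equal(unname(d$concentrations["liposome"]), 2, tolerance = 1e-8)
  expect_equal(unname(d$concentrations["fluorophore"]), 0, tolerance = 1e-8)
  expect_lt(d$residual_ss, 1e-12)

  # all-zero spectrum
  raw$absorbance <- 0 * raw$absorbance
  d0 <- deconvolute_spectrum(raw, refs)
  expect_equal(unname(d0$concentrations), c(0, 0))
  expect_equal(d0$residual_ss, 0)
})

test_that("deconvolution matches a grid-search oracle on a noisy mixture", {
  set.seed(4)
  raw <- refs$liposome
  raw$absorbance <- 1.5 * refs$liposome$absorbance +
    0.3 * refs$fluorophore$absorbance +
    rnorm(nrow(raw), 0, 1e-4)
  d <- deconvolute_spectrum(raw, refs)
  expect_lt(abs(d$concentrations[["liposome"]] - 1.5) / 1.5, 0.01)
  expect_lt(abs(d$concentrations[["fluorophore"]] - 0.3) / 0.3, 0.01)

  # oracle: coarse 2-D grid over non-negative scales
  grid <- expand.grid(s1 = seq(1.2, 1.8, by = 0.01),
                      s2 = seq(0.1, 0.5, by = 0.01))
  ss <- apply(grid, 1, function(g)
    sum((g[1] * refs$liposome$absorbance +
         g[2] * refs$fluorophore$absorbance - raw$absorbance)^2))
  expect_lte(d$residual_ss, min(ss) + 1e-12)
})

test_that("nearly collinear references are flagged", {
  r2 <- refs$liposome
  r2$absorbance <- r2$absorbance * (1 + 1e-13)
  expect_warning(
    d <- deconvolute_spectrum(refs$liposome,
                              list(a = refs$liposome, b = r2)),
    "linearly dependent")
  expect_true(d$ill_conditioned)
})

test_that("linear calibration inverts concentrations", {
  x <- seq(0, 200, by = 25)
  cal <- linear_calibration(x, 0.002 * x)
  expect_equal(cal$slope, 0.002)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)

  set.seed(1)
  cal2 <- linear_calibration(x, 0.002 * x + 0.01 + rnorm(length(x), 0, 1e-4))
  expect_lt(abs(cal2$inverse(0.21) - 100), 2)

  expect_error(linear_calibration(rep(5, 4), 1:4), "distinct")
})

test_that("generalized polarization obeys its exact formula and bounds", {
  expect_equal(gp_value(0.5, 0.5), 0)
  expect_equal(gp_value(1, 0), 1)
  expect_equal(gp_value(0.6, 0.4), 0.2)
  expect_error(gp_value(0, 0), "positive")
  # bounded and antisymmetric under channel swap
  set.seed(2)
  i1 <- runif(50, 0.01, 2); i2 <- runif(50, 0.01, 2)
  g <- gp_value(i1, i2)
  expect_true(all(g >= -1 & g <= 1))
  expect_equal(gp_value(i2, i1), -g)
})

test_that("melting midpoint is the extremum of the first differential", {
  temp <- seq(14, 34, by = 0.25)
  gp_clean <- -0.05 + 0.6 / (1 + exp((temp - 24) / 0.8))
  mm <- melting_midpoint(temp, gp_clean)
  expect_lt(abs(mm$tm - 24), 0.05)

  set.seed(8)
  ok <- vapply(1:20, function(i) {
    gp <- gp_clean + rnorm(length(temp), 0, 0.002)
    abs(melting_midpoint(temp, gp)$tm - 24) <= 0.25
  }, logical(1))
  expect_gte(sum(ok), 19)

  # a linear GP trace has no transition
  expect_error(melting_midpoint(temp, 0.5 - 0.01 * temp), "no transition")
  expect_error(melting_midpoint(temp[1:4], gp_clean[1:4]), "at least 5")
})

test_that("folded fraction readouts interpolate and ratio correctly", {
  expect_equal(folded_fraction("gel_monomer", folded = 30, unfolded = 10),
               0.75)
  expect_equal(folded_fraction("trp_ratio", ratio = 1.4, ratio_folded = 1.4,
                               ratio_unfolded = 0.9), 1.0)
  expect_equal(folded_fraction("trp_ratio", ratio = 1.15, ratio_folded = 1.4,
                               ratio_unfolded = 0.9), 0.5)
  expect_error(folded_fraction("trp_ratio", ratio = 1, ratio_folded = 1.1,
                               ratio_unfolded = 1.1), "degenerate")
  expect_error(folded_fraction("gel_monomer", folded = 0, unfolded = 0),
               "zero")
})
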