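test_that("pure references unmix to conversions 0 and 1 with zero residual", {
  pair <- default_pair()
  f0 <- unmix(pair$nucleoside$spectrum, pair, preprocess = FALSE)
  expect_equal(f0$conversion, 0)
  expect_lt(f0$residual_rms, 1e-12)
  f1 <- unmix(pair$nucleobase$spectrum, pair, preprocess = FALSE)
  expect_equal(f1$conversion, 1)
})

test_that("a constructed 30/70 mixture recovers coefficients summing to 1", {
  pair <- default_pair()
  s <- pair$nucleoside$spectrum
  s$absorbance_au <- 0.30 * pair$nucleoside$spectrum$absorbance_au +
    0.70 * pair$nucleobase$spectrum$absorbance_au
  f <- unmix(s, pair, preprocess = FALSE)
  expect_equal(f$conversion, 0.70, tolerance = 1e-12)
  expect_equal(unname(sum(coef(f))), 1, tolerance = 1e-12)
  expect_length(f$flags, 0)
})

test_that("noiseless mixtures are recovered exactly across the conversion range", {
  pair <- default_pair()
  for (x in seq(0, 1, by = 0.1)) {
    s <- simulate_mixture(pair, x, noise_sigma = 0, scale = 0.5)
    expect_equal(unmix(s, pair)$conversion, x, tolerance = 1e-9)
  }
})

test_that("least-squares fit agrees with the grid-search oracle under noise", {
  pair <- default_pair()
  s <- simulate_mixture(pair, 0.55, noise_sigma = 0.002, scale = 0.5, seed = 42)
  f <- unmix(s, pair)
  g <- brute_force_unmix(s, pair, grid_step = 1e-4)
  expect_equal(f$conversion, g$conversion, tolerance = 1e-3)
  # the oracle can do no better than the analytic optimum
  expect_gte(g$residual_rms, f$residual_rms - 1e-12)
})

test_that("fit residual beats random non-negative candidate coefficients", {
  pair <- default_pair()
  s <- simulate_mixture(pair, 0.4, noise_sigma = 0.005, scale = 0.5, seed = 9)
  f <- unmix(s, pair)
  proc <- normalize_to_isosbestic(restrict_to_fit_range(s, pair$fit_range_nm),
                                  278)$spectrum
  rn <- pair$nucleoside$spectrum$absorbance_au[
    pair$nucleoside$spectrum$wavelengths_nm <= 320]
  rb <- pair$nucleobase$spectrum$absorbance_au[
    pair$nucleobase$spectrum$wavelengths_nm <= 320]
  set.seed(1)
  for (i in 1:50) {
    cand <- runif(2, 0, 1.5)
    rms <- sqrt(mean((proc$absorbance_au - cand[1] * rn - cand[2] * rb)^2))
    expect_gte(rms, f$residual_rms)
  }
})

test_that("constrained solve matches an independent NNLS implementation", {
  skip_if_not_installed("pracma")
  pair <- default_pair()
  keep <- pair$nucleoside$spectrum$wavelengths_nm <= 320
  rn <- pair$nucleoside$spectrum$absorbance_au[keep]
  rb <- pair$nucleobase$spectrum$absorbance_au[keep]
  grid <- pair$nucleoside$spectrum$wavelengths_nm[keep]
  set.seed(3)
  for (i in 1:20) {
    # deliberately include infeasible targets that force an active constraint
    a <- runif(1, -0.5, 1.5) * rn + runif(1, -0.5, 1.5) * rb +
      rnorm(length(rn), 0, 0.01)
    f <- unmix(uv_spectrum(grid, a), pair, preprocess = FALSE)
    ref <- pracma::lsqnonneg(cbind(rn, rb), a)$x
    expect_equal(unname(coef(f)), ref, tolerance = 1e-8)
  }
})

test_that("degenerate inputs raise informative errors", {
  pair <- default_pair()
  # near-identical references are indistinguishable
  clone <- pair
  clone$nucleobase$spectrum$absorbance_au <-
    1.0001 * clone$nucleoside$spectrum$absorbance_au
  s <- simulate_mixture(pair, 0.5, noise_sigma = 0, scale = 0.5)
  expect_error(unmix(s, clone), "indistinguishable")
  zero <- uv_spectrum(250:320, rep(0, 71))
  expect_error(unmix(zero, pair, preprocess = FALSE), "all-zero")
})

test_that("swapping the references maps conversion to its complement", {
  pair <- default_pair()
  swapped <- pair
  swapped$nucleoside <- pair$nucleobase
  swapped$nucleobase <- pair$nucleoside
  set.seed(8)
  for (x in runif(20)) {
    s <- simulate_mixture(pair, x, noise_sigma = 0.002, scale = 0.5,
                          seed = round(1e6 * x))
    a <- unmix(s, pair)$conversion
    b <- unmix(s, swapped)$conversion
    expect_equal(b, 1 - a, tolerance = 1e-12)
  }
})

test_that("unmix_series preserves order and propagates per-sample results", {
  pair <- default_pair()
  fits <- unmix_series(list(pair$nucleoside$spectrum,
                            pair$nucleobase$spectrum),
                       pair, preprocess = FALSE)
  expect_equal(vapply(fits, `[[`, 0, "conversion"), c(0, 1))
  xs <- seq(0, 1, by = 0.1)
  fits2 <- unmix_series(lapply(xs, simulate_mixture, pair = pair,
                               noise_sigma = 0, scale = 0.5), pair)
  expect_equal(vapply(fits2, `[[`, 0, "conversion"), xs, tolerance = 1e-9)
  expect_error(unmix_series(list(), pair), "empty")
})

test_that("QC flags fire on poor fits and coefficient-sum anomalies", {
  pair <- default_pair()
  # an unnormalized half-scale sample breaks the coefficient-sum expectation
  s <- simulate_mixture(pair, 0.5, noise_sigma = 0, scale = 0.5)
  f <- unmix(s, pair, preprocess = FALSE)
  expect_true("coef_sum_anomaly" %in% f$flags)
  # heavy uncorrected background spoils the fit
  bg <- generate_background("protein", list(amplitude_au = 0.2))
  dirty <- simulate_mixture(pair, 0.5, noise_sigma = 0, background = bg,
                            scale = 0.5)
  expect_true("poor_fit" %in% unmix(dirty, pair)$flags)
  # clean normalized data never flags
  clean <- simulate_mixture(pair, 0.5, noise_sigma = 0.002, scale = 0.5,
                            seed = 2)
  expect_length(unmix(clean, pair)$flags, 0)
})

test_that("brute-force oracle geometry on a coarse grid", {
  pair <- default_pair()
  s <- simulate_mixture(pair, 0.7, noise_sigma = 0, scale = 0.5)
  coarse <- brute_force_unmix(s, pair, grid_step = 0.5)
  expect_true(coarse$conversion %in% c(0.5, 1.0))
  pure <- brute_force_unmix(pair$nucleobase$spectrum, pair,
                            preprocess = FALSE)
  expect_equal(pure$conversion, 1)
})

test_that("wavelength calibration rejects singular response matrices", {
  pair <- default_pair()
  calib <- wavelength_calibration(pair, c(262, 300))
  expect_equal(dim(calib$response_matrix), c(2L, 2L))
  # the isosbestic point twice: responses proportional by construction
  expect_error(wavelength_calibration(pair, c(278, 278)), "singular")
  expect_error(wavelength_calibration(pair, c(260, 270, 280)), "1 or 2")
})

test_that("two-wavelength mode matches full-spectrum unmixing on clean data", {
  pair <- default_pair()
  calib <- wavelength_calibration(pair, c(262, 300))
  pure <- simulate_mixture(pair, 1, noise_sigma = 0, scale = 0.5)
  expect_equal(unmix_wavelength_mode(pure, calib)$conversion, 1,
               tolerance = 1e-12)
  for (x in c(0.15, 0.5, 0.85)) {
    s <- simulate_mixture(pair, x, noise_sigma = 0, scale = 0.5)
    expect_equal(unmix_wavelength_mode(s, calib)$conversion,
                 unmix(s, pair)$conversion, tolerance = 1e-9)
  }
})

test_that("one-wavelength mode needs the total amount and clips negatives", {
  pair <- default_pair()
  calib1 <- wavelength_calibration(pair, 295)
  s <- simulate_mixture(pair, 0.6, noise_sigma = 0, scale = 0.5)
  expect_error(unmix_wavelength_mode(s, calib1), "total")
  f <- unmix_wavelength_mode(s, calib1, total = 0.5)
  expect_equal(f$conversion, 0.6, tolerance = 1e-9)
  # an inconsistent (too small) total forces a negative solved amount
  f2 <- unmix_wavelength_mode(s, calib1, total = 0.2)
  expect_true("clipped" %in% f2$flags)
  expect_true(all(coef(f2) >= 0))
})

test_that("the optional flat-offset term absorbs a baseline shift", {
  pair <- default_pair()
  s <- simulate_mixture(pair, 0.4, noise_sigma = 0, scale = 0.5)
  proc <- normalize_to_isosbestic(restrict_to_fit_range(s, pair$fit_range_nm),
                                  278)$spectrum
  shifted <- proc
  shifted$absorbance_au <- proc$absorbance_au + 0.05
  f <- unmix(shifted, pair, preprocess = FALSE, offset = TRUE)
  expect_equal(f$offset, 0.05, tolerance = 1e-9)
  expect_equal(f$conversion, 0.4, tolerance = 1e-9)
})
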