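test_that("uv_spectrum enforces grid and absorbance invariants", {
  expect_error(uv_spectrum(300, 0.1), "at least 2")
  expect_error(uv_spectrum(c(260, 255), c(0.1, 0.2)),
               "not strictly increasing")
  expect_error(uv_spectrum(c(250, 250, 251), c(0.1, 0.2, 0.3)),
               "not strictly increasing")
  expect_error(uv_spectrum(250:252, c(0.1, 0.2)), "differ in length")
  expect_error(uv_spectrum(250:252, c(0.1, NA, 0.3)), "finite")
  expect_error(uv_spectrum(250:251, c(0.1, 0.2), dilution_factor = -3),
               "positive")
  # negative absorbance is legitimate after background subtraction
  s <- uv_spectrum(250:251, c(-0.01, 0.2))
  expect_s3_class(s, "uv_spectrum")
})

test_that("spectrum_at interpolates within range and refuses extrapolation", {
  s <- uv_spectrum(c(250, 252, 254), c(0, 1, 0))
  expect_equal(spectrum_at(s, 251), 0.5)
  expect_equal(spectrum_at(s, c(250, 254)), c(0, 0))
  expect_error(spectrum_at(s, 249), "extrapolation refused")
  expect_error(interpolate_spectrum(s, 250:255), "extrapolation refused")
})

test_that("read_spectra_table parses the standard 250-350 nm grid", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(wavelength_nm = 250:350, A1 = runif(101), A2 = runif(101),
                   A3 = runif(101))
  utils::write.csv(df, tmp, row.names = FALSE)
  set <- read_spectra_table(tmp)
  expect_length(set$samples, 3)
  expect_true(all(vapply(set$samples,
                         function(s) length(s$wavelengths_nm), 0L) == 101L))
  expect_equal(set$samples$A2$absorbance_au, df$A2)
})

test_that("read_spectra_table rejects malformed tables with named errors", {
  bad_order <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,A1", "260,0.1", "255,0.2"), bad_order)
  expect_error(read_spectra_table(bad_order), "not strictly increasing")

  bad_cell <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,A1", "250,0.1", "251,oops"), bad_cell)
  expect_error(read_spectra_table(bad_cell), "non-numeric.*A1")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,A,A", "250,0.1,0.2", "251,0.1,0.2"), dup)
  expect_error(read_spectra_table(dup), "duplicate column")

  short <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,A1", "250,0.1"), short)
  expect_error(read_spectra_table(short), "at least 2")

  expect_error(read_spectra_table(withr::local_tempfile()), "not found")
})

test_that("write/read round trip preserves values (property over random sets)", {
  for (seed in 1:5) {
    set.seed(seed)
    n_samp <- sample(1:4, 1)
    grid <- sort(sample(seq(250, 350, by = 0.5), sample(20:101, 1)))
    samples <- lapply(seq_len(n_samp), function(i)
      uv_spectrum(grid, rnorm(length(grid), 0.3, 0.2), label = paste0("s", i)))
    names(samples) <- paste0("s", seq_len(n_samp))
    blanks <- list(plate = uv_spectrum(grid, runif(length(grid), 0, 0.05)))
    set <- plate_spectra_set(samples, blanks)
    tmp <- withr::local_tempfile(fileext = ".csv")
    write_spectra_table(set, tmp)
    back <- read_spectra_table(tmp)
    expect_equal(names(back$samples), names(set$samples))
    for (nm in names(samples)) {
      expect_equal(back$samples[[nm]]$wavelengths_nm, grid, tolerance = 1e-12)
      expect_equal(back$samples[[nm]]$absorbance_au,
                   samples[[nm]]$absorbance_au, tolerance = 1e-12)
    }
    expect_equal(back$blanks$plate$absorbance_au,
                 blanks$plate$absorbance_au, tolerance = 1e-12)
  }
})

test_that("write_spectra_table output has header plus one line per wavelength", {
  s <- uv_spectrum(250:350, runif(101), label = "only")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_spectra_table(s, tmp)
  expect_length(readLines(tmp), 102L)
  expect_error(write_spectra_table(plate_spectra_set(list()), tmp),
               "at least one sample")
})

test_that("plate_spectra_set enforces shared grids and blank vocabulary", {
  a <- uv_spectrum(250:350, runif(101))
  b <- uv_spectrum(250:349, runif(100))
  expect_error(plate_spectra_set(list(s1 = a, s2 = b)), "share one wavelength grid")
  expect_error(plate_spectra_set(list(s1 = a), list(gunk = a)),
               "unknown blank kind")
})

test_that("reference library round-trips and validates Table-1-style metadata", {
  pair <- default_pair()
  dir <- write_pair_library(pair)
  lib <- load_reference_library(dir)
  expect_named(lib, c("syn-nucleobase", "syn-nucleoside"), ignore.order = TRUE)
  ns <- lib[["syn-nucleoside"]]
  expect_equal(ns$role, "nucleoside")
  expect_equal(ns$lambda_max_nm, 266)
  expect_equal(ns$isosbestic_points_nm, 278)
  expect_equal(ns$spectral_extension_nm, 320)
})

test_that("library loading errors name the compound and missing field", {
  dir <- withr::local_tempdir()
  utils::write.csv(data.frame(wavelength_nm = 250:350, absorbance_au = runif(101)),
                   file.path(dir, "thing.csv"), row.names = FALSE)
  yaml::write_yaml(list(compound_id = "thing", role = "nucleoside",
                        ph_condition = "pH 13", lambda_max_nm = 266,
                        isosbestic_points_nm = list(278)),
                   file.path(dir, "thing.yaml"))
  expect_error(load_reference_library(dir),
               "thing.*missing field.*spectral_extension_nm")
})

test_that("isosbestic point outside the recorded grid is rejected", {
  dir <- withr::local_tempdir()
  utils::write.csv(data.frame(wavelength_nm = 280:350, absorbance_au = runif(71)),
                   file.path(dir, "late.csv"), row.names = FALSE)
  yaml::write_yaml(list(compound_id = "late", role = "nucleoside",
                        ph_condition = "pH 13", lambda_max_nm = 290,
                        isosbestic_points_nm = list(278),
                        spectral_extension_nm = 340),
                   file.path(dir, "late.yaml"))
  expect_error(load_reference_library(dir), "278.*outside")
})

test_that("entries with two isosbestic points retain both", {
  # 5-ethynyluridine-like: isosbestic points at 262 and 288 nm
  sc <- synthetic_scenario()
  pair <- generate_reference_pair(sc)
  dir <- withr::local_tempdir()
  for (m in list(pair$nucleoside, pair$nucleobase)) {
    m$isosbestic_points_nm <- c(262, 288)
    m$spectrum$absorbance_au <- m$spectrum$absorbance_au / m$norm_scale
    m$normalized <- FALSE; m$norm_scale <- NULL
    write_reference_spectrum(m, dir)
  }
  lib <- load_reference_library(dir)
  expect_equal(lib[["syn-nucleoside"]]$isosbestic_points_nm, c(262, 288))
})

test_that("build_reference_pair selects the isosbestic point and fit range", {
  pair <- default_pair()
  expect_equal(pair$active_isosbestic_nm, 278)
  expect_equal(pair$fit_range_nm, c(250, 320))
  expect_false(pair$wavelength_mode_only)
  # both normalized members are exactly 1 at the isosbestic point
  expect_equal(spectrum_at(pair$nucleoside$spectrum, 278), 1, tolerance = 1e-12)
  expect_equal(spectrum_at(pair$nucleobase$spectrum, 278), 1, tolerance = 1e-12)
})

test_that("two isosbestic points: default is the higher-signal one, override wins", {
  grid <- 250:350
  mk <- function(role, id) {
    a <- 0.7 * exp(-(grid - if (role == "nucleoside") 285 else 298)^2 / 260)
    reference_spectrum(uv_spectrum(grid, a, label = id), compound_id = id,
                       role = role, ph_condition = "200 mM NaOH, pH 13.3",
                       lambda_max_nm = if (role == "nucleoside") 285 else 298,
                       isosbestic_points_nm = c(262, 288),
                       spectral_extension_nm = 340)
  }
  ns <- mk("nucleoside", "eu"); nb <- mk("nucleobase", "eu-base")
  auto <- build_reference_pair(ns, nb)
  # both spectra are far stronger at 288 than at 262
  expect_equal(auto$active_isosbestic_nm, 288)
  over <- build_reference_pair(ns, nb, isosbestic = 262)
  expect_equal(over$active_isosbestic_nm, 262)
  expect_error(build_reference_pair(ns, nb, isosbestic = 270),
               "not listed in the metadata")
})

test_that("pairs without an isosbestic point are flagged wavelength-mode only", {
  grid <- 250:350
  mk <- function(role, id, ctr)
    reference_spectrum(uv_spectrum(grid, exp(-(grid - ctr)^2 / 180), label = id),
                       compound_id = id, role = role,
                       ph_condition = "100 mM NaOH, pH 13",
                       lambda_max_nm = max(250, ctr),
                       isosbestic_points_nm = numeric(0),
                       spectral_extension_nm = 310)
  pair <- build_reference_pair(mk("nucleoside", "riba", 252),
                               mk("nucleobase", "riba-base", 264))
  expect_true(pair$wavelength_mode_only)
  expect_null(pair$active_isosbestic_nm)
  expect_false(pair$nucleoside$normalized)
})

test_that("pair construction rejects mismatched conditions and grids", {
  pair <- default_pair()
  raw <- function(m) {
    m$spectrum$absorbance_au <- m$spectrum$absorbance_au / m$norm_scale
    m$normalized <- FALSE; m$norm_scale <- NULL
    m
  }
  ns <- raw(pair$nucleoside); nb <- raw(pair$nucleobase)
  nb2 <- nb; nb2$ph_condition <- "500 mM NaOH, pH 13.7"
  expect_error(build_reference_pair(ns, nb2), "different pH conditions")
  expect_error(build_reference_pair(nb, ns), "nucleoside and a nucleobase")
  nb3 <- nb
  nb3$spectrum <- uv_spectrum(400:500, rep(0.1, 101))
  nb3$lambda_max_nm <- 450; nb3$isosbestic_points_nm <- 450
  nb3$spectral_extension_nm <- 460
  expect_error(build_reference_pair(ns, nb3), "do not overlap")
})
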