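#' Assemble a run configuration
#'
#' All thresholds of the analysis pipeline in one validated object. Any
#' field can come from a YAML config file ([read_run_config()]) or be set
#' directly; command-line flags of the bundled CLI script map onto these
#' keys one-to-one.
#'
#' @param spectra Path to the sample spectra CSV (dialect of
#'   [read_spectra_table()]).
#' @param reference_library Path to the reference library directory.
#' @param out_dir Output directory for results, plots and the run log.
#' @param nucleoside_id,nucleobase_id Compound ids selecting the pair from
#'   the library.
#' @param isosbestic Optional isosbestic override (nm).
#' @param fit_range Optional fitting range override, length-2 numeric (nm).
#' @param mode `"isosbestic"` (full-spectrum unmixing, default) or
#'   `"wavelength"` (fallback for pairs without an isosbestic point; uses
#'   `wavelengths`).
#' @param wavelengths Wavelengths for wavelength mode (1 or 2 values, nm).
#' @param baseline_threshold Baseline-shift flag threshold (AU, default
#'   0.10).
#' @param snr_threshold Signal-to-background pass threshold (default 5).
#' @param noise_floor Normalization noise floor (AU, default 0.05).
#' @param residual_tol,coef_sum_tol Fit QC thresholds (see [unmix()]).
#' @param isosbestic_drift_tol Warn tolerance for
#'   [check_isosbestic_constancy()] (default 0.10).
#' @param equilibrium_window,equilibrium_slope_tol Plateau-detection
#'   parameters (see [detect_equilibrium()]).
#' @param total Known total amount for one-wavelength mode.
#' @param seed Integer seed recorded in the provenance block.
#' @return An object of class `run_config`.
#' @export
run_config <- function(spectra, reference_library, out_dir,
                       nucleoside_id, nucleobase_id,
                       isosbestic = NULL, fit_range = NULL,
                       mode = c("isosbestic", "wavelength"),
                       wavelengths = NULL,
                       baseline_threshold = 0.10, snr_threshold = 5,
                       noise_floor = 0.05, residual_tol = 0.01,
                       coef_sum_tol = 0.10, isosbestic_drift_tol = 0.10,
                       equilibrium_window = 5, equilibrium_slope_tol = 1e-4,
                       total = NULL, seed = 1L) {
  mode <- match.arg(mode)
  thresholds <- c(baseline_threshold = baseline_threshold,
                  snr_threshold = snr_threshold, noise_floor = noise_floor,
                  residual_tol = residual_tol, coef_sum_tol = coef_sum_tol,
                  isosbestic_drift_tol = isosbestic_drift_tol,
                  equilibrium_slope_tol = equilibrium_slope_tol)
  if (any(thresholds <= 0))
    stop("all thresholds must be positive; offending: ",
         paste(names(thresholds)[thresholds <= 0], collapse = ", "),
         call. = FALSE)
  structure(
    list(spectra = spectra, reference_library = reference_library,
         out_dir = out_dir, nucleoside_id = nucleoside_id,
         nucleobase_id = nucleobase_id, isosbestic = isosbestic,
         fit_range = fit_range, mode = mode, wavelengths = wavelengths,
         baseline_threshold = baseline_threshold,
         snr_threshold = snr_threshold, noise_floor = noise_floor,
         residual_tol = residual_tol, coef_sum_tol = coef_sum_tol,
         isosbestic_drift_tol = isosbestic_drift_tol,
         equilibrium_window = equilibrium_window,
         equilibrium_slope_tol = equilibrium_slope_tol,
         total = total, seed = as.integer(seed)),
    class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @param ... Overrides applied on top of the file's values (CLI flags).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  dots <- list(...)
  cfg[names(dots)] <- dots
  allowed <- names(formals(run_config))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(run_config, cfg)
}

#' Run the full unmixing pipeline
#'
#' Executes preprocess, unmix and monitor on a spectra file against a
#' reference library, and writes results (CSV + JSON with provenance), a
#' two-panel plot (conversion vs. time and the raw isosbestic trace) and a
#' run log into the output directory. QC flags are warnings carried in the
#' outputs; they never abort a run — the decision to remeasure a flagged
#' sample is the experimenter's.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with `series` (the `conversion_series`),
#'   `fits`, `reports`, and `files` (paths written).
#' @export
run_unmix <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    message(msg)
  }
  logf("uvmix run started %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"))

  lib <- load_reference_library(config$reference_library)
  for (id in c(config$nucleoside_id, config$nucleobase_id))
    if (is.null(lib[[id]]))
      stop("reference '", id, "' not found in library; available: ",
           paste(names(lib), collapse = ", "), call. = FALSE)
  pair <- build_reference_pair(lib[[config$nucleoside_id]],
                               lib[[config$nucleobase_id]],
                               isosbestic = config$isosbestic,
                               fit_range = config$fit_range)
  if (config$mode == "isosbestic" && pair$wavelength_mode_only)
    stop("pair ", config$nucleoside_id, "/", config$nucleobase_id,
         " has no isosbestic point of base cleavage; re-run with mode = \"wavelength\"",
         call. = FALSE)
  logf("pair: %s / %s, isosbestic %s, fit range %g-%g nm",
       config$nucleoside_id, config$nucleobase_id,
       if (is.null(pair$active_isosbestic_nm)) "none"
       else paste0(pair$active_isosbestic_nm, " nm"),
       pair$fit_range_nm[1L], pair$fit_range_nm[2L])

  set <- read_spectra_table(config$spectra)
  logf("loaded %d sample(s), %d blank(s)", length(set$samples),
       length(set$blanks))

  fits <- list()
  reports <- list()
  extra_flags <- list()
  for (nm in names(set$samples)) {
    s <- set$samples[[nm]]
    if (config$mode == "wavelength") {
      if (is.null(config$wavelengths))
        stop("wavelength mode requires `wavelengths` in the config",
             call. = FALSE)
      for (kind in names(set$blanks))
        s <- subtract_background(s, set$blanks[[kind]], kind = kind)
      calib <- wavelength_calibration(pair, config$wavelengths)
      fit <- unmix_wavelength_mode(s, calib, total = config$total)
      pp <- list(report = NULL, flags = character(0))
    } else {
      pp <- preprocess_spectrum(
        s, pair, blanks = set$blanks,
        baseline_threshold = config$baseline_threshold,
        noise_floor = config$noise_floor, fit_range = config$fit_range)
      fit <- unmix(pp$spectrum, pair, preprocess = FALSE,
                   residual_tol = config$residual_tol,
                   coef_sum_tol = config$coef_sum_tol)
      if (length(set$blanks)) {
        snr <- signal_to_background(
          pp$spectrum, set$blanks[[1L]],
          range_nm = pair$fit_range_nm, threshold = config$snr_threshold)
        if (!snr$pass) pp$flags <- c(pp$flags, "low_snr")
      }
    }
    fit$label <- nm
    fit$time_s <- s$time_s
    fits[[nm]] <- fit
    reports[[nm]] <- pp$report
    extra_flags[[nm]] <- pp$flags
    logf("  %s: conversion %.4f, residual %.3g%s", nm, fit$conversion,
         fit$residual_rms,
         if (length(c(fit$flags, pp$flags)))
           paste0(" [", paste(unique(c(fit$flags, pp$flags)), collapse = ","), "]")
         else "")
  }

  # assemble a time series when times are available
  times <- vapply(names(set$samples), function(nm) {
    t <- set$samples[[nm]]$time_s
    if (is.null(t)) parse_time_label(nm) else t
  }, 0)
  series <- NULL
  iso_trace <- NULL
  if (!anyNA(times) && length(fits) >= 2L) {
    series <- build_conversion_series(fits, times_s = times,
                                      extra_flags = extra_flags)
    if (sum(lengths(series$flags) == 0) >= config$equilibrium_window)
      series <- detect_equilibrium(series,
                                   window = config$equilibrium_window,
                                   slope_tol = config$equilibrium_slope_tol)
    if (!is.null(pair$active_isosbestic_nm)) {
      corrected <- lapply(set$samples, function(s) {
        for (kind in names(set$blanks))
          s <- subtract_background(s, set$blanks[[kind]], kind = kind)
        s
      })
      iso <- check_isosbestic_constancy(corrected, pair$active_isosbestic_nm,
                                        tol = config$isosbestic_drift_tol)
      iso_trace <- iso$iso_au[order(times)]
      if (iso$warn)
        logf("WARNING: isosbestic drift %.3f exceeds tolerance %.3f",
             iso$deviation, config$isosbestic_drift_tol)
    }
  }

  files <- write_unmix_results(fits, reports, extra_flags, series, iso_trace,
                               pair, config)
  logf("results written to %s", config$out_dir)
  invisible(list(series = series, fits = fits, reports = reports,
                 files = files))
}

# labels like "t000120" carry the sampling time in seconds
parse_time_label <- function(label) {
  m <- regmatches(label, regexpr("^t([0-9]+)$", label))
  if (length(m)) as.numeric(sub("^t", "", m)) else NA_real_
}

#' Serialize unmixing results
#'
#' Writes `results.csv` (one row per sample: label, time, conversion,
#' coefficients, residual, flags), `results.json` (the same plus full
#' provenance: config, thresholds, pair, reference-file hashes, seed) and,
#' when a series exists, `series.csv` and `conversion_plot.pdf`.
#'
#' @param fits Named list of `unmix_fit` objects.
#' @param reports,extra_flags Per-sample preprocess outputs (may be `NULL`).
#' @param series Optional `conversion_series`.
#' @param iso_trace Optional raw isosbestic absorbance trace (plot panel 2).
#' @param pair The `reference_pair` used.
#' @param config The `run_config`.
#' @return Character vector of written file paths, invisibly.
#' @export
write_unmix_results <- function(fits, reports, extra_flags, series,
                                iso_trace, pair, config) {
  out <- config$out_dir
  df <- data.frame(
    label = names(fits),
    time_s = vapply(fits, function(f)
      if (is.null(f$time_s)) NA_real_ else f$time_s, 0),
    conversion = vapply(fits, `[[`, 0, "conversion"),
    coeff_nucleoside = vapply(fits, function(f) f$coefficients[[1L]], 0),
    coeff_nucleobase = vapply(fits, function(f) f$coefficients[[2L]], 0),
    residual_rms = vapply(fits, `[[`, 0, "residual_rms"),
    flags = vapply(seq_along(fits), function(i)
      paste(unique(c(fits[[i]]$flags,
                     if (!is.null(extra_flags)) extra_flags[[i]]
                     else character(0))), collapse = ";"), ""),
    row.names = NULL)
  csv_path <- file.path(out, "results.csv")
  utils::write.csv(df, csv_path, row.names = FALSE)

  lib_files <- list.files(config$reference_library, full.names = TRUE)
  provenance <- list(
    config = unclass(config),
    pair = list(nucleoside = pair$nucleoside$compound_id,
                nucleobase = pair$nucleobase$compound_id,
                active_isosbestic_nm = pair$active_isosbestic_nm,
                fit_range_nm = pair$fit_range_nm,
                wavelength_mode_only = pair$wavelength_mode_only),
    reference_hashes = as.list(stats::setNames(
      vapply(lib_files, function(f) unname(tools::md5sum(f)), ""),
      basename(lib_files))),
    package_version = as.character(utils::packageVersion("uvmix")))
  json_path <- file.path(out, "results.json")
  jsonlite::write_json(list(results = df, provenance = provenance),
                       json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  files <- c(csv_path, json_path)

  if (!is.null(series)) {
    series_path <- file.path(out, "series.csv")
    sdf <- as.data.frame(series)
    if (!is.null(series$equilibrium_conversion)) {
      sdf$equilibrium_conversion <- series$equilibrium_conversion
      sdf$time_to_equilibrium_s <- series$time_to_equilibrium_s
    }
    utils::write.csv(sdf, series_path, row.names = FALSE)
    plot_path <- file.path(out, "conversion_plot.pdf")
    grDevices::pdf(plot_path, width = 9, height = 4.5)
    plot(series, raw_iso_au = iso_trace)
    grDevices::dev.off()
    files <- c(files, series_path, plot_path)
  }
  invisible(files)
}

#' Validate every compound in a reference library
#'
#' Checks each metadata record and spectrum against the reference-spectrum
#' invariants (required fields present; absorption maximum and every listed
#' isosbestic point inside the wavelength range; spectral extension not
#' below the absorption maximum). For compounds whose partner is present,
#' the declared isosbestic point is compared against the actual crossing of
#' the two spectra (located by a sign-change scan); a discrepancy beyond
#' 2 nm yields a warning entry.
#'
#' @param path Reference-library directory.
#' @return A data frame (class `library_report`) with columns `compound`,
#'   `status` (`"pass"`, `"warn"` or `"fail"`) and `detail`.
#' @export
run_validate_library <- function(path) {
  if (!dir.exists(path))
    stop("reference library directory not found: ", path, call. = FALSE)
  metas <- list.files(path, pattern = "\\.ya?ml$", full.names = TRUE)
  if (!length(metas))
    stop("no metadata sidecars (*.yaml) in ", path, call. = FALSE)
  rows <- list()
  refs <- list()
  for (mf in metas) {
    id <- basename(tools::file_path_sans_ext(mf))
    res <- tryCatch({
      lib1 <- load_single_reference(mf)
      refs[[lib1$compound_id]] <- lib1
      c(lib1$compound_id, "pass", "")
    }, error = function(e) c(id, "fail", conditionMessage(e)))
    rows[[length(rows) + 1L]] <- res
  }
  # cross-check declared isosbestic points against actual crossings
  roles <- vapply(refs, `[[`, "", "role")
  for (ns in refs[roles == "nucleoside"]) {
    for (nb in refs[roles == "nucleobase"]) {
      common <- intersect(ns$isosbestic_points_nm, nb$isosbestic_points_nm)
      if (!length(common) ||
          !identical(ns$ph_condition, nb$ph_condition)) next
      for (iso in common) {
        actual <- locate_crossing(ns$spectrum, nb$spectrum, near = iso)
        if (is.na(actual) || abs(actual - iso) > 2)
          rows[[length(rows) + 1L]] <- c(
            paste0(ns$compound_id, "/", nb$compound_id), "warn",
            sprintf("declared isosbestic %g nm vs actual crossing %s",
                    iso, if (is.na(actual)) "none found"
                         else sprintf("%.1f nm", actual)))
      }
    }
  }
  report <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(report) <- c("compound", "status", "detail")
  class(report) <- c("library_report", class(report))
  report
}

load_single_reference <- function(meta_file) {
  d <- tempfile()
  dir.create(d)
  on.exit(unlink(d, recursive = TRUE))
  base <- tools::file_path_sans_ext(meta_file)
  file.copy(meta_file, d)
  if (file.exists(paste0(base, ".csv"))) file.copy(paste0(base, ".csv"), d)
  load_reference_library(d)[[1L]]
}

# first sign change of (scaled) difference between two spectra near `near`;
# each spectrum is scaled to unit maximum so raw-intensity differences
# don't masquerade as crossings
locate_crossing <- function(a, b, near = NULL) {
  grid <- a$wavelengths_nm
  if (!same_grid(a, b)) b <- interpolate_spectrum(b, grid)
  d <- a$absorbance_au / max(a$absorbance_au) -
       b$absorbance_au / max(b$absorbance_au)
  sgn <- which(d[-1L] * d[-length(d)] <= 0 & d[-1L] != d[-length(d)])
  if (!length(sgn)) return(NA_real_)
  # linear interpolation of each zero; pick the crossing closest to `near`
  zeros <- vapply(sgn, function(i) {
    grid[i] + d[i] * (grid[i + 1L] - grid[i]) / (d[i] - d[i + 1L])
  }, 0)
  if (is.null(near)) zeros[1L] else zeros[which.min(abs(zeros - near))]
}

#' @export
print.library_report <- function(x, ...) {
  cat(sprintf("<library_report> %d entr%s: %d pass, %d warn, %d fail\n",
              nrow(x), if (nrow(x) == 1) "y" else "ies",
              sum(x$status == "pass"), sum(x$status == "warn"),
              sum(x$status == "fail")))
  print.data.frame(x)
  invisible(x)
}
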