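#' Subtract a blank (background) spectrum from a sample
#'
#' Pointwise subtraction after interpolating the blank onto the sample grid
#' where needed. Reference spectra are never re-corrected: they were already
#' blank-corrected when recorded. The applied blank kind is recorded in the
#' sample's `corrections` metadata.
#'
#' @param sample A `uv_spectrum`.
#' @param blank A `uv_spectrum` covering the sample's wavelength range.
#' @param kind Blank kind label recorded in the metadata
#'   (`"plate"`, `"shift"`, `"protein"`, `"solvent"` or `"buffer"`).
#' @return The corrected `uv_spectrum`.
#' @export
subtract_background <- function(sample, blank, kind = "plate") {
  stopifnot(inherits(sample, "uv_spectrum"), inherits(blank, "uv_spectrum"))
  if (!same_grid(sample, blank))
    blank <- interpolate_spectrum(blank, sample$wavelengths_nm)
  out <- sample
  out$absorbance_au <- sample$absorbance_au - blank$absorbance_au
  out$corrections <- c(sample$corrections, paste0("blank:", kind))
  out
}

#' Estimate the flat baseline offset of a sample
#'
#' Beyond the pair's spectral extension neither analyte absorbs, so any
#' remaining signal there is background. The offset is the mean absorbance
#' over the analyte-free window from spectral extension + `pad` nm to the
#' end of the grid (inclusive).
#'
#' @param sample A `uv_spectrum` whose grid extends beyond the pair's
#'   spectral extension.
#' @param pair A `reference_pair` (its smaller spectral extension is used).
#' @param pad Guard band (nm) past the spectral extension excluded from the
#'   window; default 5.
#' @return Baseline offset in AU.
#' @export
estimate_baseline_offset <- function(sample, pair, pad = 5) {
  stopifnot(inherits(sample, "uv_spectrum"), inherits(pair, "reference_pair"))
  ext <- min(pair$nucleoside$spectral_extension_nm,
             pair$nucleobase$spectral_extension_nm)
  keep <- sample$wavelengths_nm >= ext + pad
  if (sum(keep) < 5L)
    stop("cannot estimate baseline: analyte-free window beyond ",
         ext + pad, " nm has fewer than 5 points", call. = FALSE)
  mean(sample$absorbance_au[keep])
}

#' Flag a baseline-shifted sample
#'
#' A distinct flat elevation of the whole spectrum (well or particle
#' artifact) precludes an accurate fit; such samples are flagged and by
#' default excluded from series — the remedy is remeasurement in a different
#' well, not spectral massaging. The comparison is strict: an offset exactly
#' at the threshold does not flag.
#'
#' @param offset Baseline offset (AU), e.g. from
#'   [estimate_baseline_offset()].
#' @param threshold Flag threshold in AU (default 0.10).
#' @return `TRUE` iff `offset > threshold`.
#' @export
flag_baseline_shift <- function(offset, threshold = 0.10) {
  stopifnot(is.numeric(offset), is.numeric(threshold))
  offset > threshold
}

#' Normalize a spectrum to the isosbestic point
#'
#' Divides the whole spectrum by its absorbance at the isosbestic wavelength,
#' so the output has absorbance exactly 1 there. Because nucleoside and
#' nucleobase share an extinction coefficient at this wavelength, the total
#' absorbance there is proportional only to the sampled amount — dividing by
#' it removes pipetting-volume and dilution differences. Refused when the
#' isosbestic absorbance is at or below the noise floor, where the rescaling
#' would amplify noise into large relative errors.
#'
#' @param sample A `uv_spectrum` (background-corrected).
#' @param iso_nm Isosbestic wavelength (nm), on or interpolable within the
#'   grid.
#' @param floor Noise floor in AU (default 0.05); `A(iso)` must exceed it.
#' @return A list with elements `spectrum` (normalized `uv_spectrum`) and
#'   `scale` (`1 / A(iso)`).
#' @export
normalize_to_isosbestic <- function(sample, iso_nm, floor = 0.05) {
  stopifnot(inherits(sample, "uv_spectrum"))
  a_iso <- spectrum_at(sample, iso_nm)
  if (a_iso <= floor)
    stop(sprintf("isosbestic signal below noise floor (A(%g nm) = %.4g <= %.3g AU); consider re-sampling with a smaller dilution",
                 iso_nm, a_iso, floor), call. = FALSE)
  out <- sample
  out$absorbance_au <- sample$absorbance_au / a_iso
  out$corrections <- c(sample$corrections, sprintf("normalized@%gnm", iso_nm))
  list(spectrum = out, scale = 1 / a_iso)
}

#' Restrict a spectrum to a fitting range
#'
#' Fitting can be limited to an information-rich window — e.g. the 265-295 nm
#' tail region for uridine — to exclude wavelengths dominated by solvent or
#' other background.
#'
#' @param sample A `uv_spectrum`.
#' @param range_nm Length-2 numeric interval (nm), closed.
#' @return The subset `uv_spectrum`.
#' @export
restrict_to_fit_range <- function(sample, range_nm) {
  stopifnot(inherits(sample, "uv_spectrum"), length(range_nm) == 2L)
  range_nm <- sort(as.numeric(range_nm))
  keep <- sample$wavelengths_nm >= range_nm[1L] - 1e-9 &
          sample$wavelengths_nm <= range_nm[2L] + 1e-9
  if (sum(keep) < 2L)
    stop(sprintf("fit range [%g, %g] nm selects fewer than 2 grid points",
                 range_nm[1L], range_nm[2L]), call. = FALSE)
  out <- sample
  out$wavelengths_nm <- sample$wavelengths_nm[keep]
  out$absorbance_au <- sample$absorbance_au[keep]
  out
}

#' Signal-to-background ratio over a wavelength range
#'
#' The unmixing method is recommended only while background absorption stays
#' below 20 % of the analyte signal, i.e. while this ratio exceeds 5:
#' background signals are absolute quantities sensitive to pipetting, whereas
#' the analyte signal is normalized away, so a large background degrades fit
#' accuracy disproportionately.
#'
#' @param sample Analyte (background-corrected) `uv_spectrum`.
#' @param background Background `uv_spectrum` on a grid covering `range_nm`.
#' @param range_nm Length-2 wavelength interval over which peaks are
#'   compared; defaults to the sample's full range.
#' @param threshold Pass threshold on the ratio (default 5).
#' @return A list with `ratio` (max |signal| / max |background|, `Inf` when
#'   the background is identically zero) and `pass` (`ratio > threshold`...
#'   `TRUE` for infinite ratio).
#' @export
signal_to_background <- function(sample, background, range_nm = NULL,
                                 threshold = 5) {
  stopifnot(inherits(sample, "uv_spectrum"), inherits(background, "uv_spectrum"))
  if (is.null(range_nm)) range_nm <- range(sample$wavelengths_nm)
  s <- restrict_to_fit_range(sample, range_nm)
  if (!same_grid(sample, background))
    background <- interpolate_spectrum(background, sample$wavelengths_nm)
  b <- restrict_to_fit_range(background, range_nm)
  bmax <- max(abs(b$absorbance_au))
  ratio <- if (bmax == 0) Inf else max(abs(s$absorbance_au)) / bmax
  list(ratio = ratio, pass = is.infinite(ratio) || ratio > threshold)
}

#' Preprocess a sample spectrum for unmixing
#'
#' Applies the full correction pipeline in fixed order: subtract blanks,
#' estimate and flag the baseline offset, restrict to the fitting range,
#' normalize to the isosbestic point. Normalization must come last so that it
#' sees background-free absorbance at the isosbestic wavelength.
#'
#' @param sample A raw `uv_spectrum`.
#' @param pair A `reference_pair`.
#' @param blanks Named list of blank `uv_spectrum`s (names are blank kinds);
#'   subtracted in the order given.
#' @param baseline_threshold Baseline flag threshold in AU (default 0.10).
#' @param noise_floor Normalization noise floor in AU (default 0.05).
#' @param fit_range Optional fitting-range override (nm); default the pair's.
#' @return A list with `spectrum` (processed), `report` (a `preprocess_report`
#'   with fields `baseline_offset_au`, `baseline_flag`, `applied_blanks`,
#'   `normalization_scale`) and `flags` (character vector, e.g.
#'   `"baseline_shift"`).
#' @export
preprocess_spectrum <- function(sample, pair, blanks = list(),
                                baseline_threshold = 0.10,
                                noise_floor = 0.05,
                                fit_range = NULL) {
  stopifnot(inherits(sample, "uv_spectrum"), inherits(pair, "reference_pair"))
  s <- sample
  for (kind in names(blanks))
    s <- subtract_background(s, blanks[[kind]], kind = kind)

  ext <- min(pair$nucleoside$spectral_extension_nm,
             pair$nucleobase$spectral_extension_nm)
  offset <- if (max(s$wavelengths_nm) > ext + 5)
    estimate_baseline_offset(s, pair) else NA_real_
  flag <- !is.na(offset) && flag_baseline_shift(offset, baseline_threshold)

  if (is.null(fit_range)) fit_range <- pair$fit_range_nm
  s <- restrict_to_fit_range(s, fit_range)

  scale <- NULL
  if (!pair$wavelength_mode_only) {
    n <- normalize_to_isosbestic(s, pair$active_isosbestic_nm,
                                 floor = noise_floor)
    s <- n$spectrum
    scale <- n$scale
  }
  report <- structure(
    list(baseline_offset_au = offset, baseline_flag = flag,
         applied_blanks = names(blanks),
         normalization_scale = scale),
    class = "preprocess_report")
  list(spectrum = s, report = report,
       flags = if (flag) "baseline_shift" else character(0))
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("<preprocess_report>\n")
  cat(sprintf("  baseline offset: %s AU%s\n",
              if (is.na(x$baseline_offset_au)) "n/a"
              else sprintf("%.4f", x$baseline_offset_au),
              if (isTRUE(x$baseline_flag)) "  ** FLAGGED **" else ""))
  cat("  blanks applied:",
      if (length(x$applied_blanks)) paste(x$applied_blanks, collapse = ", ")
      else "none", "\n")
  if (!is.null(x$normalization_scale))
    cat(sprintf("  normalization scale: %.4g\n", x$normalization_scale))
  invisible(x)
}
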