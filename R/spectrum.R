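#' Construct a UV absorption spectrum
#'
#' A `uv_spectrum` holds absorbance (AU) on a strictly increasing wavelength
#' grid (nm), plus acquisition metadata. Negative absorbance values are
#' permitted (they arise legitimately after background subtraction).
#'
#' @param wavelengths_nm Numeric vector of wavelengths in nm, strictly
#'   increasing, length >= 2.
#' @param absorbance_au Numeric vector of absorbance values (AU), same length
#'   as `wavelengths_nm`, all finite.
#' @param label Free-text sample identifier.
#' @param well Optional plate well id (e.g. `"B4"`).
#' @param time_s Optional sampling time in seconds.
#' @param dilution_factor Optional positive dilution factor.
#'
#' @return An object of class `uv_spectrum`.
#' @examples
#' s <- uv_spectrum(250:350, exp(-((250:350) - 266)^2 / 200), label = "demo")
#' print(s)
#' @export
uv_spectrum <- function(wavelengths_nm, absorbance_au, label = "",
                        well = NULL, time_s = NULL, dilution_factor = NULL) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  absorbance_au <- as.numeric(absorbance_au)
  if (length(wavelengths_nm) < 2L)
    stop("a spectrum needs at least 2 wavelength points", call. = FALSE)
  if (length(wavelengths_nm) != length(absorbance_au))
    stop("wavelengths and absorbance values differ in length", call. = FALSE)
  if (anyNA(wavelengths_nm) || any(!is.finite(wavelengths_nm)))
    stop("wavelengths must be finite", call. = FALSE)
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelengths not strictly increasing", call. = FALSE)
  if (anyNA(absorbance_au) || any(!is.finite(absorbance_au)))
    stop("absorbance values must be finite", call. = FALSE)
  if (!is.null(dilution_factor)) {
    dilution_factor <- as.numeric(dilution_factor)
    if (length(dilution_factor) != 1L || !is.finite(dilution_factor) ||
        dilution_factor <= 0)
      stop("dilution_factor must be a positive scalar", call. = FALSE)
  }
  structure(
    list(wavelengths_nm = wavelengths_nm,
         absorbance_au = absorbance_au,
         label = as.character(label)[1L],
         well = if (is.null(well)) NULL else as.character(well)[1L],
         time_s = if (is.null(time_s)) NULL else as.numeric(time_s)[1L],
         dilution_factor = dilution_factor,
         corrections = character(0)),
    class = "uv_spectrum")
}

#' @export
print.uv_spectrum <- function(x, ...) {
  rng <- range(x$wavelengths_nm)
  cat(sprintf("<uv_spectrum> %s: %d points, %g-%g nm, A in [%.4g, %.4g]\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$wavelengths_nm), rng[1L], rng[2L],
              min(x$absorbance_au), max(x$absorbance_au)))
  if (!is.null(x$time_s)) cat(sprintf("  time_s: %g\n", x$time_s))
  if (length(x$corrections))
    cat("  corrections:", paste(x$corrections, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.uv_spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelengths_nm, absorbance_au = x$absorbance_au)
}

#' @export
plot.uv_spectrum <- function(x, ...,
                             xlab = "Wavelength [nm]", ylab = "Absorbance [AU]",
                             type = "l") {
  graphics::plot(x$wavelengths_nm, x$absorbance_au, type = type,
                 xlab = xlab, ylab = ylab,
                 main = if (nzchar(x$label)) x$label else NULL, ...)
  invisible(x)
}

#' Absorbance at arbitrary wavelengths
#'
#' Linear interpolation within the spectrum's wavelength range. Extrapolation
#' is refused: at 1 nm spacing spectra are smooth enough for interpolation,
#' but values outside the recorded range would be invented data.
#'
#' @param spectrum A `uv_spectrum`.
#' @param at Numeric vector of query wavelengths (nm).
#' @return Numeric vector of absorbance values.
#' @export
spectrum_at <- function(spectrum, at) {
  stopifnot(inherits(spectrum, "uv_spectrum"))
  rng <- range(spectrum$wavelengths_nm)
  if (any(at < rng[1L] - 1e-9) || any(at > rng[2L] + 1e-9))
    stop(sprintf("wavelength(s) outside spectrum range [%g, %g]: extrapolation refused",
                 rng[1L], rng[2L]), call. = FALSE)
  stats::approx(spectrum$wavelengths_nm, spectrum$absorbance_au,
                xout = at, rule = 1)$y
}

#' Interpolate a spectrum onto a new wavelength grid
#'
#' @inheritParams spectrum_at
#' @param grid Target wavelength grid (strictly increasing, within the
#'   spectrum's range).
#' @return A `uv_spectrum` on `grid`, metadata preserved.
#' @export
interpolate_spectrum <- function(spectrum, grid) {
  a <- spectrum_at(spectrum, grid)
  out <- spectrum
  out$wavelengths_nm <- as.numeric(grid)
  out$absorbance_au <- a
  out
}

# shared-grid test used across the package
same_grid <- function(a, b, tol = 1e-9) {
  length(a$wavelengths_nm) == length(b$wavelengths_nm) &&
    all(abs(a$wavelengths_nm - b$wavelengths_nm) <= tol)
}
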