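#' Assemble a conversion time series from unmix fits
#'
#' Orders fits by sampling time and collects conversions and per-point QC
#' flags. Flagged points are retained and marked, never silently dropped.
#'
#' @param fits A list of `unmix_fit` objects (e.g. an `unmix_series`), each
#'   carrying a sampling time, or missing times supplied via `times_s`.
#' @param times_s Optional numeric vector of sampling times (seconds)
#'   overriding the fits' own `time_s`.
#' @param extra_flags Optional list (parallel to `fits`) of additional flag
#'   character vectors, e.g. from [preprocess_spectrum()].
#' @return An object of class `conversion_series` with fields `times_s`,
#'   `conversions`, `residual_rms`, `flags` (list of character vectors),
#'   `labels`; equilibrium fields are added by [detect_equilibrium()].
#' @export
build_conversion_series <- function(fits, times_s = NULL, extra_flags = NULL) {
  if (length(fits) < 2L)
    stop("a conversion series needs at least 2 points", call. = FALSE)
  if (is.null(times_s))
    times_s <- vapply(fits, function(f)
      if (is.null(f$time_s)) NA_real_ else f$time_s, 0)
  if (anyNA(times_s))
    stop("every fit must carry a sampling time", call. = FALSE)
  if (anyDuplicated(times_s))
    stop("duplicate sampling times", call. = FALSE)
  flags <- lapply(seq_along(fits), function(i)
    unique(c(fits[[i]]$flags,
             if (!is.null(extra_flags)) extra_flags[[i]] else character(0))))
  ord <- order(times_s)
  structure(
    list(times_s = times_s[ord],
         conversions = vapply(fits, `[[`, 0, "conversion")[ord],
         residual_rms = vapply(fits, `[[`, 0, "residual_rms")[ord],
         flags = flags[ord],
         labels = vapply(fits, `[[`, "", "label")[ord],
         equilibrium_conversion = NULL,
         time_to_equilibrium_s = NULL),
    class = "conversion_series")
}

#' @export
print.conversion_series <- function(x, ...) {
  cat(sprintf("<conversion_series> %d points, t = %g-%g s\n",
              length(x$times_s), min(x$times_s), max(x$times_s)))
  n_flag <- sum(lengths(x$flags) > 0)
  if (n_flag) cat(sprintf("  %d flagged point(s)\n", n_flag))
  if (!is.null(x$equilibrium_conversion))
    cat(sprintf("  equilibrium: conversion %.4f reached at t = %g s\n",
                x$equilibrium_conversion, x$time_to_equilibrium_s))
  invisible(x)
}

#' @export
as.data.frame.conversion_series <- function(x, ...) {
  data.frame(time_s = x$times_s, conversion = x$conversions,
             residual_rms = x$residual_rms,
             flags = vapply(x$flags, paste, "", collapse = ";"),
             label = x$labels, stringsAsFactors = FALSE)
}

#' @export
summary.conversion_series <- function(object, ...) {
  print(object)
  print(utils::head(as.data.frame(object), 10))
  invisible(object)
}

#' @export
plot.conversion_series <- function(x, raw_iso_au = NULL, ...) {
  if (!is.null(raw_iso_au)) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  flagged <- lengths(x$flags) > 0
  graphics::plot(x$times_s, x$conversions, type = "b", ylim = c(0, 1),
                 xlab = "Time [s]", ylab = "Conversion", ...)
  if (any(flagged))
    graphics::points(x$times_s[flagged], x$conversions[flagged],
                     pch = 4, col = 2, cex = 1.5)
  if (!is.null(x$equilibrium_conversion))
    graphics::abline(h = x$equilibrium_conversion, lty = 3)
  if (!is.null(raw_iso_au))
    graphics::plot(x$times_s, raw_iso_au, type = "b", xlab = "Time [s]",
                   ylab = "A(isosbestic) [AU]",
                   ylim = c(0, max(raw_iso_au) * 1.2))
  invisible(x)
}

#' Check isosbestic-point constancy across a raw series
#'
#' At the isosbestic point of base cleavage, nucleoside and nucleobase share
#' one extinction coefficient, so the raw (pre-normalization,
#' background-corrected) absorbance there should stay constant throughout a
#' reaction when sampling volumes are consistent. A drifting isosbestic
#' signal indicates pipetting errors, analyte instability or a wrong
#' reference pair.
#'
#' @param raw_samples List of at least 2 background-corrected `uv_spectrum`s
#'   on a shared grid.
#' @param iso_nm Isosbestic wavelength (nm).
#' @param tol Warn tolerance on the relative deviation (default 0.10).
#' @return A list with `deviation` (`(max - min)/median` of the isosbestic
#'   absorbances), `warn` (logical), and `iso_au` (the per-sample values).
#' @export
check_isosbestic_constancy <- function(raw_samples, iso_nm, tol = 0.10) {
  if (length(raw_samples) < 2L)
    stop("need at least 2 spectra", call. = FALSE)
  ref <- raw_samples[[1L]]
  for (s in raw_samples)
    if (!same_grid(ref, s))
      stop("series spectra must share one wavelength grid", call. = FALSE)
  iso_au <- vapply(raw_samples, spectrum_at, 0, at = iso_nm)
  med <- stats::median(iso_au)
  if (med <= 0)
    stop("median isosbestic absorbance is non-positive", call. = FALSE)
  deviation <- (max(iso_au) - min(iso_au)) / med
  list(deviation = deviation, warn = deviation > tol, iso_au = iso_au)
}

#' Detect equilibrium in a conversion series
#'
#' Scans for the earliest time from which every trailing window of `window`
#' consecutive points has an absolute fitted linear slope below `slope_tol`.
#' The equilibrium conversion is the mean over that plateau. Points flagged
#' by QC are excluded from the slope fits but remain in the series.
#'
#' @param series A `conversion_series`.
#' @param window Number of points per trailing window (default 5, minimum 3).
#' @param slope_tol Slope threshold in conversion units per second
#'   (default 1e-4).
#' @return The input series with `time_to_equilibrium_s` and
#'   `equilibrium_conversion` filled in (both `NULL` when no plateau is
#'   reached — the two fields are only ever present together).
#' @export
detect_equilibrium <- function(series, window = 5, slope_tol = 1e-4) {
  stopifnot(inherits(series, "conversion_series"))
  if (window < 3L) stop("window must be at least 3 points", call. = FALSE)
  keep <- lengths(series$flags) == 0
  t <- series$times_s[keep]
  x <- series$conversions[keep]
  n <- length(t)
  if (n < window)
    stop(sprintf("series has %d unflagged points, fewer than window = %d",
                 n, window), call. = FALSE)
  slope <- function(tt, xx) {
    tc <- tt - mean(tt)
    sum(tc * xx) / sum(tc * tc)
  }
  start <- NA_integer_
  for (i in seq_len(n - window + 1L)) {
    ok <- TRUE
    for (j in i:(n - window + 1L)) {
      if (abs(slope(t[j:(j + window - 1L)], x[j:(j + window - 1L)])) >= slope_tol) {
        ok <- FALSE
        break
      }
    }
    if (ok) { start <- i; break }
  }
  if (is.na(start)) {
    series$time_to_equilibrium_s <- NULL
    series$equilibrium_conversion <- NULL
  } else {
    series$time_to_equilibrium_s <- t[start]
    series$equilibrium_conversion <- mean(x[start:n])
  }
  series
}

#' Flag series points measured past the reference's stability window
#'
#' Some analytes degrade under the quench conditions (e.g. 2-fluoroadenosine
#' pairs are stable for about 10 minutes at pH 13); points whose age since
#' quench exceeds the reference's `stability_window_s` are flagged
#' `"stability"` but retained.
#'
#' @param series A `conversion_series`.
#' @param pair A `reference_pair` (the smaller of the two members'
#'   stability windows applies; nothing happens if neither declares one).
#' @param age_since_quench_s Numeric vector: each point's sample age
#'   (seconds between quenching and measurement), recycled if length 1.
#' @return The series with `"stability"` added to the flags of offending
#'   points.
#' @export
flag_stability <- function(series, pair, age_since_quench_s) {
  stopifnot(inherits(series, "conversion_series"),
            inherits(pair, "reference_pair"))
  windows <- c(pair$nucleoside$stability_window_s,
               pair$nucleobase$stability_window_s)
  if (is.null(windows) || !length(windows)) return(series)
  w <- min(windows)
  age <- rep_len(as.numeric(age_since_quench_s), length(series$times_s))
  over <- which(age > w)
  for (i in over)
    series$flags[[i]] <- unique(c(series$flags[[i]], "stability"))
  series
}
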