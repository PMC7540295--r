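#' Unmix a spectrum into nucleoside and nucleobase contributions
#'
#' Fits the pair's normalized reference spectra to a processed experimental
#' spectrum by least squares over the fitting range:
#' \deqn{(c_N, c_B) = \arg\min_{c_N, c_B \ge 0} \sum_\lambda
#'   [A(\lambda) - c_N R_N(\lambda) - c_B R_B(\lambda)]^2}
#' and derives the degree of conversion
#' \eqn{x = c_B / (c_N + c_B)}. Non-negativity reflects physical
#' concentrations and is enforced by a constrained solve (for two components
#' the exact solution is the best of the unconstrained optimum and the two
#' boundary fits), not by post-hoc clipping, which would distort the
#' companion coefficient.
#'
#' After isosbestic normalization both references and the sample have
#' absorbance 1 at the isosbestic point, so the coefficient sum is expected
#' to be close to 1; a departure beyond `coef_sum_tol` is flagged
#' `"coef_sum_anomaly"`. A root-mean-square residual above `residual_tol`
#' flags `"poor_fit"`.
#'
#' @param sample A `uv_spectrum`. With `preprocess = TRUE` (default) it is
#'   restricted to the pair's fitting range and normalized to the active
#'   isosbestic point first; pass `preprocess = FALSE` for a sample already
#'   processed (e.g. by [preprocess_spectrum()]).
#' @param pair A validated `reference_pair`.
#' @param preprocess Restrict + normalize the sample before fitting?
#' @param nonneg Constrain coefficients to be non-negative (default `TRUE`).
#' @param offset Include a free flat-offset term (exploratory only; default
#'   `FALSE` — baseline shifts are excluded upstream, not absorbed here).
#' @param residual_tol RMS-residual threshold for the `"poor_fit"` flag
#'   (normalized units; default 0.01).
#' @param coef_sum_tol Tolerance on `|c_N + c_B - 1|` for the
#'   `"coef_sum_anomaly"` flag (default 0.10).
#' @param noise_floor Noise floor passed to [normalize_to_isosbestic()].
#' @return An object of class `unmix_fit` with components `coefficients`
#'   (named: nucleoside, nucleobase), `conversion`, `residual_rms`,
#'   `fit_range_nm`, `flags`, `fitted.values`, `residuals`,
#'   `wavelengths_nm`, `observed`, and metadata (`label`, `time_s`, pair
#'   compound ids, `method`).
#' @examples
#' pair <- generate_reference_pair(synthetic_scenario())
#' s <- simulate_mixture(pair, x = 0.3, noise_sigma = 0, seed = 1)
#' fit <- unmix(s, pair)
#' coef(fit)
#' fit$conversion
#' @export
unmix <- function(sample, pair, preprocess = TRUE, nonneg = TRUE,
                  offset = FALSE, residual_tol = 0.01, coef_sum_tol = 0.10,
                  noise_floor = 0.05) {
  stopifnot(inherits(sample, "uv_spectrum"), inherits(pair, "reference_pair"))
  validate_reference_pair(pair)
  if (pair$wavelength_mode_only)
    stop("pair has no isosbestic point; use unmix_wavelength_mode()",
         call. = FALSE)
  flags <- character(0)
  if (preprocess) {
    sample <- restrict_to_fit_range(sample, pair$fit_range_nm)
    n <- normalize_to_isosbestic(sample, pair$active_isosbestic_nm,
                                 floor = noise_floor)
    sample <- n$spectrum
  }
  rn <- restrict_to_fit_range(pair$nucleoside$spectrum,
                              range(sample$wavelengths_nm))
  rb <- restrict_to_fit_range(pair$nucleobase$spectrum,
                              range(sample$wavelengths_nm))
  if (!same_grid(rn, sample)) {
    rn <- interpolate_spectrum(pair$nucleoside$spectrum, sample$wavelengths_nm)
    rb <- interpolate_spectrum(pair$nucleobase$spectrum, sample$wavelengths_nm)
  }
  a <- sample$absorbance_au
  if (all(a == 0)) stop("all-zero sample spectrum", call. = FALSE)
  x1 <- rn$absorbance_au
  x2 <- rb$absorbance_au
  if (abs(stats::cor(x1, x2)) > 0.999)
    stop("references indistinguishable over the fit range (shape correlation > 0.999)",
         call. = FALSE)

  if (offset) {
    X <- cbind(nucleoside = x1, nucleobase = x2, offset = 1)
    cf <- stats::lsfit(X, a, intercept = FALSE)$coefficients
    if (nonneg && any(cf[1:2] < 0)) {
      # active-set over the two component coefficients, offset always free
      cands <- list(c(fit_one_with_offset(a, x2), comp = 2L),
                    c(fit_one_with_offset(a, x1), comp = 1L))
      sse <- vapply(cands, function(z) z[["sse"]], 0)
      z <- cands[[which.min(sse)]]
      cf <- if (z[["comp"]] == 2L) c(0, z[["coef"]], z[["off"]])
            else c(z[["coef"]], 0, z[["off"]])
    }
    coefs <- c(nucleoside = unname(cf[1L]), nucleobase = unname(cf[2L]))
    fitted <- coefs[1L] * x1 + coefs[2L] * x2 + cf[3L]
    off_val <- unname(cf[3L])
  } else {
    coefs <- nnls2(a, x1, x2, nonneg = nonneg)
    fitted <- coefs[1L] * x1 + coefs[2L] * x2
    off_val <- NULL
  }
  res <- a - fitted
  rms <- sqrt(mean(res^2))
  total <- coefs[1L] + coefs[2L]
  conversion <- if (total > 0) unname(coefs[2L] / total) else NA_real_
  if (!is.na(conversion)) conversion <- min(max(conversion, 0), 1)
  if (rms > residual_tol) flags <- c(flags, "poor_fit")
  if (abs(total - 1) > coef_sum_tol) flags <- c(flags, "coef_sum_anomaly")

  structure(
    list(coefficients = c(nucleoside = unname(coefs[1L]),
                          nucleobase = unname(coefs[2L])),
         conversion = conversion,
         residual_rms = rms,
         fit_range_nm = range(sample$wavelengths_nm),
         flags = flags,
         fitted.values = fitted,
         residuals = res,
         wavelengths_nm = sample$wavelengths_nm,
         observed = a,
         offset = off_val,
         label = sample$label,
         time_s = sample$time_s,
         pair_ids = c(nucleoside = pair$nucleoside$compound_id,
                      nucleobase = pair$nucleobase$compound_id),
         method = if (nonneg) "nnls" else "ols"),
    class = "unmix_fit")
}

# Exact two-variable non-negative least squares: take the unconstrained
# normal-equation solution if feasible, otherwise the better of the two
# single-component boundary fits (coefficients clamped at 0).
nnls2 <- function(a, x1, x2, nonneg = TRUE) {
  g11 <- sum(x1 * x1); g12 <- sum(x1 * x2); g22 <- sum(x2 * x2)
  b1 <- sum(x1 * a); b2 <- sum(x2 * a)
  det <- g11 * g22 - g12 * g12
  if (det <= .Machine$double.eps * g11 * g22)
    stop("references indistinguishable over the fit range", call. = FALSE)
  c1 <- (b1 * g22 - b2 * g12) / det
  c2 <- (b2 * g11 - b1 * g12) / det
  if (!nonneg || (c1 >= 0 && c2 >= 0)) return(c(c1, c2))
  # boundary candidates
  c1_only <- max(b1 / g11, 0)
  c2_only <- max(b2 / g22, 0)
  sse1 <- sum((a - c1_only * x1)^2)
  sse2 <- sum((a - c2_only * x2)^2)
  if (sse1 <= sse2) c(c1_only, 0) else c(0, c2_only)
}

# single component + free offset, for the exploratory offset model
fit_one_with_offset <- function(a, x) {
  cf <- stats::lsfit(cbind(x), a)$coefficients # intercept + slope
  slope <- max(unname(cf[2L]), 0)
  off <- if (slope == unname(cf[2L])) unname(cf[1L]) else mean(a)
  list(coef = slope, off = off, sse = sum((a - off - slope * x)^2))
}

#' @export
print.unmix_fit <- function(x, ...) {
  cat(sprintf("<unmix_fit> %s  (%s / %s)\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              x$pair_ids["nucleoside"], x$pair_ids["nucleobase"]))
  cat(sprintf("  conversion: %.4f   coefficients: %.4f + %.4f = %.4f\n",
              x$conversion, x$coefficients[1L], x$coefficients[2L],
              sum(x$coefficients)))
  cat(sprintf("  residual RMS: %.3g over %g-%g nm%s\n", x$residual_rms,
              x$fit_range_nm[1L], x$fit_range_nm[2L],
              if (length(x$flags)) paste0("   flags: ",
                                          paste(x$flags, collapse = ", "))
              else ""))
  invisible(x)
}

#' @export
summary.unmix_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  n = %d wavelengths, method = %s\n",
              length(object$wavelengths_nm), object$method))
  invisible(object)
}

#' @export
coef.unmix_fit <- function(object, ...) object$coefficients

#' @export
fitted.unmix_fit <- function(object, ...) object$fitted.values

#' @export
residuals.unmix_fit <- function(object, ...) object$residuals

#' @export
predict.unmix_fit <- function(object, pair = NULL, wavelengths = NULL, ...) {
  if (is.null(wavelengths)) return(object$fitted.values)
  if (is.null(pair))
    stop("predicting at new wavelengths requires the reference_pair",
         call. = FALSE)
  rn <- spectrum_at(pair$nucleoside$spectrum, wavelengths)
  rb <- spectrum_at(pair$nucleobase$spectrum, wavelengths)
  object$coefficients[1L] * rn + object$coefficients[2L] * rb +
    if (is.null(object$offset)) 0 else object$offset
}

#' @export
plot.unmix_fit <- function(x, ...) {
  graphics::plot(x$wavelengths_nm, x$observed, type = "l",
                 xlab = "Wavelength [nm]", ylab = "Normalized absorbance",
                 main = sprintf("%s: conversion %.3f", x$label, x$conversion),
                 ...)
  graphics::lines(x$wavelengths_nm, x$fitted.values, lty = 2, col = 2)
  graphics::legend("topright", c("observed", "fitted"), lty = 1:2,
                   col = 1:2, bty = "n")
  invisible(x)
}

#' Unmix an ordered series of spectra
#'
#' Applies [unmix()] to each spectrum in order; per-sample QC flags are
#' propagated into the individual fits.
#'
#' @param samples List of `uv_spectrum` objects, all preprocessed
#'   identically (or raw, with `preprocess = TRUE`).
#' @param pair A `reference_pair`.
#' @param ... Passed to [unmix()].
#' @return A list of `unmix_fit` objects (class `unmix_series`), order
#'   preserved.
#' @export
unmix_series <- function(samples, pair, ...) {
  if (length(samples) == 0L) stop("empty sample list", call. = FALSE)
  fits <- lapply(samples, unmix, pair = pair, ...)
  class(fits) <- "unmix_series"
  fits
}

#' @export
print.unmix_series <- function(x, ...) {
  cat(sprintf("<unmix_series> %d fits, conversions %s\n", length(x),
              paste(sprintf("%.3f", vapply(x, `[[`, 0, "conversion")),
                    collapse = ", ")))
  invisible(x)
}

#' Brute-force unmixing oracle
#'
#' Exhaustive grid search over the conversion fraction. At each candidate
#' conversion `x` the mixture shape `(1-x) R_N + x R_B` is fixed and the
#' best total amount is the one-dimensional least-squares projection of the
#' sample onto that shape (clamped at 0); the SSE-minimizing grid point
#' wins. Slow but transparent — used to cross-check [unmix()].
#'
#' @inheritParams unmix
#' @param grid_step Conversion grid resolution (default 1e-4).
#' @return An `unmix_fit` (method `"grid"`).
#' @export
brute_force_unmix <- function(sample, pair, grid_step = 1e-4,
                              preprocess = TRUE, noise_floor = 0.05) {
  stopifnot(inherits(sample, "uv_spectrum"), inherits(pair, "reference_pair"))
  if (preprocess) {
    sample <- restrict_to_fit_range(sample, pair$fit_range_nm)
    sample <- normalize_to_isosbestic(sample, pair$active_isosbestic_nm,
                                      floor = noise_floor)$spectrum
  }
  rn <- interpolate_spectrum(pair$nucleoside$spectrum, sample$wavelengths_nm)
  rb <- interpolate_spectrum(pair$nucleobase$spectrum, sample$wavelengths_nm)
  a <- sample$absorbance_au
  if (all(a == 0)) stop("all-zero sample spectrum", call. = FALSE)
  if (abs(stats::cor(rn$absorbance_au, rb$absorbance_au)) > 0.999)
    stop("references indistinguishable over the fit range", call. = FALSE)
  xs <- seq(0, 1, by = grid_step)
  if (xs[length(xs)] < 1) xs <- c(xs, 1)
  # at fixed x the mixture shape is m(x) = (1-x) R_N + x R_B and the best
  # total is the projection <m, a>/<m, m> (clamped at 0); both inner
  # products are quadratics in x, so the whole grid is evaluated at once
  rn_a <- rn$absorbance_au
  rb_a <- rb$absorbance_au
  proj <- (1 - xs) * sum(rn_a * a) + xs * sum(rb_a * a)
  mm <- (1 - xs)^2 * sum(rn_a^2) + 2 * xs * (1 - xs) * sum(rn_a * rb_a) +
    xs^2 * sum(rb_a^2)
  t_hat <- pmax(proj / mm, 0)
  sse <- sum(a^2) - 2 * t_hat * proj + t_hat^2 * mm
  i <- which.min(sse)
  best <- list(sse = sse[i], x = xs[i], total = t_hat[i])
  cn <- best$total * (1 - best$x)
  cb <- best$total * best$x
  fitted <- cn * rn$absorbance_au + cb * rb$absorbance_au
  structure(
    list(coefficients = c(nucleoside = cn, nucleobase = cb),
         conversion = best$x,
         residual_rms = sqrt(best$sse / length(a)),
         fit_range_nm = range(sample$wavelengths_nm),
         flags = character(0),
         fitted.values = fitted, residuals = a - fitted,
         wavelengths_nm = sample$wavelengths_nm, observed = a,
         offset = NULL, label = sample$label, time_s = sample$time_s,
         pair_ids = c(nucleoside = pair$nucleoside$compound_id,
                      nucleobase = pair$nucleobase$compound_id),
         method = "grid"),
    class = "unmix_fit")
}

#' Calibration for single-/multi-wavelength reaction monitoring
#'
#' For pairs without an isosbestic point of base cleavage (e.g. ribavirin,
#' whose absorption maxima lie below 250 nm), normalization is impossible but
#' reaction monitoring can still be performed from absorbance at one or two
#' chosen wavelengths. The calibration records the relative absorptivity of
#' each component at those wavelengths (the response matrix).
#'
#' @param pair A `reference_pair`.
#' @param wavelengths One or two wavelengths (nm) within the pair's grid.
#' @param max_condition Maximum acceptable condition number of the 2x2
#'   response matrix (default 1e6).
#' @return An object of class `wavelength_calibration` with elements
#'   `wavelengths_nm` and `response_matrix` (rows = wavelengths, columns =
#'   nucleoside, nucleobase).
#' @export
wavelength_calibration <- function(pair, wavelengths, max_condition = 1e6) {
  stopifnot(inherits(pair, "reference_pair"))
  wavelengths <- as.numeric(wavelengths)
  if (!length(wavelengths) %in% 1:2)
    stop("wavelength mode uses 1 or 2 wavelengths", call. = FALSE)
  M <- cbind(nucleoside = spectrum_at(pair$nucleoside$spectrum, wavelengths),
             nucleobase = spectrum_at(pair$nucleobase$spectrum, wavelengths))
  rownames(M) <- as.character(wavelengths)
  if (nrow(M) == 2L) {
    if (abs(det(M)) < .Machine$double.eps * sum(abs(M)) ||
        kappa(M, exact = TRUE) > max_condition)
      stop("singular response matrix: the two wavelengths give proportional responses",
           call. = FALSE)
  }
  structure(list(wavelengths_nm = wavelengths, response_matrix = M),
            class = "wavelength_calibration")
}

#' Unmix from absorbance at one or two wavelengths
#'
#' Fallback mode for pairs lacking an isosbestic point. In two-wavelength
#' mode the 2x2 linear system `A(lambda_i) = sum_j M_ij c_j` is solved for
#' the component amounts; in one-wavelength mode the known total amount
#' (`total`) closes the system. Solved amounts below zero are clipped to 0
#' and flagged `"clipped"`.
#'
#' @param sample A background-corrected `uv_spectrum` (not normalized).
#' @param calib A `wavelength_calibration`.
#' @param total Known total component amount, required for one-wavelength
#'   mode.
#' @return An `unmix_fit` (method `"wavelength"`).
#' @export
unmix_wavelength_mode <- function(sample, calib, total = NULL) {
  stopifnot(inherits(sample, "uv_spectrum"),
            inherits(calib, "wavelength_calibration"))
  a <- spectrum_at(sample, calib$wavelengths_nm)
  M <- calib$response_matrix
  flags <- character(0)
  if (length(calib$wavelengths_nm) == 2L) {
    cf <- solve(M, a)
  } else {
    if (is.null(total))
      stop("one-wavelength mode requires the known total amount (`total`)",
           call. = FALSE)
    # A = m_N c_N + m_B c_B with c_N + c_B = total
    m <- M[1L, ]
    denom <- m["nucleobase"] - m["nucleoside"]
    if (abs(denom) < .Machine$double.eps * sum(abs(m)))
      stop("components indistinguishable at this wavelength", call. = FALSE)
    cb <- (a - m["nucleoside"] * total) / denom
    cf <- c(total - cb, cb)
  }
  if (any(cf < 0)) {
    cf <- pmax(cf, 0)
    flags <- c(flags, "clipped")
  }
  tot <- sum(cf)
  conversion <- if (tot > 0) unname(cf[2L] / tot) else NA_real_
  fitted <- as.numeric(M %*% cf)
  structure(
    list(coefficients = c(nucleoside = unname(cf[1L]),
                          nucleobase = unname(cf[2L])),
         conversion = conversion,
         residual_rms = sqrt(mean((a - fitted)^2)),
         fit_range_nm = range(calib$wavelengths_nm),
         flags = flags,
         fitted.values = fitted, residuals = a - fitted,
         wavelengths_nm = calib$wavelengths_nm, observed = a,
         offset = NULL, label = sample$label, time_s = sample$time_s,
         pair_ids = colnames(M),
         method = "wavelength"),
    class = "unmix_fit")
}
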