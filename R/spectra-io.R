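#' Assemble a plate spectra set
#'
#' Groups sample spectra and blank spectra measured on one plate. Blanks are
#' keyed by kind: `plate` (empty-well / NaOH background), `protein` (diluted
#' enzyme), `solvent` (UV-active cosolvent such as DMSO or DMF) and `buffer`
#' (concentrated quench buffer). All member spectra must share one wavelength
#' grid.
#'
#' @param samples Named list of `uv_spectrum` objects.
#' @param blanks Named list of `uv_spectrum` objects; names must be drawn from
#'   `c("plate", "shift", "protein", "solvent", "buffer")`.
#' @return An object of class `plate_spectra_set`.
#' @export
plate_spectra_set <- function(samples, blanks = list()) {
  if (length(samples) == 0L)
    stop("plate_spectra_set needs at least one sample spectrum", call. = FALSE)
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    samples <- stats::setNames(samples, vapply(samples, function(s) s$label, ""))
  if (anyDuplicated(names(samples)))
    stop("duplicate sample labels: ",
         paste(unique(names(samples)[duplicated(names(samples))]), collapse = ", "),
         call. = FALSE)
  allowed <- c("plate", "shift", "protein", "solvent", "buffer")
  if (length(blanks)) {
    bad <- setdiff(names(blanks), allowed)
    if (length(bad))
      stop("unknown blank kind(s): ", paste(bad, collapse = ", "),
           " (allowed: ", paste(allowed, collapse = ", "), ")", call. = FALSE)
  }
  all_sp <- c(samples, blanks)
  ref <- all_sp[[1L]]
  for (s in all_sp)
    if (!same_grid(ref, s))
      stop("all spectra in a plate set must share one wavelength grid",
           call. = FALSE)
  structure(list(samples = samples, blanks = blanks),
            class = "plate_spectra_set")
}

#' @export
print.plate_spectra_set <- function(x, ...) {
  cat(sprintf("<plate_spectra_set> %d sample(s), %d blank(s) [%s]\n",
              length(x$samples), length(x$blanks),
              paste(names(x$blanks), collapse = ", ")))
  invisible(x)
}

#' Read a table of spectra from CSV
#'
#' The table dialect is fixed: comma-separated, UTF-8, `.` decimal, header
#' row, first column `wavelength_nm`, one additional column per sample or
#' blank. Columns whose names start with `blank_` followed by a blank kind
#' (e.g. `blank_plate`) are loaded as blanks.
#'
#' @param path Path to a CSV file.
#' @return A `plate_spectra_set`.
#' @examples
#' \donttest{
#' tmp <- tempfile(fileext = ".csv")
#' write.csv(data.frame(wavelength_nm = 250:350, A1 = runif(101)),
#'           tmp, row.names = FALSE)
#' read_spectra_table(tmp)
#' }
#' @export
read_spectra_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        fileEncoding = "UTF-8")
  if (nrow(df) < 2L)
    stop("spectra table needs at least 2 wavelength rows: ", path, call. = FALSE)
  if (ncol(df) < 2L)
    stop("spectra table needs a wavelength column plus at least one sample: ",
         path, call. = FALSE)
  if (anyDuplicated(names(df)))
    stop("duplicate column labels in ", path, ": ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "),
         call. = FALSE)
  num <- lapply(seq_along(df), function(j) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]) & nzchar(trimws(df[[j]])))
    if (length(bad) || anyNA(v))
      stop(sprintf("non-numeric value in '%s', column '%s', data row %d",
                   path, names(df)[j],
                   if (length(bad)) bad[1L] else which(is.na(v))[1L]),
           call. = FALSE)
    v
  })
  wl <- num[[1L]]
  if (any(diff(wl) <= 0))
    stop("wavelengths not strictly increasing in ", path, call. = FALSE)
  samples <- list()
  blanks <- list()
  for (j in 2:ncol(df)) {
    nm <- names(df)[j]
    sp <- uv_spectrum(wl, num[[j]], label = nm)
    if (grepl("^blank_", nm)) {
      blanks[[sub("^blank_", "", nm)]] <- sp
    } else {
      samples[[nm]] <- sp
    }
  }
  if (!length(samples))
    stop("no sample columns (only blanks) in ", path, call. = FALSE)
  plate_spectra_set(samples, blanks)
}

#' Write a plate spectra set to CSV
#'
#' Emits the same dialect that [read_spectra_table()] reads; blanks are
#' written with a `blank_` column-name prefix. Round-tripping preserves
#' values to the emitted precision (15 significant digits).
#'
#' @param spectra A `plate_spectra_set` (or a single `uv_spectrum`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(spectra, path) {
  if (inherits(spectra, "uv_spectrum"))
    spectra <- plate_spectra_set(stats::setNames(
      list(spectra), if (nzchar(spectra$label)) spectra$label else "sample"))
  stopifnot(inherits(spectra, "plate_spectra_set"))
  cols <- spectra$samples
  if (length(spectra$blanks))
    cols <- c(cols, stats::setNames(spectra$blanks,
                                    paste0("blank_", names(spectra$blanks))))
  df <- data.frame(wavelength_nm = cols[[1L]]$wavelengths_nm,
                   check.names = FALSE)
  for (nm in names(cols)) df[[nm]] <- cols[[nm]]$absorbance_au
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Construct a reference spectrum with compound metadata
#'
#' Wraps a pure-compound spectrum (recorded under the stated quench/pH
#' condition, typically a 10- to 20-fold alkaline dilution of a 2 mM stock)
#' together with the metadata that drives pair construction: the compound's
#' role (nucleoside or nucleobase), its absorption maximum, the isosbestic
#' point(s) of base cleavage shared with its partner, and the spectral
#' extension — the wavelength beyond which neither member of the pair
#' absorbs appreciably.
#'
#' @param spectrum A `uv_spectrum`.
#' @param compound_id Compound identifier (e.g. `"thymidine"`).
#' @param role `"nucleoside"` or `"nucleobase"`.
#' @param ph_condition Text description of the measurement medium
#'   (e.g. `"100 mM NaOH, pH 13"`).
#' @param lambda_max_nm Absorption maximum (nm).
#' @param isosbestic_points_nm Numeric vector of 0, 1 or 2 isosbestic
#'   wavelengths (nm); empty for pairs lacking one.
#' @param spectral_extension_nm Wavelength (nm) beyond which the pair does
#'   not absorb appreciably; must be >= `lambda_max_nm`.
#' @param quench_medium Quench medium text (default `"NaOH"`).
#' @param stability_window_s Optional stability window after quenching
#'   (seconds); samples analysed later than this are flagged.
#' @return An object of class `reference_spectrum`.
#' @export
reference_spectrum <- function(spectrum, compound_id, role, ph_condition,
                               lambda_max_nm, isosbestic_points_nm = numeric(0),
                               spectral_extension_nm,
                               quench_medium = "NaOH",
                               stability_window_s = NULL) {
  stopifnot(inherits(spectrum, "uv_spectrum"))
  role <- match.arg(role, c("nucleoside", "nucleobase"))
  lambda_max_nm <- as.numeric(lambda_max_nm)
  isosbestic_points_nm <- as.numeric(isosbestic_points_nm)
  spectral_extension_nm <- as.numeric(spectral_extension_nm)
  if (length(isosbestic_points_nm) > 2L)
    stop(compound_id, ": at most 2 isosbestic points supported", call. = FALSE)
  rng <- range(spectrum$wavelengths_nm)
  for (w in c(lambda_max_nm, isosbestic_points_nm))
    if (w < rng[1L] || w > rng[2L])
      stop(sprintf("%s: wavelength %g nm outside spectrum range [%g, %g]",
                   compound_id, w, rng[1L], rng[2L]), call. = FALSE)
  if (spectral_extension_nm < lambda_max_nm)
    stop(compound_id, ": spectral_extension_nm must be >= lambda_max_nm",
         call. = FALSE)
  structure(
    list(spectrum = spectrum, compound_id = as.character(compound_id),
         role = role, ph_condition = as.character(ph_condition),
         quench_medium = as.character(quench_medium),
         lambda_max_nm = lambda_max_nm,
         isosbestic_points_nm = isosbestic_points_nm,
         spectral_extension_nm = spectral_extension_nm,
         stability_window_s = if (is.null(stability_window_s)) NULL
                              else as.numeric(stability_window_s),
         normalized = FALSE, norm_scale = NULL),
    class = "reference_spectrum")
}

#' @export
print.reference_spectrum <- function(x, ...) {
  cat(sprintf("<reference_spectrum> %s (%s), lambda_max %g nm, isosbestic %s, extension %g nm\n",
              x$compound_id, x$role, x$lambda_max_nm,
              if (length(x$isosbestic_points_nm))
                paste(x$isosbestic_points_nm, collapse = "/") else "none",
              x$spectral_extension_nm))
  invisible(x)
}

# required sidecar keys; stability_window_s is optional
.ref_required_fields <- c("compound_id", "role", "ph_condition",
                          "lambda_max_nm", "isosbestic_points_nm",
                          "spectral_extension_nm")

#' Load a reference-spectrum library from a directory
#'
#' Each compound is stored as a two-column CSV (`wavelength_nm`,
#' `absorbance_au`) plus a YAML sidecar of the same basename with keys
#' `compound_id`, `role`, `ph_condition`, `quench_medium`, `lambda_max_nm`,
#' `isosbestic_points_nm` (a list, possibly empty), `spectral_extension_nm`
#' and optionally `stability_window_s`.
#'
#' @param directory Directory containing `<compound>.csv` / `<compound>.yaml`
#'   pairs.
#' @return Named list of validated `reference_spectrum` objects.
#' @export
load_reference_library <- function(directory) {
  if (!dir.exists(directory))
    stop("reference library directory not found: ", directory, call. = FALSE)
  metas <- list.files(directory, pattern = "\\.ya?ml$", full.names = TRUE)
  if (!length(metas))
    stop("no metadata sidecars (*.yaml) in ", directory, call. = FALSE)
  out <- list()
  for (mf in metas) {
    meta <- yaml::read_yaml(mf)
    base <- tools::file_path_sans_ext(mf)
    id <- if (!is.null(meta$compound_id)) meta$compound_id else basename(base)
    missing <- setdiff(.ref_required_fields, names(meta))
    # an explicitly null isosbestic list means "no isosbestic point", not missing
    if ("isosbestic_points_nm" %in% names(meta))
      missing <- setdiff(missing, "isosbestic_points_nm")
    if (length(missing))
      stop(sprintf("reference metadata for '%s' is missing field(s): %s",
                   id, paste(missing, collapse = ", ")), call. = FALSE)
    csv <- paste0(base, ".csv")
    if (!file.exists(csv))
      stop("spectrum file not found for '", id, "': ", csv, call. = FALSE)
    df <- utils::read.csv(csv, fileEncoding = "UTF-8")
    if (!all(c("wavelength_nm", "absorbance_au") %in% names(df)))
      stop("reference spectrum '", id,
           "' must have columns wavelength_nm, absorbance_au", call. = FALSE)
    sp <- uv_spectrum(df$wavelength_nm, df$absorbance_au, label = id)
    iso <- meta$isosbestic_points_nm
    out[[id]] <- reference_spectrum(
      sp, compound_id = id, role = meta$role,
      ph_condition = meta$ph_condition,
      quench_medium = if (is.null(meta$quench_medium)) "NaOH" else meta$quench_medium,
      lambda_max_nm = meta$lambda_max_nm,
      isosbestic_points_nm = if (is.null(iso)) numeric(0) else unlist(iso),
      spectral_extension_nm = meta$spectral_extension_nm,
      stability_window_s = meta$stability_window_s)
  }
  out
}

#' Write a reference spectrum (CSV + YAML sidecar) into a library directory
#'
#' @param ref A `reference_spectrum`.
#' @param directory Target directory (created if absent).
#' @return The CSV path, invisibly.
#' @export
write_reference_spectrum <- function(ref, directory) {
  stopifnot(inherits(ref, "reference_spectrum"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  base <- file.path(directory, ref$compound_id)
  df <- data.frame(wavelength_nm = ref$spectrum$wavelengths_nm,
                   absorbance_au = ref$spectrum$absorbance_au)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   paste0(base, ".csv"), row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  meta <- list(compound_id = ref$compound_id, role = ref$role,
               ph_condition = ref$ph_condition,
               quench_medium = ref$quench_medium,
               lambda_max_nm = ref$lambda_max_nm,
               isosbestic_points_nm = as.list(ref$isosbestic_points_nm),
               spectral_extension_nm = ref$spectral_extension_nm)
  if (!is.null(ref$stability_window_s))
    meta$stability_window_s <- ref$stability_window_s
  yaml::write_yaml(meta, paste0(base, ".yaml"))
  invisible(paste0(base, ".csv"))
}

#' Build a validated nucleoside/nucleobase reference pair
#'
#' Selects the active isosbestic point, normalizes both members to absorbance
#' 1 there (recording the pre-normalization scales so raw spectra remain
#' recoverable) and fixes the fitting range. When a compound pair lists two
#' isosbestic points the default choice is the point of larger common
#' absorbance, which gives the better signal-to-noise for normalization; an
#' explicit `isosbestic` argument always wins. Pairs without any isosbestic
#' point (e.g. ribavirin) cannot be normalized and are flagged for the
#' single-/multi-wavelength fallback mode instead.
#'
#' @param nucleoside,nucleobase `reference_spectrum` objects with matching
#'   `ph_condition` and overlapping wavelength grids.
#' @param isosbestic Optional isosbestic wavelength override (must be listed
#'   in the metadata of both members).
#' @param fit_range Optional length-2 numeric fitting interval (nm). Default
#'   `[250 (or grid start), min spectral extension]`.
#' @return An object of class `reference_pair` with elements `nucleoside`,
#'   `nucleobase` (normalized members), `active_isosbestic_nm` (or `NULL`),
#'   `fit_range_nm` and `wavelength_mode_only`.
#' @examples
#' sc <- synthetic_scenario()
#' pair <- generate_reference_pair(sc)
#' pair$active_isosbestic_nm
#' @export
build_reference_pair <- function(nucleoside, nucleobase,
                                 isosbestic = NULL, fit_range = NULL) {
  stopifnot(inherits(nucleoside, "reference_spectrum"),
            inherits(nucleobase, "reference_spectrum"))
  if (nucleoside$role != "nucleoside" || nucleobase$role != "nucleobase")
    stop("arguments must be a nucleoside and a nucleobase reference (in that order)",
         call. = FALSE)
  if (!identical(nucleoside$ph_condition, nucleobase$ph_condition))
    stop("pair members measured under different pH conditions: '",
         nucleoside$ph_condition, "' vs '", nucleobase$ph_condition, "'",
         call. = FALSE)
  lo <- max(min(nucleoside$spectrum$wavelengths_nm),
            min(nucleobase$spectrum$wavelengths_nm))
  hi <- min(max(nucleoside$spectrum$wavelengths_nm),
            max(nucleobase$spectrum$wavelengths_nm))
  if (hi <= lo)
    stop("reference grids do not overlap", call. = FALSE)

  # common isosbestic candidates
  iso_common <- intersect(nucleoside$isosbestic_points_nm,
                          nucleobase$isosbestic_points_nm)
  if (!is.null(isosbestic)) {
    if (!any(abs(iso_common - isosbestic) < 1e-9))
      stop("requested isosbestic point ", isosbestic,
           " nm is not listed in the metadata of both members", call. = FALSE)
    active_iso <- as.numeric(isosbestic)
  } else if (length(iso_common) == 0L) {
    active_iso <- NULL
  } else if (length(iso_common) == 1L) {
    active_iso <- iso_common
  } else {
    # two candidates: prefer the one with larger common absorbance after
    # scaling each member to unit maximum (better normalization S/N)
    score <- vapply(iso_common, function(w) {
      an <- spectrum_at(nucleoside$spectrum, w) / max(nucleoside$spectrum$absorbance_au)
      ab <- spectrum_at(nucleobase$spectrum, w) / max(nucleobase$spectrum$absorbance_au)
      (an + ab) / 2
    }, 0)
    active_iso <- iso_common[which.max(score)]
  }

  ext <- min(nucleoside$spectral_extension_nm, nucleobase$spectral_extension_nm)
  if (is.null(fit_range)) {
    fit_range <- c(max(250, lo), min(ext, hi))
  } else {
    fit_range <- sort(as.numeric(fit_range))
    if (fit_range[1L] < lo || fit_range[2L] > hi)
      stop("fit_range outside the common wavelength grid", call. = FALSE)
  }
  if (fit_range[2L] > ext + 1e-9)
    stop("fit_range upper bound exceeds the pair's spectral extension (",
         ext, " nm)", call. = FALSE)

  # interpolate nucleobase onto the nucleoside grid over the overlap
  grid <- nucleoside$spectrum$wavelengths_nm
  grid <- grid[grid >= lo - 1e-9 & grid <= hi + 1e-9]
  ns <- nucleoside
  nb <- nucleobase
  ns$spectrum <- interpolate_spectrum(ns$spectrum, grid)
  nb$spectrum <- interpolate_spectrum(nb$spectrum, grid)

  wavelength_mode_only <- is.null(active_iso)
  if (!wavelength_mode_only) {
    for (nm in c("ns", "nb")) {
      ref <- get(nm)
      a_iso <- spectrum_at(ref$spectrum, active_iso)
      if (a_iso <= 0)
        stop(ref$compound_id, ": non-positive absorbance at the isosbestic point",
             call. = FALSE)
      ref$norm_scale <- 1 / a_iso
      ref$spectrum$absorbance_au <- ref$spectrum$absorbance_au / a_iso
      ref$normalized <- TRUE
      assign(nm, ref)
    }
  }
  pair <- structure(
    list(nucleoside = ns, nucleobase = nb,
         active_isosbestic_nm = active_iso,
         fit_range_nm = fit_range,
         wavelength_mode_only = wavelength_mode_only),
    class = "reference_pair")
  validate_reference_pair(pair)
  pair
}

#' Validate a reference pair's invariants
#'
#' Checks: identical grids over the fit range; both normalized members within
#' 1 +/- 0.02 at the active isosbestic point; fit-range upper bound not past
#' either member's spectral extension.
#'
#' @param pair A `reference_pair`.
#' @return `pair`, invisibly; errors on violation.
#' @export
validate_reference_pair <- function(pair) {
  stopifnot(inherits(pair, "reference_pair"))
  if (!same_grid(pair$nucleoside$spectrum, pair$nucleobase$spectrum))
    stop("pair members do not share a wavelength grid", call. = FALSE)
  if (!is.null(pair$active_isosbestic_nm)) {
    for (m in list(pair$nucleoside, pair$nucleobase)) {
      a <- spectrum_at(m$spectrum, pair$active_isosbestic_nm)
      if (abs(a - 1) > 0.02)
        stop(sprintf("%s: normalized absorbance at isosbestic %g nm is %.4f (must be 1.00 +/- 0.02)",
                     m$compound_id, pair$active_isosbestic_nm, a), call. = FALSE)
    }
  }
  ext <- min(pair$nucleoside$spectral_extension_nm,
             pair$nucleobase$spectral_extension_nm)
  if (pair$fit_range_nm[2L] > ext + 1e-9)
    stop("fit range extends past the pair's spectral extension", call. = FALSE)
  invisible(pair)
}

#' @export
print.reference_pair <- function(x, ...) {
  cat(sprintf("<reference_pair> %s / %s\n", x$nucleoside$compound_id,
              x$nucleobase$compound_id))
  cat(sprintf("  isosbestic: %s   fit range: %g-%g nm%s\n",
              if (is.null(x$active_isosbestic_nm)) "none"
              else paste0(x$active_isosbestic_nm, " nm"),
              x$fit_range_nm[1L], x$fit_range_nm[2L],
              if (x$wavelength_mode_only) "   [wavelength mode only]" else ""))
  invisible(x)
}
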