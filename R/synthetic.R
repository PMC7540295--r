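#' Define a synthetic spectral scenario
#'
#' Parameterizes the generator used for validation: smooth Gaussian-band
#' absorbance spectra for a nucleoside/nucleobase pair with a designed
#' isosbestic crossing, mixtures at known mole fractions, Gaussian
#' measurement noise, the common plate/shift/protein/solvent background
#' archetypes, and first-order reaction kinetics. Defaults emulate the
#' thymidine/thymine pair under alkaline conditions: absorption maxima at
#' 266 and 290 nm, isosbestic point of base cleavage at 278 nm, spectral
#' extension 320 nm, measured on the standard 250-350 nm grid in 1 nm steps.
#' Peak amplitudes around 0.5-0.8 AU correspond to a 2 mM substrate sampled
#' at a dilution factor of 15; measurement noise sigma defaults to 0.002 AU.
#'
#' @param nucleoside_bands,nucleobase_bands Data frame (or list) of Gaussian
#'   band parameters with columns `center_nm`, `width_nm` (standard
#'   deviation), `amplitude_au`; one or two rows per component.
#' @param target_isosbestic_nm Designed isosbestic wavelength (nm).
#' @param extension_nm Declared spectral extension (nm).
#' @param grid Wavelength grid (default 250-350 nm in 1 nm steps).
#' @param noise_sigma_au Gaussian measurement noise sigma (AU).
#' @param background_kind One of `"none"`, `"plate"`, `"shift"`,
#'   `"protein"`, `"solvent"`.
#' @param background_params Named list of per-kind parameters passed to
#'   [generate_background()].
#' @param x_eq,k_per_s First-order kinetics: equilibrium conversion and rate
#'   constant, `x(t) = x_eq (1 - exp(-k t))`.
#' @param times_s Sampling times for simulated reaction series (seconds).
#' @param scale Base signal scale: the raw absorbance at the isosbestic
#'   point (AU).
#' @param scale_jitter_sd Log-sd of per-sample multiplicative pipetting
#'   jitter (0 disables; default 0).
#' @param ph_condition,compound_ids Metadata written into the generated
#'   references.
#' @param seed Integer seed recorded in the scenario and used by the
#'   simulators.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(
    nucleoside_bands = data.frame(center_nm = 266, width_nm = 11,
                                  amplitude_au = 0.65),
    nucleobase_bands = data.frame(center_nm = 290, width_nm = 10,
                                  amplitude_au = 0.75),
    target_isosbestic_nm = 278,
    extension_nm = 320,
    grid = seq(250, 350, by = 1),
    noise_sigma_au = 0.002,
    background_kind = "none",
    background_params = list(),
    x_eq = 0.8, k_per_s = 0.01,
    times_s = seq(0, 600, by = 30),
    scale = 0.5,
    scale_jitter_sd = 0,
    ph_condition = "100 mM NaOH, pH 13",
    compound_ids = c(nucleoside = "syn-nucleoside", nucleobase = "syn-nucleobase"),
    seed = 1L) {
  nucleoside_bands <- as.data.frame(nucleoside_bands)
  nucleobase_bands <- as.data.frame(nucleobase_bands)
  for (b in list(nucleoside_bands, nucleobase_bands)) {
    stopifnot(all(c("center_nm", "width_nm", "amplitude_au") %in% names(b)),
              nrow(b) >= 1L, nrow(b) <= 2L,
              all(b$width_nm > 0), all(b$amplitude_au > 0))
  }
  stopifnot(x_eq >= 0, x_eq <= 1, noise_sigma_au >= 0, scale > 0,
            scale_jitter_sd >= 0)
  background_kind <- match.arg(background_kind,
                               c("none", "plate", "shift", "protein", "solvent"))
  structure(
    list(nucleoside_bands = nucleoside_bands,
         nucleobase_bands = nucleobase_bands,
         target_isosbestic_nm = target_isosbestic_nm,
         extension_nm = extension_nm, grid = grid,
         noise_sigma_au = noise_sigma_au,
         background_kind = background_kind,
         background_params = background_params,
         x_eq = x_eq, k_per_s = k_per_s, times_s = times_s,
         scale = scale, scale_jitter_sd = scale_jitter_sd,
         ph_condition = ph_condition, compound_ids = compound_ids,
         seed = as.integer(seed)),
    class = "synthetic_scenario")
}

# evaluate a sum of Gaussian bands on a grid
band_sum <- function(bands, grid) {
  a <- numeric(length(grid))
  for (i in seq_len(nrow(bands)))
    a <- a + bands$amplitude_au[i] *
      exp(-(grid - bands$center_nm[i])^2 / (2 * bands$width_nm[i]^2))
  a
}

# run expr with a temporary RNG state so simulators are reproducible
# without clobbering the caller's random stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic reference pair with a designed isosbestic point
#'
#' Builds two smooth band-sum spectra, rescales the nucleobase spectrum so
#' the two are equal at the target isosbestic wavelength (guaranteeing a
#' crossing there), and assembles a normalized, validated `reference_pair`.
#'
#' @param scenario A `synthetic_scenario`.
#' @return A `reference_pair` passing all pair invariants.
#' @examples
#' pair <- generate_reference_pair(synthetic_scenario())
#' pair
#' @export
generate_reference_pair <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  grid <- scenario$grid
  iso <- scenario$target_isosbestic_nm
  a_ns <- band_sum(scenario$nucleoside_bands, grid)
  a_nb <- band_sum(scenario$nucleobase_bands, grid)
  at <- function(a, w) stats::approx(grid, a, xout = w)$y
  # rescale the nucleobase so both spectra cross at the target isosbestic
  a_nb <- a_nb * at(a_ns, iso) / at(a_nb, iso)

  fit_lo <- max(250, min(grid))
  in_fit <- grid >= fit_lo & grid <= scenario$extension_nm
  if (abs(stats::cor(a_ns[in_fit], a_nb[in_fit])) > 0.999)
    stop("degenerate pair: band shapes are indistinguishable over the fit range",
         call. = FALSE)

  ids <- scenario$compound_ids
  ns <- reference_spectrum(
    uv_spectrum(grid, a_ns, label = ids[["nucleoside"]]),
    compound_id = ids[["nucleoside"]], role = "nucleoside",
    ph_condition = scenario$ph_condition,
    lambda_max_nm = grid[which.max(a_ns)],
    isosbestic_points_nm = iso,
    spectral_extension_nm = scenario$extension_nm)
  nb <- reference_spectrum(
    uv_spectrum(grid, a_nb, label = ids[["nucleobase"]]),
    compound_id = ids[["nucleobase"]], role = "nucleobase",
    ph_condition = scenario$ph_condition,
    lambda_max_nm = grid[which.max(a_nb)],
    isosbestic_points_nm = iso,
    spectral_extension_nm = scenario$extension_nm)
  build_reference_pair(ns, nb)
}

#' Generate a synthetic background spectrum
#'
#' Reproduces the background archetypes commonly seen on UV-transparent
#' 96-well plates:
#' \describe{
#'   \item{plate}{smooth well/plate absorption, about 0.03 AU at 300 nm and
#'     curving up toward slightly higher values at 250 nm
#'     (`level` at 300 nm, `rise` added at 250 nm, decay constant `tau_nm`).}
#'   \item{shift}{a flat baseline elevation of `level` AU at every
#'     wavelength (well/particle artifact).}
#'   \item{protein}{the long-wavelength tail of an aromatic protein band:
#'     Gaussian centered at `center_nm` (280) with sd `width_nm` (25) and
#'     peak `amplitude_au`.}
#'   \item{solvent}{organic-cosolvent absorption (DMSO/DMF-like): a steep
#'     monotone rise below `cutoff_nm`, identically 0 at and above it;
#'     `peak_au` is the value at 250 nm.}
#' }
#'
#' @param kind One of `"plate"`, `"shift"`, `"protein"`, `"solvent"`.
#' @param params Named list overriding the per-kind defaults listed above.
#' @param grid Wavelength grid (default 250-350 nm, 1 nm steps).
#' @return A `uv_spectrum` labelled `background:<kind>`.
#' @export
generate_background <- function(kind, params = list(),
                                grid = seq(250, 350, by = 1)) {
  kind <- match.arg(kind, c("plate", "shift", "protein", "solvent"))
  p <- function(name, default)
    if (!is.null(params[[name]])) params[[name]] else default
  a <- switch(kind,
    plate = {
      level <- p("level", 0.03); rise <- p("rise", 0.02)
      tau <- p("tau_nm", 30)
      # exponential approach: equals `level` at 300 nm, `~level+rise` at 250
      base <- rise * (exp(-(grid - 250) / tau) - exp(-50 / tau)) /
        (1 - exp(-50 / tau))
      base + level
    },
    shift = rep(p("level", 0.12), length(grid)),
    protein = p("amplitude_au", 0.05) *
      exp(-(grid - p("center_nm", 280))^2 / (2 * p("width_nm", 25)^2)),
    solvent = {
      cutoff <- p("cutoff_nm", 280); tau <- p("tau_nm", 10)
      peak <- p("peak_au", 0.3)
      raw <- ifelse(grid < cutoff, expm1((cutoff - grid) / tau), 0)
      top <- expm1((cutoff - min(grid)) / tau)
      if (top > 0) raw * peak / top else raw
    })
  uv_spectrum(grid, a, label = paste0("background:", kind))
}

#' Simulate a noisy mixture spectrum at a known conversion
#'
#' Constructs
#' `S(lambda) = scale * [(1 - x) R_N(lambda) + x R_B(lambda)] +
#' background(lambda) + noise`, with i.i.d. Gaussian noise. The seed makes
#' the output reproducible bit-for-bit without disturbing the caller's RNG
#' stream.
#'
#' @param pair A `reference_pair` (normalized members are used).
#' @param x True conversion (mole fraction of nucleobase) in `[0, 1]`.
#' @param noise_sigma Gaussian noise sd in AU (default 0.002).
#' @param background Optional background `uv_spectrum` to add (interpolated
#'   onto the pair grid).
#' @param scale Positive signal scale: the noiseless absorbance at the
#'   isosbestic point.
#' @param seed Optional integer seed.
#' @param label,time_s Metadata for the generated spectrum.
#' @return A `uv_spectrum` on the pair's grid.
#' @export
simulate_mixture <- function(pair, x, noise_sigma = 0.002, background = NULL,
                             scale = 1, seed = NULL,
                             label = sprintf("mix_x%.3f", x), time_s = NULL) {
  stopifnot(inherits(pair, "reference_pair"))
  if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop("conversion x must lie in [0, 1]", call. = FALSE)
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  grid <- pair$nucleoside$spectrum$wavelengths_nm
  a <- scale * ((1 - x) * pair$nucleoside$spectrum$absorbance_au +
                x * pair$nucleobase$spectrum$absorbance_au)
  if (!is.null(background)) {
    bg <- if (same_grid(pair$nucleoside$spectrum, background)) background
          else interpolate_spectrum(background, grid)
    a <- a + bg$absorbance_au
  }
  if (noise_sigma > 0)
    a <- a + with_seed(seed, stats::rnorm(length(a), 0, noise_sigma))
  uv_spectrum(grid, a, label = label, time_s = time_s)
}

#' Simulate a first-order reaction series with ground truth
#'
#' Generates one mixture spectrum per sampling time following
#' `x(t) = x_eq (1 - exp(-k t))`, with optional per-sample multiplicative
#' scale jitter emulating pipetting variability. The true conversions are
#' always returned alongside the spectra: no fixture exists without its
#' ground truth.
#'
#' @param pair A `reference_pair`.
#' @param scenario A `synthetic_scenario` supplying kinetics
#'   (`x_eq`, `k_per_s`, `times_s`), `noise_sigma_au`, `scale`,
#'   `scale_jitter_sd`, background settings and the `seed`.
#' @return A list with `spectra` (list of `uv_spectrum`, times attached),
#'   `truth` (data frame `time_s`, `conversion`, `scale`) and `background`
#'   (the shared background `uv_spectrum`, or `NULL`).
#' @export
simulate_reaction_series <- function(pair, scenario) {
  stopifnot(inherits(pair, "reference_pair"),
            inherits(scenario, "synthetic_scenario"))
  times <- scenario$times_s
  if (!length(times)) stop("scenario has an empty sampling-time list",
                           call. = FALSE)
  x_true <- scenario$x_eq * (1 - exp(-scenario$k_per_s * times))
  bg <- if (scenario$background_kind == "none") NULL
        else generate_background(scenario$background_kind,
                                 scenario$background_params, scenario$grid)
  scales <- rep(scenario$scale, length(times))
  if (scenario$scale_jitter_sd > 0)
    scales <- scales * with_seed(scenario$seed + 1000L,
      stats::rlnorm(length(times), 0, scenario$scale_jitter_sd))
  spectra <- lapply(seq_along(times), function(i)
    simulate_mixture(pair, x_true[i],
                     noise_sigma = scenario$noise_sigma_au,
                     background = bg, scale = scales[i],
                     seed = scenario$seed + i,
                     label = sprintf("t%06d", as.integer(round(times[i]))),
                     time_s = times[i]))
  list(spectra = spectra,
       truth = data.frame(time_s = times, conversion = x_true,
                          scale = scales),
       background = bg)
}

#' Write a complete synthetic fixture directory
#'
#' Emits everything needed to exercise the full pipeline from files: the
#' spectra table (with the background as a blank column when present), the
#' reference library (CSV + YAML sidecars), the scenario as YAML, and the
#' ground-truth conversions as CSV.
#'
#' @param scenario A `synthetic_scenario`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_synthetic_fixture <- function(scenario, dir) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pair <- generate_reference_pair(scenario)
  sim <- simulate_reaction_series(pair, scenario)
  blanks <- list()
  if (!is.null(sim$background))
    blanks[[scenario$background_kind]] <- sim$background
  set <- plate_spectra_set(
    stats::setNames(sim$spectra, vapply(sim$spectra, `[[`, "", "label")),
    blanks)
  write_spectra_table(set, file.path(dir, "spectra.csv"))
  libdir <- file.path(dir, "reference_library")
  # store the raw (pre-normalization) references, as a real library would
  for (m in list(pair$nucleoside, pair$nucleobase)) {
    raw <- m
    if (isTRUE(m$normalized)) {
      raw$spectrum$absorbance_au <- m$spectrum$absorbance_au / m$norm_scale
      raw$normalized <- FALSE
      raw$norm_scale <- NULL
    }
    write_reference_spectrum(raw, libdir)
  }
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  sc <- scenario
  sc$nucleoside_bands <- as.list(sc$nucleoside_bands)
  sc$nucleobase_bands <- as.list(sc$nucleobase_bands)
  yaml::write_yaml(unclass(sc), file.path(dir, "scenario.yaml"))
  invisible(dir)
}
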