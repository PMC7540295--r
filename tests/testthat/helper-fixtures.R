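# Shared fixtures: all built in code, nothing read from disk.

# thymidine/thymine-like pair on the standard 250-350 nm grid
default_pair <- function(...) {
  generate_reference_pair(synthetic_scenario(...))
}

# uridine/uracil-like pair: maxima 262/281, isosbestic 271, extension 310
uridine_scenario <- function(...) {
  synthetic_scenario(
    nucleoside_bands = data.frame(center_nm = 262, width_nm = 10,
                                  amplitude_au = 0.6),
    nucleobase_bands = data.frame(center_nm = 281, width_nm = 9,
                                  amplitude_au = 0.7),
    target_isosbestic_nm = 271,
    extension_nm = 310,
    compound_ids = c(nucleoside = "syn-uridine", nucleobase = "syn-uracil"),
    ...)
}

# a randomized plausible scenario for property tests
random_scenario <- function(seed) {
  set.seed(seed)
  c_ns <- runif(1, 258, 272)
  c_nb <- c_ns + runif(1, 14, 26)
  iso <- (c_ns + c_nb) / 2 + runif(1, -2, 2)
  synthetic_scenario(
    nucleoside_bands = data.frame(center_nm = c_ns,
                                  width_nm = runif(1, 9, 13),
                                  amplitude_au = runif(1, 0.4, 0.9)),
    nucleobase_bands = data.frame(center_nm = c_nb,
                                  width_nm = runif(1, 8, 12),
                                  amplitude_au = runif(1, 0.4, 0.9)),
    target_isosbestic_nm = iso,
    extension_nm = 325,
    seed = seed)
}

# write a small reference library for a pair into a temp dir, returning it
write_pair_library <- function(pair, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  for (m in list(pair$nucleoside, pair$nucleobase)) {
    raw <- m
    if (isTRUE(m$normalized)) {
      raw$spectrum$absorbance_au <- m$spectrum$absorbance_au / m$norm_scale
      raw$normalized <- FALSE
      raw$norm_scale <- NULL
    }
    write_reference_spectrum(raw, dir)
  }
  dir
}
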