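Package: uvmix
Title: Spectral Unmixing of UV Absorption Spectra for Nucleoside Reaction Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monitors transformations between nucleosides and nucleobases
    (e.g. enzymatic phosphorolysis) from plate-reader UV absorption spectra.
    A measured spectrum recorded after alkaline quenching is expressed as a
    non-negative linear combination of the normalized reference spectra of
    the nucleoside and its free nucleobase; normalization to the isosbestic
    point of base cleavage removes pipetting-volume effects, and the fitted
    coefficients yield the degree of conversion. Includes background
    correction and quality-control rules (baseline-shift flagging,
    signal-to-background checks, restricted fitting ranges), a single- and
    two-wavelength fallback mode for pairs without an isosbestic point,
    conversion time-series assembly with equilibrium detection, and a
    synthetic-spectrum generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
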