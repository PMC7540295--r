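# uvmix

Reaction monitoring of transformations between nucleosides and nucleobases
(e.g. enzymatic phosphorolysis by nucleoside phosphorylases) from
plate-reader UV absorption spectra, by **spectral unmixing**.

## Who this is for

Enzymology and biocatalysis labs that follow nucleobase-cleavage (or
glycosylation) reactions by quenching samples in alkali and recording
250–350 nm absorbance spectra on a 96-well plate reader, instead of running
each timepoint through HPLC. The package turns a table of such spectra plus
a reference-spectrum library into conversion time courses with
quality-control flags.

## The model

Under alkaline quench conditions a reaction sample is a two-component
linear mixture of the nucleoside and its free nucleobase:

    A(λ) = c_N · R_N(λ) + c_B · R_B(λ) + background(λ) + noise

After background subtraction, each spectrum is normalized at the
**isosbestic point of base cleavage** — the wavelength where both analytes
share one extinction coefficient, so absorbance there tracks only the
sampled amount; this removes pipetting-volume errors. The normalized
reference spectra are then fitted by non-negative least squares

    (c_N, c_B) = argmin_{c ≥ 0} Σ_λ [A(λ) − c_N R_N(λ) − c_B R_B(λ)]²

(for two components the constrained optimum is closed-form), and the degree
of conversion is the mole fraction

    x = c_B / (c_N + c_B).

Around the core fit the package provides: background archetypes and their
correction (plate, flat shift, protein, solvent), baseline-shift flagging
(offset > 0.10 AU), the signal-to-background > 5 rule, restricted fitting
ranges for solvent-contaminated spectra (e.g. 265–295 nm for uridine-like
pyrimidines), a single-/two-wavelength fallback for pairs without an
isosbestic point, conversion-series assembly with isosbestic-constancy QC
and equilibrium detection, and a seeded synthetic-spectrum generator used
for validation.

## Worked example

```r
library(uvmix)

scenario <- synthetic_scenario(seed = 7)       # thymidine/thymine-like pair
pair <- generate_reference_pair(scenario)
pair
#> <reference_pair> syn-nucleoside / syn-nucleobase
#>   isosbestic: 278 nm   fit range: 250-320 nm

sim <- simulate_reaction_series(pair, scenario) # x(t) = 0.8 (1 - e^{-0.01 t})
fits <- unmix_series(sim$spectra, pair)
series <- detect_equilibrium(build_conversion_series(fits))
series
#> <conversion_series> 21 points, t = 0-600 s
#>   equilibrium: conversion 0.7931 reached at t = 390 s

data.frame(time_s = series$times_s,
           true = round(sim$truth$conversion, 4),
           recovered = round(series$conversions, 4))[1:6, ]
#>   time_s   true recovered
#> 1      0 0.0000    0.0001
#> 2     30 0.2073    0.2069
#> 3     60 0.3610    0.3609
#> 4     90 0.4747    0.4751
#> 5    120 0.5590    0.5591
#> 6    150 0.6215    0.6213
```

The pair is generated with its absorption maxima at 266 and 290 nm and the
designed isosbestic crossing at 278 nm; mixtures carry Gaussian measurement
noise of σ = 0.002 AU. Each recovered conversion is within a few 10⁻⁴ of
the simulated truth, and the plateau detector reports the equilibrium
conversion (0.7931, the mean over the detected plateau of a series still
creeping toward x_eq = 0.8) and the time it was reached. A single fit shows
the QC quantities:

```r
fits[[5]]
#> <unmix_fit> t000120  (syn-nucleoside / syn-nucleobase)
#>   conversion: 0.5591   coefficients: 0.4405 + 0.5586 = 0.9991
#>   residual RMS: 0.00367 over 250-320 nm
```

The coefficient sum sits near 1 (as isosbestic normalization dictates);
departures beyond 0.10, poor residuals, baseline shifts, low
signal-to-background, isosbestic drift and expired stability windows all
raise named flags rather than silently altering results.

File-based workflows use `read_spectra_table()` /
`load_reference_library()` / `run_unmix()`, or the CLI:

```sh
Rscript inst/cli/uvmix.R simulate --out fixture --seed 4
Rscript inst/cli/uvmix.R validate-library --library fixture/reference_library
```

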