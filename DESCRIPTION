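Package: srftir
Title: Chemometrics for Synchrotron FTIR Spectromicroscopy of Microbial
    Stress Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of synchrotron-radiation Fourier-transform infrared
    (SR-FTIR) spectromicroscopy maps of bacterial monolayers under osmotic
    and matric (drought) stress.  Provides readers and writers for wide-CSV
    and JCAMP-DX spectra, signal-to-noise quality filtering, Kohler extended
    multiplicative signal correction (EMSC), vector normalisation,
    Savitzky-Golay second-derivative quantitation under the Beer-Lambert
    law, characteristic-peak compound identification with z-tests against
    control spectra, PC-LDA ordination with back-projected loadings and
    cluster-vector spectra, solute-potential and specific-growth-rate
    physiology calculations, and seeded generators of synthetic spectral
    maps and growth curves used as the validation test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    signal,
    stats,
    utils
Suggests:
    MASS,
    cluster,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
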