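Package: isoedir
Title: Isotope-Edited Infrared Difference Spectroscopy of DNA Duplexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for isotope-edited Fourier-transform infrared (FTIR)
    analysis of DNA duplexes carrying site-specific 13C2-labelled thymine
    bases. Generates synthetic light/heavy replicate spectra from additive
    band models, reads and writes two-column CSV and a JCAMP-DX subset,
    implements multipoint baseline correction and normalization to the
    phosphate band, computes light-minus-heavy difference spectra with
    replicate statistics and noise lines, fits multi-component carbonyl
    bands to quantify isotope shifts and minor-band splitting (a marker
    for Hoogsteen A-T base pairs), calibrates carbonyl frequency against
    the Gutmann solvent acceptor number to infer the hydrogen-bonding
    environment of the thymine C2 carbonyl, and performs bookkeeping over
    externally computed counterpoise-corrected interaction energies and
    atoms-in-molecules bond critical point densities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
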