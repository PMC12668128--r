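Package: conformfp
Title: Conformational Fingerprinting of Rare DNA States and Mutational
    Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the sequence-specific propensities of
    rare DNA conformational states and comparing the resulting
    "conformational fingerprints" against trinucleotide (SBS96) cancer
    mutational signatures.  Includes Lorentzian deconvolution of 1D NMR
    spectra, Henderson-Hasselbalch apparent-pKa titration analysis with
    nearest-neighbour additivity cycles, three-state Bloch-McConnell
    fitting of off-resonance R1rho relaxation-dispersion data with
    Monte-Carlo uncertainties, two-state UV melting thermodynamics, and
    Jensen-Shannon-divergence scoring of fingerprints against signature
    catalogs with a resampled null distribution.  A synthetic-data module
    emulates every experimental input so the full pipeline can be
    exercised and validated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    withr,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
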