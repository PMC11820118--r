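Package: pldscale
Title: Scaling Laws for Phase Separation of Prion-Like Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing liquid-liquid phase separation of
    prion-like low-complexity domains (PLDs) with data-driven scaling
    laws. Extracts coexisting densities from slab density profiles,
    fits binodals and critical points via the law of coexisting
    densities (3.06 exponent) and rectilinear diameters, fits and
    applies mutation-class scaling laws for changes in the critical
    solution temperature, computes the aromatic patterning order
    parameter sigma-aro, evaluates the energy terms of a residue-level
    coarse-grained protein model (harmonic bonds, Debye-Hueckel
    electrostatics, Wang-Frenkel pairs), designs composition-preserving
    sequence variants, and generates synthetic datasets with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
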