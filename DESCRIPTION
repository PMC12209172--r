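Package: nucleoFRET
Title: Single-Particle FRET Analysis of Nucleosome Conformational States
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-particle FRET (spFRET) measurements
    of fluorescently labelled nucleosomes diffusing in solution. Computes
    crosstalk-corrected proximity ratios from two-channel burst intensities,
    rejects bright/slow aggregates, builds replicate-averaged proximity-ratio
    profiles, decomposes them into Gaussian subpopulations corresponding to
    intact, reorganized and open nucleosome states, fits one-site binding
    isotherms to fluorescence titrations to estimate dissociation constants,
    interpolates half-saturation points of gel-shift binding series, and
    compares single-complex acceptor-intensity distributions across gel bands
    to infer nucleosome stoichiometry. A synthetic-data generator emulates
    every measurement type so the full pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'crosstalk.R'
    'synthetic-data.R'
    'burst-processing.R'
    'mixture.R'
    'binding.R'
    'stoichiometry.R'
    'scenarios.R'
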