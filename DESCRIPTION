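Package: AbetaFingerprint
Title: Epitope and Modification Fingerprinting of Anti-Amyloid-Beta Antibodies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for fingerprinting the sequence and modification
    specificity of anti-amyloid-beta (Abeta) antibodies from peptide
    microarray, titration, biolayer-interferometry and
    immunoprecipitation-mass-spectrometry readouts. Implements peptide
    library design (overlapping tiling windows, deep positional
    substitution scans, post-translational-modification variant panels),
    wildtype-normalized deep-mutational-scan matrices with
    dominant-negative and core-motif calling, familial-AD and rodent
    variant impact reports, Boltzmann dose-response (EC50) fitting, 1:1
    Langmuir kinetic simulation and global fitting (kon, koff, KD),
    theoretical monoisotopic/average mass and isoelectric-point
    calculators for modified Abeta variants, MALDI peak assignment
    against an Abeta variant panel, and seedable synthetic-data
    generators for every input so the whole pipeline is testable without
    raw array images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
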