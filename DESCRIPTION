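Package: phenolProfiler
Title: Extraction Optimization, MSn Annotation and Quantification of
    Plant Phenolics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A three-stage pipeline for profiling phenolic compounds in
    botanical extracts by ultrasound-assisted extraction and
    HPLC-PDA-ESI-MSn. Stage one builds central composite circumscribed
    (CCC) response-surface designs, fits the second-order polynomial to
    total-phenolic yields by ordinary least squares on coded factors,
    and locates the constrained optimum of the fitted surface. Stage two
    annotates negative-mode MSn spectral trees with compound names via a
    neutral-loss and marker-ion decision cascade covering
    hydroxycinnamic acid esters, hydroxybenzoic acids, flavones and
    hydroxy fatty acids. Stage three fits calibration curves, computes
    LOD/LOQ, recovery and RSD validation statistics, quantifies
    compounds lacking authentic standards through relative response
    factors against internal standards, and aggregates contents per
    compound class. A synthetic-data generator reproduces the
    statistical structure of each stage so the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'spectral-tree.R'
    'loss-rules.R'
    'annotate.R'
    'ccc-design.R'
    'quant.R'
    'synthgen.R'
    'io.R'
    'phenolProfiler-package.R'
    'pipeline.R'
    'surface-fit.R'
    'surface-optimize.R'
RoxygenNote: 7.3.3
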