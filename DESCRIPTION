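Package: regvarRF
Title: Random-Forest Scoring, Interpretation and Ranking of Non-Coding
    Regulatory Variants
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to score non-coding variants for regulatory impact with a
    balanced random-forest classifier, and to make the scores interpretable
    and usable in disease-gene analyses.  The package constructs matched
    negative-control sets (random, local, and cytogenetic-band/biotype
    adjusted), trains forests with per-tree balanced resampling, evaluates
    them with leakage-free band-aware cross-validation, decomposes each
    variant's score into additive per-feature contributions along decision
    paths (out-of-bag for training variants), clusters contribution profiles,
    and ranks candidate variants after filtering on regulatory-region target
    genes.  A synthetic-data generator emulates the genome layout, annotation
    tracks and variant classes needed to exercise the full pipeline without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    ranger,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    VariantAnnotation,
    SummarizedExperiment,
    data.table,
    jsonlite,
    cluster,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotation.R'
    'sampling.R'
    'model.R'
    'evaluation.R'
    'core-io.R'
    'ranking.R'
    'synthetic-data.R'
    'cli.R'
    'explain.R'
    'interpretation.R'
    'utils.R'
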