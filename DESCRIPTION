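Package: fattaste
Title: Oral Fatty-Acid Taste Thresholds, Papillae Microbiota and Multiblock PLS-DA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools linking orosensory fatty-acid detection thresholds to the
    microbiota of the circumvallate papillae and to salivary variables. Implements
    the ascending 3-alternative forced-choice (3-AFC) threshold procedure and
    taster/non-taster classification, microbiome feature-table stages (low-count
    filtering, rank aggregation, relative abundance, Shannon diversity,
    rarefaction, Bray-Curtis principal coordinates, taxon-covariate regression,
    and a two-class LDA effect-size screen), and multiblock partial least squares
    discriminant analysis (MB-PLS-DA) with block-balanced scaling, block
    importances, variable importance in the projection (VIP) selection and
    Mann-Whitney post-hoc tests. A seeded synthetic-cohort generator with planted
    taster/non-taster effects makes every stage testable end to end without
    subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    mixOmics
Config/testthat/edition: 3
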