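Package: proxidiff
Title: Differential Proximity-Labeling Interactomics with Gene-Set Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for BioID proximity-labeling interactome
    studies built around a five-condition experimental design
    (bait-ligase + biotin, ligase-only + biotin, bait without biotin,
    biotin-only, and untreated cells). Implements protein-level median
    normalization, group-vs-group contrasts with Benjamini-Hochberg
    correction, and a triple-contrast corrected interaction effect that
    subtracts biotin-background and bait over-expression artifacts from
    the main bait-vs-ligase comparison. Also provides a weighted
    Kolmogorov-Smirnov gene-set enrichment engine with phenotype
    permutation (ES, NES, nominal p, FDR q), minimal co-expression
    module detection (soft-threshold adjacency, topological overlap,
    average-linkage modules, eigengene-trait correlation), gene-set
    integration arithmetic (dual-condition Venn logic, interactor
    mapping, minimum-membership filters, exact hypergeometric list
    overlap), and a synthetic-data generator so every stage runs and is
    verified offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    mclust,
    jsonlite
Config/testthat/edition: 3
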