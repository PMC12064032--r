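Package: tilemave
Title: Tiled Deep Mutational Scanning of Protein Abundance and Interaction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-assay deep mutational scanning of tiled
    site-saturation variant libraries, as used to dissect protein stability
    (DHFR protein-fragment complementation) and protein-protein interaction
    (yeast two-hybrid) effects of missense and nonsense variants. Provides a
    synthetic-data generator for tiled libraries under growth selection,
    paired-end amplicon merging and codon-level variant calling, Enrich2-style
    enrichment scores normalised to synonymous wild-type variants with
    random-effects replicate combination, per-tile rescaling of bimodal
    abundance scores, per-position aggregation and heatmap matrices,
    structural features (relative solvent accessibility, interface contacts),
    and evaluation against clinical classifications and stability/conservation
    predictors via ROC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    metafor,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
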