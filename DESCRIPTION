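Package: eqtlhot
Title: Combinatorial eQTL Mapping and Trans-Regulatory Hotspot Detection
    for Biparental Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for expression quantitative trait locus (eQTL) analysis
    in biparental F2 and recombinant-inbred-line populations: Kosambi
    linkage-map construction anchored to physical marker positions,
    interval mapping, inclusive composite interval mapping and a
    genome-wide composite interval mapping scan with permutation-derived
    LOD thresholds, two-of-three-method consensus merging of cis and
    trans signals, percentile-based trans-regulatory hotspot detection,
    Pearson co-expression networks, Fisher-test term enrichment with a
    multiply-by-genes Bonferroni convention, and a candidate-variant
    prioritization cascade. Ships a seeded cross simulator with planted
    cis effects and trans hotspots for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
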