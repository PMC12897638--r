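Package: twinmeth
Title: Two-Tier Differential Methylation Analysis for Monozygotic Twin-Pair WGBS Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for calling differentially methylated CpG sites (dmCpGs)
    from whole-genome bisulfite sequencing of matched monozygotic twin pairs
    assigned to control and nutrient-restricted treatments. Implements a
    beta-binomial Wald test for the group contrast and for single twin-pair
    contrasts (with local smoothing), a two-tier calling scheme combining
    group-level thresholds with k-of-n cross-pair consensus replication,
    interval-based co-annotation of sites to promoters, exons, introns and
    CpG islands, regional summary tables, top-site rankings, a Liver Sparing
    Index for within-pair phenotype severity, and hypergeometric
    over-representation analysis with rich factors. A seeded synthetic
    twin-pair methylome generator provides ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
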