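Package: cazymer
Title: CAZyme Profiling, Polysaccharide Utilization Locus Detection and
    Genome-Bin Functional Analysis for Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of assembled shotgun metagenomes with a
    focus on plant-fiber degrading communities such as the ruminant gut.
    Annotates carbohydrate-active enzymes (CAZymes) from HMM domain-hit
    tables using a dbCAN-style filtering cascade with per-protein overlap
    resolution, classifies glycoside hydrolases into substrate categories,
    detects polysaccharide utilization loci (PULs) anchored on SusC-SusD
    tandem gene pairs, profiles genome bins (QC gating, relative abundance,
    CAZyme capability matrices, cellulosome screening), screens bins for
    volatile fatty acid pathway marker genes, compares CAZyme family
    profiles between metagenomes with Fisher's exact test and
    Benjamini-Hochberg FDR, and assigns lowest-common-ancestor taxonomy
    from similarity-hit tables.  A seeded synthetic-data generator with
    planted ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
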