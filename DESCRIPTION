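Package: slafmap
Title: F2 Linkage Mapping, QTL Scanning and Heterozygote-Advantage Scoring
    for SLAF-Seq Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for genetic analysis of biparental F2 populations derived
    from doubled-haploid parents and genotyped with reduced-representation
    sequencing (SLAF-seq). Covers marker quality control with segregation
    pattern classification and distortion tests, linkage-map construction
    (EM recombination-fraction estimation, MLOD grouping, minimum-spanning-tree
    marker ordering, singleton error blanking, k-nearest-neighbour imputation,
    Kosambi distances), Haley-Knott interval mapping with cofactors and
    permutation thresholds for quantitative and binary traits, and a
    favorable-allelic-variant (FAV) procedure that scores heterozygote
    enrichment across phenotype bins to flag markers associated with
    heterosis. A synthetic-data module simulates F2 populations with known
    linkage structure, observation noise and trait architecture so the whole
    pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
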