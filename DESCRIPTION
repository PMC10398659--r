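Package: temeth
Title: Transposable-Element Methylome Change Scoring, Hypo-DMR Calling,
    and Target-Overlap Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of whole-genome bisulfite sequencing cytosine reports
    for transposable-element (TE) silencing studies. Computes per-TE
    coverage-weighted methylation-change scores between genotypes, calls
    CG-hypomethylated differentially methylated regions (hypo-DMRs) and
    RdDM-target bins on a fixed 50-bp genome tiling, quantifies the overlap
    of the two target sets with a hypergeometric test and a size-matched
    shuffle null, and computes methylation metaprofiles anchored at target
    regions. Includes a seeded generator of synthetic per-cytosine
    methylation data over a toy genome with TE families carrying coding and
    noncoding segments under a panel of methylation-mutant genotype
    scenarios, and a reproducible end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
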