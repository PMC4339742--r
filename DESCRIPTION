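Package: phenomarker
Title: Genetic Markers and Maps from High-Throughput Molecular Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Converts multimodal molecular phenotypes (gene expression,
    protein or metabolite abundance) measured on experimental crosses
    between diploid inbred strains into discrete genetic markers by
    Gaussian mixture modeling, filters unreliable candidates with
    QTL-based quality control (no-QTL, multiple-QTL, epistasis and
    genotype-by-environment checks), and uses the survivors to saturate
    an existing genetic map or to build one de novo.  Includes single-
    and two-locus genome scans by Haley-Knott regression, recombination
    fraction estimation, linkage grouping with mirrored-group merging
    for parent-free phasing, marker ordering, Haldane and Kosambi map
    functions, a full synthetic-data generator with ground truth, and
    readers/writers for rotated-CSV ("csvr") cross files and GFF3 maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    mclust,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
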