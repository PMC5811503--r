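Package: gwabnet
Title: Network-Based Boosting of GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Prioritizes candidate phenotype genes by boosting GWAS
    summary statistics (per-SNP P-values) over a weighted co-functional
    gene network. SNPs are assigned to genes by chromosomal proximity,
    per-gene association evidence is converted to log odds, and a soft
    guilt-by-association score summed over network neighbours above a
    contributor P-value threshold is added under a naive Bayes
    assumption. Rankings are evaluated by the partial AUC before 5%
    false-positive rate against a reference gene set, compared with a
    randomized-network null, and the contributor threshold is selected
    by a grid scan. Includes a synthetic-data generator with planted
    network modules for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    methods,
    tools,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
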