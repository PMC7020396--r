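Package: gwaspath
Title: Pathway Association Analysis of GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Collapses GWAS SNP-trait associations into linkage-block tagSNPs
    using pairwise linkage-disequilibrium data, transfers tagSNP allele
    effects and p-values to nearby genes within a physical window, and scores
    user-supplied metabolic pathways with a weighted running-sum enrichment
    statistic against a bootstrap null distribution of resampled gene
    effects, reporting per-pathway enrichment scores, z-scores, p-values,
    Storey/Benjamini-Hochberg q-values, and running-sum rugplots. Inputs are
    TASSEL-style association statistics, allele effects and LD tables, GFF3
    gene annotations, and tab-delimited pathway definitions. Includes a
    synthetic-data generator with planted pathway signal for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    IRanges,
    S4Vectors,
    jsonlite,
    parallel,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
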