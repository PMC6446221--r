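Package: stressgwas
Title: Stress-Resistance Phenomics and Mixed-Model GWAS for Yeast Strain
    Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links stress-resistance phenotypes of Saccharomyces cerevisiae
    strain collections to their genetic variants. Extracts five growth
    parameters (lag, maximum specific growth rate, amplitude, half-maximum
    time, area under the curve) from dose-response growth curves, scores
    strains by performance (cross-sectional) and robustness (retention under
    increasing inhibitory levels), and ranks them per condition with rank
    variability and parameter-influence analyses. Runs EMMA-style mixed-model
    association of the rankings against core-genome SNP/indel markers grouped
    into linkage-disequilibrium blocks and against copy-number-variation
    gain/loss interval markers, sets significance cutoffs from the departure
    of observed from expected P-value quantiles, assigns gene-level P values
    including upstream regulatory regions, and decomposes the relative
    contribution of SNP, gain and loss evidence per gene category.
    Protein-interaction modules enriched for associated genes are discovered
    by maximal-clique enrichment with a random-gene-list null, and cohort
    comparisons use rank-based tests with FDR control. A synthetic-data
    generator reproduces the statistical structure of all inputs so the full
    pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
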