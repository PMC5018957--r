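Package: popsnp
Title: Multi-Caller SNP Consensus and Population Genomics for Inbred Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Consensus single-nucleotide-polymorphism discovery from
    multiple variant callers with hard depth and allele-fraction filters,
    concordance classification against an independent call set, construction
    of missing-data-free bi-allelic genotype matrices across inbred
    accessions, and downstream population genomics: p-distance
    neighbour-joining trees, principal component analysis with Patterson
    normalisation, STRUCTURE-style Bayesian admixture with Evanno delta-K
    model selection, sliding-window haplotype diversity and Hudson F_ST, and
    linkage-disequilibrium decay and Gabriel-style block detection. Includes
    a seedable synthetic-data generator (Balding-Nichols structured
    populations with a mosaic-donor linkage model and caller error profiles)
    so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
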