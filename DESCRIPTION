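Package: evorank
Title: Evolutionary Context and Rank-Based Prioritization of GWAS Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-site evolutionary context for human genomic
    positions from a multi-species alignment on a time-calibrated phylogeny
    (per-site substitution rate by uniform-cost small parsimony, and the
    evolutionary timespan over which a position has existed in the lineages
    of the tree), and uses that context to re-rank genome-wide association
    study (GWAS) results. The E-rank score (P/MAF) * 1/(Kr * Kt) adjusts an
    association P-value by the minor allele frequency and the within-set
    ranks of the site's evolutionary rate and timespan, promoting variants
    at conserved, long-lived positions. Includes readers for Newick trees
    and MAF/FASTA/TSV alignment columns, an in-memory association store
    with filtering, aggregation, sorting and keyword search, rank-comparison
    plot data, and a seeded simulator for trees, alignment columns and
    association tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    Biostrings,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
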