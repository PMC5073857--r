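# Shared fixtures, built in code.

# The 4-taxon worked tree used throughout: two cherries of 100 My joined by
# 400 My internal edges; total time 1200 My.
toyTree <- function() {
  readTimeTree("((H:100,B:100):400,(C:100,D:100):400);")
}

toyColumn <- function(bases, ref = "H") {
  SiteColumn(bases, ref)
}

# Five valid association records (P spread over 1e-8 .. 0.04) for filter
# and summary semantics; mirrors the shipped extdata fixture.
toyAssociations <- function() {
  data.frame(
    rsid = c("rs1001", "rs1002", "rs1003", "rs1004", "rs1005"),
    pmid = c("20000001", "20000001", "20000002", "20000002", "20000003"),
    study_title = c("GWAS of type 1 diabetes", "GWAS of type 1 diabetes",
                    "GWAS of myocardial infarction",
                    "GWAS of myocardial infarction", "GWAS of height"),
    phenotype = c("Type 1 diabetes", "Type 1 diabetes",
                  "Myocardial infarction", "Myocardial infarction",
                  "Height"),
    phenotype_category = c("Metabolic", "Metabolic", "Cardiovascular",
                           "Cardiovascular", "Anthropometric"),
    p_value = c(1e-8, 1e-6, 1e-4, 1e-3, 0.04),
    allele = c("A", "C", "G", "T", "A"),
    maf = c(0.30, 0.12, 0.45, 0.05, 0.25),
    chrom = c("chr6", "chr6", "chr1", "chr2", "chr3"),
    pos = c(31540141L, 31543031L, 1005001L, 2005002L, 3005003L),
    region_type = c("missense", "intron", "intron", "3'UTR", "intergenic"),
    gene = c("LTA", "TNF", "", "FTO", ""),
    aa_change = c("T60N", "", "", "", ""),
    polyphen2 = c("benign", "", "", "", ""),
    sift = c("tolerated", "", "", "", ""),
    evod = c("neutral", "", "", "", ""),
    stringsAsFactors = FALSE)
}

# A ranking-ready record table: associations with evolutionary context.
toyRankable <- function() {
  df <- toyAssociations()[, c("rsid", "p_value", "maf")]
  df$evol_rate <- c(0.0, 0.4, 1.2, 2.5, 0.1)
  df$evol_span <- c(1.0, 0.9, 0.3, 0.15, 0.95)
  df
}

shippedFixture <- function() {
  system.file("extdata", "toy_associations.tsv", package = "evorank")
}
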