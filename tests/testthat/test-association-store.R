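test_that("ingest keeps valid rows and reports every rejection", {
  a <- loadAssociations(toyAssociations())
  expect_equal(nrow(associationRecords(a)), 5L)
  expect_equal(nrow(rejectedRecords(a)), 0L)

  # shipped fixture adds a P = 0.2 row and a duplicate-key row
  a2 <- loadAssociations(shippedFixture())
  expect_equal(nrow(associationRecords(a2)), 5L)
  rej <- rejectedRecords(a2)
  expect_equal(nrow(rej), 2L)
  expect_true(any(grepl("inclusion threshold", rej$reason)))
  expect_true(any(grepl("duplicate", rej$reason)))
  expect_equal(rej$rsid[grepl("duplicate", rej$reason)], "rs1001")
})

test_that("ingest derives log10_p and rejects unparsable P-values", {
  df <- toyAssociations()
  df$p_value <- as.character(df$p_value)
  df$p_value[3] <- "not-a-number"
  a <- loadAssociations(df)
  expect_equal(nrow(associationRecords(a)), 4L)
  expect_equal(rejectedRecords(a)$reason, "unparsable P-value")
  rec <- associationRecords(a)
  expect_equal(rec$log10_p, signif(log10(rec$p_value), 6))
  expect_true(all(rec$log10_p <= log10(0.05)))
})

test_that("missing required columns are named in the error", {
  df <- toyAssociations()
  df$pmid <- NULL
  expect_error(loadAssociations(df), "pmid")
})

test_that("rsid/pmid indexes return the right records", {
  a <- loadAssociations(toyAssociations())
  expect_equal(nrow(getSnp(a, "rs1001")), 1L)
  expect_equal(getSnp(a, "rs1003")$p_value, 1e-4)
  expect_equal(nrow(getStudy(a, "20000002")), 2L)
})

test_that("filters follow the fixture counts and conjunctive semantics", {
  a <- loadAssociations(toyAssociations())
  expect_equal(nrow(associationRecords(filterRecords(a, maxP = 1e-5))), 2L)
  expect_equal(nrow(associationRecords(filterRecords(a))), 5L)
  expect_equal(associationRecords(filterRecords(a, gene = "LTA"))$rsid,
               "rs1001")
  expect_equal(associationRecords(filterRecords(a, gene = "lta"))$rsid,
               "rs1001")   # case-insensitive
  both <- filterRecords(a, maxP = 1e-3, regionType = "intron")
  expect_equal(associationRecords(both)$rsid, c("rs1002", "rs1003"))
  expect_error(filterRecords(a, regionType = "exonish"), "valid tokens")
})

test_that("the E-score filter needs rankings computed for the set", {
  a <- loadAssociations(toyAssociations())
  expect_error(filterRecords(a, maxEScore = 0.01), "rankings")
  rec <- associationRecords(a)
  rec$evol_rate <- c(0, 0.4, 1.2, 2.5, 0.1)
  rec$evol_span <- c(1, 0.9, 0.3, 0.15, 0.95)
  rk <- computeRankings(rec)
  cut <- sort(rankedTable(rk)$e_score)[3]
  out <- filterRecords(a, maxEScore = cut, rankings = rk)
  expect_equal(nrow(associationRecords(out)), 3L)
})

test_that("filter composition equals filtering by the conjunction", {
  set.seed(55)
  sim <- simulateAssociationTable(simulationConfig(nSnps = 200L, seed = 55))
  a <- loadAssociations(sim$table)
  phen <- unique(associationRecords(a)$phenotype)
  genes <- setdiff(unique(associationRecords(a)$gene), "")
  for (i in 1:40) {
    c1 <- list(maxP = stats::runif(1, 1e-6, 0.05))
    c2 <- switch(sample(3, 1),
                 list(phenotype = sample(phen, 1)),
                 list(gene = sample(genes, 1)),
                 list(regionType = sample(regionTypeVocabulary()[1:7], 1)))
    seq2 <- do.call(filterRecords, c(list(do.call(
      filterRecords, c(list(a), c1))), c2))
    joint <- do.call(filterRecords, c(list(a), c1, c2))
    expect_equal(associationRecords(seq2), associationRecords(joint))
  }
})

test_that("per-SNP summaries count distinct studies and phenotypes", {
  df <- toyAssociations()
  extra <- df[1, ]
  extra$pmid <- "20000009"
  extra$phenotype <- "Myocardial infarction"
  extra$p_value <- 1e-3
  a <- loadAssociations(rbind(df, extra))
  s <- summarizeBySnp(a)
  r1 <- s[s$rsid == "rs1001", ]
  expect_equal(r1$n_studies, 2L)
  expect_equal(r1$n_phenotypes, 2L)
  expect_equal(r1$min_p, 1e-8)
  expect_equal(r1$max_p, 1e-3)
  single <- s[s$rsid == "rs1005", ]
  expect_equal(single$n_studies, 1L)
  expect_equal(single$min_p, single$max_p)
  # per-rsid record counts add up to the set size
  rec <- associationRecords(a)
  expect_equal(sum(table(rec$rsid)), nrow(rec))
  expect_equal(nrow(s), length(unique(rec$rsid)))
})

test_that("per-study summaries count distinct SNPs, phenotypes, genes", {
  df <- data.frame(
    rsid = c("rsA", "rsA", "rsB", "rsC"),
    pmid = "20000099",
    phenotype = c("Height", "Body mass index", "Height", "Height"),
    p_value = c(1e-4, 1e-3, 1e-5, 0.01),
    gene = c("GENE1", "GENE1", "", "GENE2"),
    stringsAsFactors = FALSE)
  s <- summarizeByStudy(loadAssociations(df))
  expect_equal(s$n_snps, 3L)
  expect_equal(s$n_phenotypes, 2L)
  expect_equal(s$n_genes, 2L)
  expect_equal(nrow(summarizeByStudy(
    filterRecords(loadAssociations(df), maxP = 1e-10))), 0L)
  s2 <- summarizeByStudy(loadAssociations(toyAssociations()))
  expect_equal(s2$pmid, sort(unique(toyAssociations()$pmid)))
})

test_that("sorting is stable, keyed, and puts missing values last", {
  a <- loadAssociations(toyAssociations())
  byP <- associationRecords(sortRecords(a, "p_value"))
  expect_equal(byP$p_value, sort(byP$p_value))
  expect_equal(byP$rsid[1], "rs1001")
  byPdesc <- associationRecords(sortRecords(a, "p_value",
                                            decreasing = TRUE))
  expect_equal(byPdesc$p_value, rev(sort(byPdesc$p_value)))
  # empty genes sort last in both directions
  byGene <- associationRecords(sortRecords(a, "gene"))
  expect_true(all(nzchar(byGene$gene[1:3])))
  expect_true(all(!nzchar(byGene$gene[4:5])))
  byGeneD <- associationRecords(sortRecords(a, "gene", decreasing = TRUE))
  expect_true(all(!nzchar(byGeneD$gene[4:5])))
  # stability: sorting twice changes nothing
  twice <- sortRecords(sortRecords(a, "maf"), "maf")
  expect_equal(associationRecords(twice),
               associationRecords(sortRecords(a, "maf")))
  # permutation: nothing created or lost
  expect_setequal(byP$rsid, associationRecords(a)$rsid)
  expect_error(sortRecords(a, "nonsense"), "valid keys")
})

test_that("keyword search is a case-insensitive substring match", {
  a <- loadAssociations(toyAssociations())
  expect_equal(nrow(associationRecords(keywordSearch(a, "diabetes"))), 2L)
  expect_equal(nrow(associationRecords(keywordSearch(a, "DIABETES"))), 2L)
  expect_equal(nrow(associationRecords(keywordSearch(a, "LTA"))), 1L)
  expect_equal(nrow(associationRecords(keywordSearch(a, "zzz-no-match"))),
               0L)
  expect_error(keywordSearch(a, "   "), "empty")
})
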