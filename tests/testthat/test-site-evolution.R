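test_that("pruning to present taxa gives the minimal spanning subtree", {
  tr <- toyTree()
  # identity: all present
  allp <- pruneToPresent(tr, toyColumn(c(H = "A", B = "A", C = "G",
                                         D = "G")))
  expect_equal(totalTreeTime(allp), 1200)
  # a cherry: the two leaf edges only
  hb <- pruneToPresent(tr, toyColumn(c(H = "A", B = "A", C = "-", D = "-")))
  expect_setequal(leafLabels(hb), c("H", "B"))
  expect_equal(totalTreeTime(hb), 200)
  # across the root: both 400 My internal edges collapse into leaf edges
  hc <- pruneToPresent(tr, toyColumn(c(H = "A", B = "-", C = "G", D = "-")))
  expect_setequal(leafLabels(hc), c("H", "C"))
  expect_equal(totalTreeTime(hc), 1000)
  # reference alone: a valid single-leaf tree, not an error
  ho <- pruneToPresent(tr, toyColumn(c(H = "A", B = "-", C = "-", D = "-")))
  expect_equal(leafLabels(ho), "H")
  expect_equal(totalTreeTime(ho), 0)
  # MISSING taxa are absent for span purposes, same as GAP
  hn <- pruneToPresent(tr, toyColumn(c(H = "A", B = "N", C = "-", D = "-")))
  expect_equal(leafLabels(hn), "H")
  # a column taxon not in the tree is caught at use time
  expect_error(pruneToPresent(tr, toyColumn(c(H = "A", Z = "A"))),
               "absent from tree")
})

test_that("parsimony count matches hand-derived cases and bounds", {
  tr <- toyTree()
  expect_equal(countSubstitutionsFitch(
    tr, toyColumn(c(H = "A", B = "A", C = "G", D = "G"))), 1L)
  expect_equal(countSubstitutionsFitch(
    tr, toyColumn(c(H = "A", B = "G", C = "A", D = "G"))), 2L)
  expect_equal(countSubstitutionsFitch(
    tr, toyColumn(c(H = "T", B = "T", C = "T", D = "T"))), 0L)
  # pruning contract: a leaf without a base is an error
  expect_error(countSubstitutionsFitch(
    tr, toyColumn(c(H = "A", B = "-", C = "A", D = "A"))),
    "pruned")
})

test_that("parsimony count equals the exhaustive oracle on random trees", {
  for (n in 3:5) {
    tt <- randomTimeTree(n, seed = 100 + n)
    set.seed(200 + n)
    labs <- allLeafLabelings(n)
    pick <- sample(nrow(labs), 40L)
    for (i in pick) {
      bases <- stats::setNames(labs[i, ], leafLabels(tt))
      col <- SiteColumn(bases, leafLabels(tt)[1L])
      expect_equal(countSubstitutionsFitch(tt, col),
                   bruteForceParsimony(tt@phylo, bases))
    }
  }
})

test_that("parsimony count agrees with an independent Fitch implementation", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  tt <- randomTimeTree(8, seed = 7)
  for (i in 1:25) {
    bases <- stats::setNames(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                             leafLabels(tt))
    col <- SiteColumn(bases, leafLabels(tt)[1L])
    pd <- phangorn::phyDat(matrix(bases, ncol = 1,
                                  dimnames = list(names(bases), NULL)),
                           type = "DNA")
    expect_equal(countSubstitutionsFitch(tt, col),
                 as.integer(phangorn::parsimony(tt@phylo, pd)))
  }
})

test_that("evolutionary rate divides the count by pruned tree time in Gy", {
  tr <- toyTree()
  expect_equal(evolRate(tr, toyColumn(c(H = "A", B = "A", C = "G",
                                        D = "G"))), 1 / 1.2)
  expect_equal(evolRate(tr, toyColumn(c(H = "A", B = "A", C = "A",
                                        D = "A"))), 0)
  # rate uses the PRUNED subtree's time: H,C present -> 1 sub / 1.0 Gy
  expect_equal(evolRate(tr, toyColumn(c(H = "A", B = "-", C = "G",
                                        D = "-"))), 1)
  # reference-only position: undefined, never 0
  expect_true(is.na(evolRate(tr, toyColumn(c(H = "A", B = "-", C = "-",
                                             D = "-")))))
})

test_that("evolutionary span is spanning-subtree time over full-tree time", {
  tr <- toyTree()
  expect_equal(evolSpan(tr, toyColumn(c(H = "A", B = "A", C = "G",
                                        D = "G"))),
               c(fraction = 1, my = 1200))
  expect_equal(evolSpan(tr, toyColumn(c(H = "A", B = "A", C = "-",
                                        D = "-"))),
               c(fraction = 200 / 1200, my = 200))
  expect_equal(evolSpan(tr, toyColumn(c(H = "A", B = "-", C = "-",
                                        D = "-"))),
               c(fraction = 0, my = 0))
})

test_that("removing a present taxon never increases the span", {
  tt <- randomTimeTree(7, seed = 31)
  taxa <- leafLabels(tt)
  set.seed(32)
  for (rep in 1:20) {
    keep <- c(taxa[1L], sample(taxa[-1L], sample(1:6, 1L)))
    res <- stats::setNames(ifelse(taxa %in% keep, "A", "-"), taxa)
    f1 <- evolSpan(tt, SiteColumn(res, taxa[1L]))[["fraction"]]
    drop1 <- setdiff(keep, taxa[1L])
    if (!length(drop1)) next
    res2 <- res
    res2[sample(drop1, 1L)] <- "-"
    f2 <- evolSpan(tt, SiteColumn(res2, taxa[1L]))[["fraction"]]
    expect_lte(f2, f1)
    expect_gte(f1, 0); expect_lte(f1, 1)
  }
})

test_that("conservation classes follow the documented rate boundaries", {
  expect_equal(classifyConservation(c(0, 0.5, 1.0, 1.000001, 2.3)),
               c("ultra", "well", "well", "less", "less"))
  expect_equal(classifyConservation(NA_real_), "unclassified")
  expect_error(classifyConservation(-0.1), ">= 0")
})

test_that("siteEvolution bundles rate, span, count and class coherently", {
  tr <- toyTree()
  se <- siteEvolution(tr, toyColumn(c(H = "A", B = "A", C = "G", D = "G")))
  expect_equal(se@evolRate, 1 / 1.2)
  expect_equal(se@nSubstitutions, 1L)
  expect_equal(se@evolSpanFraction, 1)
  expect_equal(se@nPresentTaxa, 4L)
  expect_equal(se@conservationClass, "well")

  solo <- siteEvolution(tr, toyColumn(c(H = "A", B = "-", C = "-",
                                        D = "-")))
  expect_true(is.na(solo@evolRate))
  expect_equal(solo@conservationClass, "unclassified")
  expect_equal(solo@evolSpanFraction, 0)
})

test_that("rating a gapped column equals rating its pre-pruned tree", {
  # pruning idempotence: evolRate prunes internally, so applying it to the
  # already-pruned tree with the same column must give the same rate
  tt <- randomTimeTree(6, seed = 77)
  taxa <- leafLabels(tt)
  res <- stats::setNames(c("A", "G", "-", "A", "-", "T"), taxa)
  col <- SiteColumn(res, taxa[1L])
  pruned <- pruneToPresent(tt, col)
  expect_equal(evolRate(tt, col), evolRate(pruned, col))
  expect_equal(totalTreeTime(pruneToPresent(pruned, col)),
               totalTreeTime(pruned))
})
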