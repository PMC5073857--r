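## Seeded simulator for every input kind the rest of the package consumes:
## ultrametric time trees, alignment columns with known substitution and
## deletion history, and GWAS-style association tables with known signal
## labels. A fixed seed gives byte-identical outputs; per-item substream
## seeds are derived from the base seed as (seed + 7919 * i) mod 2^31 - 1
## so each fixture is reproducible in isolation.

.substreamSeed <- function(seed, i) {
  as.integer((as.double(seed) + 7919 * as.double(i)) %% 2147483647)
}

#' Simulate an ultrametric time-calibrated tree
#'
#' A rooted ultrametric tree from a Yule (pure-birth) process, rescaled so
#' every root-to-leaf path sums to exactly \code{depthMy}. Deterministic per
#' seed.
#'
#' @param nTaxa number of leaves, >= 2.
#' @param depthMy root-to-leaf depth in My.
#' @param seed integer seed.
#' @return a [TimeTree-class] with leaves \code{t1..tN} (\code{t1} is the
#'   conventional reference taxon of downstream simulations).
#' @examples
#' tr <- simulateTimeTree(8, 100, seed = 1)
#' totalTreeTime(tr)
#' @export
simulateTimeTree <- function(nTaxa, depthMy, seed = 1L) {
  if (nTaxa < 2L) stop("nTaxa must be >= 2", call. = FALSE)
  if (depthMy <= 0) stop("depthMy must be > 0", call. = FALSE)
  set.seed(seed)
  phy <- if (nTaxa == 2L) {
    ape::read.tree(text = sprintf("(t1:%g,t2:%g);", depthMy, depthMy))
  } else {
    p <- ape::rphylo(nTaxa, birth = 1, death = 0)
    p$tip.label <- paste0("t", seq_len(nTaxa))
    depths <- ape::node.depth.edgelength(p)
    p$edge.length <- p$edge.length * depthMy / max(depths[seq_len(nTaxa)])
    p
  }
  TimeTree(phy)
}

#' Simulate one alignment column with known history
#'
#' Evolves a single site down the tree: the root base is uniform on
#' \{A,C,G,T\}; on each branch the substitution count is Poisson with mean
#' \code{rate} (substitutions/site/Gy) times the branch duration in Gy, and
#' each substitution changes the current base uniformly to one of the three
#' other bases (a Jukes-Cantor-like model -- the simplest sufficient to
#' exercise a counting-based rate estimator). Independently, each internal
#' edge deletes its whole subtending clade (all its leaves become GAP) with
#' probability \code{gapProb}; edges ancestral to the reference taxon are
#' exempt, so the reference always retains a base.
#'
#' @param tree a [TimeTree-class].
#' @param rate true rate, substitutions/site/Gy, >= 0.
#' @param gapProb per-internal-edge clade deletion probability in [0, 1).
#' @param seed integer seed.
#' @param referenceTaxon reference leaf label (default first leaf).
#' @param chrom,pos coordinate stamped on the column.
#' @return list with \code{column} (a [SiteColumn-class]) and \code{truth}
#'   (list: \code{rate}, \code{nSubstitutions} -- events on edges surviving
#'   in the pruned tree --, \code{events} data.frame of all substitutions,
#'   \code{deletedClades} list of deleted leaf sets).
#' @export
simulateColumn <- function(tree, rate, gapProb = 0, seed = 1L,
                           referenceTaxon = leafLabels(tree)[1L],
                           chrom = "chrS", pos = 1L) {
  stopifnot(methods::is(tree, "TimeTree"), rate >= 0,
            gapProb >= 0, gapProb < 1)
  phy <- stats::reorder(tree@phylo, "cladewise")
  ntip <- length(phy$tip.label)
  if (!referenceTaxon %in% phy$tip.label)
    stop("reference taxon not in tree", call. = FALSE)
  set.seed(seed)
  root <- ntip + 1L
  nnode <- ntip + phy$Nnode
  state <- character(nnode)
  state[root] <- sample(.BASES, 1L)
  ## leaves under each node, and the root->reference path (exempt edges)
  tipsUnder <- function(node) {
    if (node <= ntip) return(node)
    kids <- phy$edge[phy$edge[, 1L] == node, 2L]
    unlist(lapply(kids, tipsUnder))
  }
  refTip <- match(referenceTaxon, phy$tip.label)
  events <- list()
  deleted <- rep(FALSE, ntip)
  deletedClades <- list()
  for (e in seq_len(nrow(phy$edge))) {    # cladewise: parents before children
    parent <- phy$edge[e, 1L]
    child <- phy$edge[e, 2L]
    b <- state[parent]
    nSub <- stats::rpois(1L, rate * phy$edge.length[e] / 1000)
    if (nSub > 0L) {
      for (s in seq_len(nSub)) {
        newb <- sample(setdiff(.BASES, b), 1L)
        events[[length(events) + 1L]] <-
          data.frame(edge = e, from = b, to = newb,
                     stringsAsFactors = FALSE)
        b <- newb
      }
    }
    state[child] <- b
    if (child > ntip && gapProb > 0) {    # internal edge: clade deletion
      tips <- tipsUnder(child)
      if (!refTip %in% tips && stats::runif(1L) < gapProb) {
        deleted[tips] <- TRUE
        deletedClades[[length(deletedClades) + 1L]] <- phy$tip.label[tips]
      }
    }
  }
  residues <- state[seq_len(ntip)]
  residues[deleted] <- .GAP
  names(residues) <- phy$tip.label
  column <- SiteColumn(residues, referenceTaxon, chrom = chrom, pos = pos)
  ## substitutions observable at the leaves: events on edges all of whose
  ## descendant leaves survive at least partially
  surviving <- !deleted
  obs <- 0L
  for (e in seq_len(nrow(phy$edge))) {
    tips <- tipsUnder(phy$edge[e, 2L])
    if (any(surviving[tips]))
      obs <- obs + sum(vapply(events, function(ev) ev$edge == e, logical(1)))
  }
  list(column = column,
       truth = list(rate = rate, nSubstitutions = obs,
                    events = if (length(events)) do.call(rbind, events)
                             else data.frame(edge = integer(),
                                             from = character(),
                                             to = character()),
                    deletedClades = deletedClades))
}

#' Simulate many columns over a rate grid
#'
#' @param tree a [TimeTree-class].
#' @param rates vector of true rates; each simulated \code{nPerRate} times.
#' @param nPerRate columns per rate.
#' @param gapProb clade deletion probability.
#' @param seed base seed; column i uses the documented substream seed.
#' @param referenceTaxon reference leaf label.
#' @return list with \code{columns} (list of [SiteColumn-class]) and
#'   \code{truth} (data.frame: pos, true_rate, n_substitutions).
#' @export
simulateColumns <- function(tree, rates, nPerRate = 1L, gapProb = 0,
                            seed = 1L,
                            referenceTaxon = leafLabels(tree)[1L]) {
  grid <- rep(rates, each = nPerRate)
  cols <- vector("list", length(grid))
  truth <- data.frame(pos = seq_along(grid), true_rate = grid,
                      n_substitutions = NA_integer_)
  for (i in seq_along(grid)) {
    sim <- simulateColumn(tree, grid[i], gapProb = gapProb,
                          seed = .substreamSeed(seed, i),
                          referenceTaxon = referenceTaxon, pos = i)
    cols[[i]] <- sim$column
    truth$n_substitutions[i] <- sim$truth$nSubstitutions
  }
  list(columns = cols, truth = truth)
}

#' Simulation configuration
#'
#' Constructor for [SimulationConfig-class] with the generator's default
#' study conditions: an 8-taxon, 100-My-deep tree; the rate grid
#' \{0, 0.25, 0.5, 1, 2, 4\} substitutions/site/Gy with 200 sites per rate;
#' no gaps; a 100-SNP association table over 5 studies and 10 phenotypes
#' with a 10\% signal fraction.
#'
#' @param nTaxa,treeDepthMy tree shape.
#' @param rateGrid,nSites,gapProb column simulation.
#' @param nSnps,nStudies,nPhenotypes,signalFraction association table shape.
#' @param seed base seed.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(nTaxa = 8L, treeDepthMy = 100,
                             rateGrid = c(0, 0.25, 0.5, 1, 2, 4),
                             gapProb = 0, nSites = 200L, nSnps = 100L,
                             nStudies = 5L, nPhenotypes = 10L,
                             signalFraction = 0.1, seed = 1L) {
  methods::new("SimulationConfig", nTaxa = as.integer(nTaxa),
               treeDepthMy = treeDepthMy, rateGrid = rateGrid,
               gapProb = gapProb, nSites = as.integer(nSites),
               nSnps = as.integer(nSnps), nStudies = as.integer(nStudies),
               nPhenotypes = as.integer(nPhenotypes),
               signalFraction = signalFraction, seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nTaxa, "taxa,", object@treeDepthMy,
      "My depth; rates {", paste(object@rateGrid, collapse = ", "),
      "} x", object@nSites, "sites; gapProb", object@gapProb, ";",
      object@nSnps, "SNPs /", object@nStudies, "studies /",
      object@nPhenotypes, "phenotypes, signal", object@signalFraction,
      "; seed", object@seed, "\n")
})

.PHENOTYPE_POOL <- c(
  "Type 1 diabetes", "Type 2 diabetes", "Myocardial infarction",
  "Coronary artery disease", "Rheumatoid arthritis", "Crohn's disease",
  "Body mass index", "Height", "LDL cholesterol", "Blood pressure",
  "Asthma", "Schizophrenia", "Breast cancer", "Prostate cancer",
  "Bone mineral density", "Fasting glucose")

.GENE_POOL <- c("LTA", "TNF", "HLA-DRB1", "APOE", "TCF7L2", "FTO", "PCSK9",
                "IL23R", "CDKN2A", "BRCA1", "SORT1", "ABO", "")

#' Simulate a GWAS association table with known signal labels
#'
#' Emulates a study export from a GWAS association catalogue: one record
#' per SNP with rsid, PMID, study title, phenotype (and category), P-value,
#' allele, MAF, coordinates, region type and gene. A fraction
#' \code{signalFraction} of SNPs are "signal": P = 10^-U with U uniform on
#' [5, 10]; the rest are null with P uniform on (1e-5, 0.05], so every
#' record satisfies the P <= 0.05 ingest rule. MAF is uniform on
#' (0.01, 0.5). Keys (rsid, pmid, phenotype) are unique by construction,
#' so the output ingests with zero rejections. Deterministic per seed.
#'
#' @param config a [SimulationConfig-class] (or NULL to use defaults).
#' @param seed overrides \code{config@seed} when given.
#' @return list with \code{table} (data.frame ready for
#'   [loadAssociations()]) and \code{truth} (data.frame: rsid, signal).
#' @export
simulateAssociationTable <- function(config = simulationConfig(),
                                     seed = NULL) {
  stopifnot(methods::is(config, "SimulationConfig"))
  set.seed(if (is.null(seed)) config@seed else seed)
  n <- config@nSnps
  rsid <- sprintf("rs%07d", sample.int(9999999L, n))
  pmids <- sprintf("2%07d", sample.int(9999999L, config@nStudies))
  pmid <- sample(pmids, n, replace = TRUE)
  phenos <- .PHENOTYPE_POOL[((seq_len(config@nPhenotypes) - 1L) %%
                               length(.PHENOTYPE_POOL)) + 1L]
  phenotype <- sample(phenos, n, replace = TRUE)
  signal <- stats::runif(n) < config@signalFraction
  p <- numeric(n)
  p[signal] <- 10^-stats::runif(sum(signal), 5, 10)
  p[!signal] <- stats::runif(sum(!signal), 1e-5, 0.05)
  tab <- data.frame(
    rsid = rsid,
    pmid = pmid,
    study_title = paste("GWAS of", tolower(phenotype), "cohort", pmid),
    phenotype = phenotype,
    phenotype_category = ifelse(grepl("diabetes|glucose", phenotype,
                                      ignore.case = TRUE),
                                "Metabolic", "Other"),
    p_value = p,
    allele = sample(.BASES, n, replace = TRUE),
    maf = stats::runif(n, 0.01, 0.5),
    chrom = sample(paste0("chr", c(1:22, "X")), n, replace = TRUE),
    pos = sample.int(2.4e8, n),
    region_type = sample(regionTypeVocabulary()[1:7], n, replace = TRUE,
                         prob = c(0.45, 0.05, 0.05, 0.08, 0.05, 0.3, 0.02)),
    gene = sample(.GENE_POOL, n, replace = TRUE),
    aa_change = "",
    polyphen2 = "",
    sift = "",
    evod = "",
    stringsAsFactors = FALSE)
  list(table = tab, truth = data.frame(rsid = rsid, signal = signal))
}
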