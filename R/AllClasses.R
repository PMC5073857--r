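#' @import methods
NULL

## Residue tokens used throughout: the four bases, "-" for GAP (position
## absent from that species' alignment row) and "N" for MISSING (no data).
.BASES <- c("A", "C", "G", "T")
.GAP <- "-"
.MISSING <- "N"
.RESIDUE_TOKENS <- c(.BASES, .GAP, .MISSING)

#' TimeTree: a rooted, time-calibrated phylogeny
#'
#' Thin S4 wrapper around an \code{ape} \code{phylo} object whose branch
#' lengths are durations in millions of years (My). Validity enforces: a
#' rooted, connected tree; a branch length on every edge; all branch lengths
#' non-negative; unique, non-empty leaf labels. The total time elapsed on the
#' tree (the sum of all branch durations) must be positive, except for a
#' single-leaf tree -- the degenerate result of pruning a site column down to
#' the reference taxon alone -- where zero total time is allowed.
#'
#' @slot phylo an \code{ape::phylo} object with \code{edge.length} in My.
#' @seealso [readTimeTree()], [totalTreeTime()], [pruneToPresent()]
#' @export
setClass("TimeTree", slots = c(phylo = "ANY"))

setValidity("TimeTree", function(object) {
  phy <- object@phylo
  if (!inherits(phy, "phylo"))
    return("slot 'phylo' must be an ape 'phylo' object")
  ntip <- length(phy$tip.label)
  if (ntip < 1L)
    return("tree has no leaves")
  if (anyDuplicated(phy$tip.label))
    return("duplicate leaf label(s)")
  if (any(!nzchar(phy$tip.label)))
    return("empty leaf label(s)")
  if (is.null(phy$edge.length))
    return("unlengthed edge: tree has no branch lengths")
  if (length(phy$edge.length) != nrow(phy$edge))
    return("unlengthed edge: some edges lack a branch length")
  if (anyNA(phy$edge.length))
    return("unlengthed edge: NA branch length")
  if (any(phy$edge.length < 0))
    return("negative branch length")
  if (ntip >= 2L) {
    if (!ape::is.rooted(phy))
      return("tree must be rooted")
    if (sum(phy$edge.length) <= 0)
      return("total tree time must be > 0")
  }
  TRUE
})

#' SiteColumn: one human genomic position across species
#'
#' The per-species residues observed at a single reference (human) genomic
#' position of a multi-species alignment. Residues are one of the four bases
#' \code{A,C,G,T}, \code{"-"} (GAP: the position does not exist in that
#' species' alignment row) or \code{"N"} (MISSING: no data, e.g. the species
#' is absent from the alignment block). The reference taxon must carry a
#' proper base: columns where it does not have no human coordinate and are
#' never constructed.
#'
#' @slot chrom chromosome label of the reference position.
#' @slot pos 1-based reference position.
#' @slot assembly assembly label carried as opaque metadata (e.g. "B37/hg19").
#' @slot referenceTaxon label of the reference (human) sequence.
#' @slot residues named character vector, taxon -> residue token.
#' @seealso [readColumns()], [siteEvolution()]
#' @export
setClass("SiteColumn", slots = c(
  chrom = "character",
  pos = "integer",
  assembly = "character",
  referenceTaxon = "character",
  residues = "character"
))

setValidity("SiteColumn", function(object) {
  res <- object@residues
  if (length(res) < 1L || is.null(names(res)) || any(!nzchar(names(res))))
    return("'residues' must be a non-empty named vector")
  if (anyDuplicated(names(res)))
    return("duplicate taxon in 'residues'")
  bad <- setdiff(unique(res), .RESIDUE_TOKENS)
  if (length(bad))
    return(paste0("unknown residue character(s): ",
                  paste(sQuote(bad), collapse = ", ")))
  ref <- object@referenceTaxon
  if (length(ref) != 1L || !ref %in% names(res))
    return("reference taxon absent from 'residues'")
  if (!res[[ref]] %in% .BASES)
    return("reference taxon must carry a base in {A,C,G,T}")
  if (length(object@pos) != 1L || is.na(object@pos) || object@pos < 1L)
    return("'pos' must be a single positive integer")
  TRUE
})

#' SiteEvolution: per-position evolutionary context
#'
#' The evolutionary summary of one reference position: the evolutionary rate
#' (substitutions per site per billion years, Gy), the evolutionary timespan
#' (as a fraction of total tree time, and in absolute My), the parsimony
#' substitution count, the number of species in which the position exists,
#' and the conservation class derived from the rate. When the position exists
#' only in the reference lineage the rate is undefined (no cross-species
#' comparison is possible): \code{evolRate} and \code{nSubstitutions} are
#' \code{NA} and the class is \code{"unclassified"} -- never 0 / "ultra",
#' which would assert conservation.
#'
#' @slot evolRate substitutions/site/Gy, or NA when undefined.
#' @slot evolSpanFraction fraction of full-tree time, in [0,1].
#' @slot evolSpanMy absolute timespan in My.
#' @slot nSubstitutions parsimony substitution count (NA when rate undefined).
#' @slot nPresentTaxa number of leaves with a base at this position.
#' @slot conservationClass one of "ultra", "well", "less", "unclassified".
#' @seealso [siteEvolution()], [classifyConservation()]
#' @export
setClass("SiteEvolution", slots = c(
  evolRate = "numeric",
  evolSpanFraction = "numeric",
  evolSpanMy = "numeric",
  nSubstitutions = "integer",
  nPresentTaxa = "integer",
  conservationClass = "character"
))

setValidity("SiteEvolution", function(object) {
  f <- object@evolSpanFraction
  if (is.na(f) || f < 0 || f > 1)
    return("evolSpanFraction must lie in [0,1]")
  if (object@evolSpanMy < 0)
    return("evolSpanMy must be >= 0")
  if (object@nPresentTaxa < 1L)
    return("nPresentTaxa must be >= 1")
  r <- object@evolRate
  if (!is.na(r) && r < 0)
    return("evolRate must be >= 0 when defined")
  if (is.na(r) && object@conservationClass != "unclassified")
    return("undefined rate must be 'unclassified'")
  if (!is.na(r) && xor(r == 0, identical(object@nSubstitutions, 0L)))
    return("evolRate == 0 iff nSubstitutions == 0")
  TRUE
})

#' AssociationSet: an in-memory store of GWAS association records
#'
#' Holds association records (one per SNP x study x phenotype) that passed
#' the ingest rules -- P-value present, in (0, 0.05], and unique
#' (rsid, pmid, phenotype) key -- together with a rejection report listing
#' every dropped row and the reason. Lightweight positional indexes by rsid
#' and PMID support lookup; filtering, aggregation, sorting and keyword
#' search are provided as methods.
#'
#' @slot records data.frame of accepted records (normalized column names).
#' @slot rejected data.frame of dropped rows with a \code{reason} column.
#' @slot index list of positional indexes (split by rsid and pmid).
#' @seealso [loadAssociations()], [filterRecords()], [summarizeBySnp()]
#' @export
setClass("AssociationSet", slots = c(
  records = "data.frame",
  rejected = "data.frame",
  index = "list"
))

#' RankedSNPSet: E-rank results for one set of SNPs
#'
#' The result of [computeRankings()]: per rankable SNP the within-set midranks
#' of evolutionary rate (Kr, descending: the fastest-evolving site ranks 1)
#' and of evolutionary span (Kt, ascending: the longest-lived site ranks N),
#' the E-rank score (P/MAF) / (Kr*Kt), and the ordinal P-rank and E-rank with
#' their difference. Records that could not be ranked (missing/zero MAF,
#' undefined rate or span) are kept in \code{excluded} with per-record
#' reasons rather than silently assigned extreme ranks.
#'
#' @slot ranked data.frame with columns rsid, p_value, maf, evol_rate,
#'   evol_span, k_r, k_t, e_score, p_rank, e_rank_ordinal, rank_diff.
#' @slot excluded data.frame of unrankable records with a \code{reason} column.
#' @seealso [computeRankings()], [erankVsPrank()]
#' @export
setClass("RankedSNPSet", slots = c(
  ranked = "data.frame",
  excluded = "data.frame"
))

setValidity("RankedSNPSet", function(object) {
  r <- object@ranked
  need <- c("rsid", "p_value", "maf", "evol_rate", "evol_span",
            "k_r", "k_t", "e_score", "p_rank", "e_rank_ordinal", "rank_diff")
  miss <- setdiff(need, names(r))
  if (length(miss))
    return(paste0("ranked table missing column(s): ",
                  paste(miss, collapse = ", ")))
  n <- nrow(r)
  if (n > 0L) {
    if (!setequal(r$p_rank, seq_len(n)) ||
        !setequal(r$e_rank_ordinal, seq_len(n)))
      return("p_rank and e_rank_ordinal must be permutations of 1..N")
    if (any(r$k_r < 1 | r$k_r > n) || any(r$k_t < 1 | r$k_t > n))
      return("k_r and k_t must lie in [1, N]")
  }
  TRUE
})

#' SimulationConfig: parameters of the synthetic-data generator
#'
#' Bundles the study conditions of the simulator: the tree shape, the
#' per-site true rate grid, the clade-deletion (gap) probability, and the
#' shape and P-value mixture of the synthetic association table. The P-value
#' generator draws a fraction \code{signalFraction} of "signal" SNPs with
#' P = 10^-U, U uniform on [5, 10]; the remaining null SNPs draw P uniform
#' on (1e-5, 0.05]. MAF is uniform on (0.01, 0.5).
#'
#' @slot nTaxa number of species in the simulated tree.
#' @slot treeDepthMy root-to-leaf depth of the ultrametric tree, in My.
#' @slot rateGrid true per-site rates, substitutions/site/Gy.
#' @slot gapProb per-internal-edge clade deletion probability, in [0,1).
#' @slot nSites number of alignment columns per rate.
#' @slot nSnps,nStudies,nPhenotypes shape of the association table.
#' @slot signalFraction fraction of signal SNPs, in [0,1].
#' @slot seed integer seed; fixed seed gives byte-identical outputs.
#' @seealso [simulationConfig()], [simulateAssociationTable()]
#' @export
setClass("SimulationConfig", slots = c(
  nTaxa = "integer",
  treeDepthMy = "numeric",
  rateGrid = "numeric",
  gapProb = "numeric",
  nSites = "integer",
  nSnps = "integer",
  nStudies = "integer",
  nPhenotypes = "integer",
  signalFraction = "numeric",
  seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  if (object@nTaxa < 2L) return("nTaxa must be >= 2")
  if (object@treeDepthMy <= 0) return("treeDepthMy must be > 0")
  if (any(object@rateGrid < 0)) return("rates must be >= 0")
  if (object@gapProb < 0 || object@gapProb >= 1)
    return("gapProb must lie in [0,1)")
  if (object@signalFraction < 0 || object@signalFraction > 1)
    return("signalFraction must lie in [0,1]")
  if (object@nSnps < 1L) return("nSnps must be >= 1")
  TRUE
})
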