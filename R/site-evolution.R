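## Per-position evolutionary context: pruning, parsimony substitution
## counting, rate (subs/site/Gy), timespan and conservation class.

.singleLeafTree <- function(label) {
  ## degenerate spanning "subtree" of one leaf: no inter-species time.
  phy <- structure(list(
    edge = matrix(c(2L, 1L), nrow = 1L),
    edge.length = 0,
    tip.label = label,
    Nnode = 1L
  ), class = "phylo", order = "cladewise")
  TimeTree(phy)
}

#' Prune a tree to the taxa in which a position exists
#'
#' Returns the minimal spanning subtree of a [TimeTree-class] connecting the
#' leaves whose residue at the given [SiteColumn-class] is a proper base.
#' Internal degree-2 nodes arising from the pruning are collapsed with their
#' branch durations summed, so the total time of the result is exactly the
#' time spanned by the present lineages. When only the reference taxon is
#' present the result is a valid single-leaf tree with total time 0 (the
#' position is private to the reference lineage).
#'
#' @param tree a [TimeTree-class] containing every taxon of \code{column}.
#' @param column a [SiteColumn-class].
#' @return a [TimeTree-class].
#' @examples
#' tr <- readTimeTree("((H:100,B:100):400,(C:100,D:100):400);")
#' col <- SiteColumn(c(H = "A", B = "A", C = "-", D = "-"), "H")
#' totalTreeTime(pruneToPresent(tr, col))  # 200
#' @export
pruneToPresent <- function(tree, column) {
  stopifnot(methods::is(tree, "TimeTree"), methods::is(column, "SiteColumn"))
  leaves <- leafLabels(tree)
  present <- presentTaxa(column)
  ## a base-bearing taxon missing from the tree is a real inconsistency;
  ## gapped/missing taxa absent from a (possibly pre-pruned) tree are not
  unknown <- setdiff(present, leaves)
  if (length(unknown))
    stop("taxa in column absent from tree: ",
         paste(sQuote(unknown), collapse = ", "), call. = FALSE)
  present <- intersect(present, leaves)
  if (!column@referenceTaxon %in% present)
    stop("reference taxon has no base", call. = FALSE)
  if (length(present) == 1L)
    return(.singleLeafTree(present))
  if (setequal(present, leaves))
    return(tree)
  TimeTree(ape::keep.tip(tree@phylo, present))
}

#' Minimum substitution count at a site (small parsimony)
#'
#' The minimum number of nucleotide substitutions on the tree consistent
#' with the observed leaf bases: the Fitch small-parsimony count, computed
#' by uniform-cost dynamic programming over the four bases (exact for any
#' rooted tree, including multifurcations). The tree must already be pruned
#' to the present taxa: every leaf must carry a base in the column.
#'
#' @param tree a [TimeTree-class], pruned to present taxa.
#' @param column a [SiteColumn-class] with a base for every leaf of
#'   \code{tree}.
#' @return integer substitution count, between (number of distinct observed
#'   bases - 1) and (number of leaves - 1).
#' @examples
#' tr <- readTimeTree("((H:100,B:100):400,(C:100,D:100):400);")
#' col <- SiteColumn(c(H = "A", B = "A", C = "G", D = "G"), "H")
#' countSubstitutionsFitch(tr, col)  # 1
#' @export
countSubstitutionsFitch <- function(tree, column) {
  stopifnot(methods::is(tree, "TimeTree"), methods::is(column, "SiteColumn"))
  phy <- tree@phylo
  ntip <- length(phy$tip.label)
  if (ntip == 1L) return(0L)
  bases <- column@residues[phy$tip.label]
  if (anyNA(bases) || !all(bases %in% .BASES))
    stop("leaf without a base in column: tree must be pruned to ",
         "present taxa first", call. = FALSE)
  phy <- stats::reorder(phy, "postorder")
  nnode <- ntip + phy$Nnode
  cost <- matrix(Inf, nrow = 4L, ncol = nnode)
  cost[, seq_len(ntip)] <- Inf
  cost[cbind(match(bases, .BASES), seq_len(ntip))] <- 0
  cost[, (ntip + 1L):nnode] <- 0
  for (e in seq_len(nrow(phy$edge))) {
    parent <- phy$edge[e, 1L]
    child <- phy$edge[e, 2L]
    cmin <- min(cost[, child])
    cost[, parent] <- cost[, parent] + pmin(cost[, child], cmin + 1)
  }
  root <- ntip + 1L
  as.integer(min(cost[, root]))
}

#' Per-site evolutionary rate
#'
#' The minimum substitution count at the position divided by the total time
#' elapsed on the spanning subtree of the taxa in which the position exists,
#' in substitutions per site per billion years. Substitutions are only
#' observable where the position exists, so the denominator is the time of
#' the pruned subtree, not of the full tree. When the position exists only
#' in the reference lineage no cross-species comparison is possible and the
#' rate is undefined: \code{NA} is returned (never 0, which would assert
#' perfect conservation).
#'
#' @param tree a [TimeTree-class] (full tree; pruning is internal).
#' @param column a [SiteColumn-class].
#' @return substitutions/site/Gy, or \code{NA_real_} when undefined.
#' @examples
#' tr <- readTimeTree("((H:100,B:100):400,(C:100,D:100):400);")
#' evolRate(tr, SiteColumn(c(H = "A", B = "A", C = "G", D = "G"), "H"))
#' @export
evolRate <- function(tree, column) {
  pruned <- pruneToPresent(tree, column)
  if (length(leafLabels(pruned)) == 1L) return(NA_real_)
  timeGy <- totalTreeTime(pruned) / 1000
  countSubstitutionsFitch(pruned, column) / timeGy
}

#' Evolutionary timespan of a position
#'
#' The total time of the spanning subtree connecting the species in which
#' the position exists -- absolute (My) and as a fraction of the full tree's
#' total time, so the fraction is comparable across positions. All taxa
#' present gives fraction 1; a position private to the reference lineage
#' gives 0.
#'
#' @param tree a [TimeTree-class].
#' @param column a [SiteColumn-class].
#' @return named numeric vector \code{c(fraction = , my = )}.
#' @export
evolSpan <- function(tree, column) {
  pruned <- pruneToPresent(tree, column)
  my <- if (length(leafLabels(pruned)) == 1L) 0 else totalTreeTime(pruned)
  c(fraction = my / totalTreeTime(tree), my = my)
}

#' Conservation class of a site
#'
#' Classifies a site by its evolutionary rate: \code{"ultra"}-conserved for
#' rate exactly zero, \code{"well"}-conserved for rates in (0, 1], and
#' \code{"less"}-conserved for rates above 1 substitution/site/Gy. The
#' boundary at exactly 1.0 is assigned to "well": "greater than one" is
#' taken literally, its complement closes the upper bound. An undefined
#' (\code{NA}) rate maps to \code{"unclassified"}, never to a default class.
#'
#' @param rate numeric vector of rates in substitutions/site/Gy (NA allowed).
#' @return character vector over \code{{"ultra","well","less","unclassified"}}.
#' @examples
#' classifyConservation(c(0, 0.5, 1, 2.3, NA))
#' @export
classifyConservation <- function(rate) {
  if (any(rate < 0, na.rm = TRUE))
    stop("rate must be >= 0", call. = FALSE)
  out <- ifelse(is.na(rate), "unclassified",
         ifelse(rate == 0, "ultra",
         ifelse(rate <= 1, "well", "less")))
  as.character(out)
}

#' Full evolutionary context of one position
#'
#' Computes rate, span, substitution count, present-taxon count and
#' conservation class in one pass (the pruned subtree is built once).
#'
#' @param tree a [TimeTree-class].
#' @param column a [SiteColumn-class].
#' @return a [SiteEvolution-class].
#' @export
siteEvolution <- function(tree, column) {
  pruned <- pruneToPresent(tree, column)
  nPresent <- length(leafLabels(pruned))
  if (nPresent == 1L) {
    return(methods::new("SiteEvolution",
      evolRate = NA_real_, evolSpanFraction = 0, evolSpanMy = 0,
      nSubstitutions = NA_integer_, nPresentTaxa = 1L,
      conservationClass = "unclassified"))
  }
  my <- totalTreeTime(pruned)
  nSub <- countSubstitutionsFitch(pruned, column)
  rate <- nSub / (my / 1000)
  methods::new("SiteEvolution",
    evolRate = rate,
    evolSpanFraction = my / totalTreeTime(tree),
    evolSpanMy = my,
    nSubstitutions = nSub,
    nPresentTaxa = nPresent,
    conservationClass = classifyConservation(rate))
}

setMethod("show", "SiteEvolution", function(object) {
  cat("SiteEvolution: rate ",
      if (is.na(object@evolRate)) "undefined (reference-only position)"
      else paste0(format(object@evolRate), " subs/site/Gy"),
      "; span ", format(object@evolSpanFraction), " (",
      format(object@evolSpanMy), " My); ",
      object@nPresentTaxa, " taxa; ", object@conservationClass,
      "-conserved\n", sep = "")
})

#' Tabulate evolutionary context over many positions
#'
#' Applies [siteEvolution()] to each column and returns one row per
#' position in the format consumed by [writeSiteMetrics()] and
#' [computeRankings()].
#'
#' @param tree a [TimeTree-class].
#' @param columns list of [SiteColumn-class].
#' @return data.frame with columns chrom, pos, evol_rate,
#'   evol_span_fraction, evol_span_my, n_substitutions, n_present_taxa,
#'   conservation_class.
#' @export
siteEvolutionTable <- function(tree, columns) {
  stopifnot(length(columns) > 0L)
  rows <- lapply(columns, function(cc) {
    se <- siteEvolution(tree, cc)
    data.frame(chrom = cc@chrom, pos = cc@pos,
               evol_rate = se@evolRate,
               evol_span_fraction = se@evolSpanFraction,
               evol_span_my = se@evolSpanMy,
               n_substitutions = se@nSubstitutions,
               n_present_taxa = se@nPresentTaxa,
               conservation_class = se@conservationClass,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
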