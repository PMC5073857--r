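# Independent oracles used across the suite.

# Exhaustive small-parsimony oracle: minimum number of state changes over
# ALL 4^k internal-node labelings of a rooted phylo. Independent of the
# package's dynamic-programming implementation.
bruteForceParsimony <- function(phy, bases) {
  ntip <- length(phy$tip.label)
  k <- phy$Nnode
  leafIdx <- match(bases[phy$tip.label], c("A", "C", "G", "T"))
  stopifnot(!anyNA(leafIdx))
  combos <- as.matrix(expand.grid(rep(list(1:4), k)))
  full <- cbind(matrix(leafIdx, nrow = nrow(combos), ncol = ntip,
                       byrow = TRUE), combos)
  changes <- rowSums(full[, phy$edge[, 1L], drop = FALSE] !=
                     full[, phy$edge[, 2L], drop = FALSE])
  as.integer(min(changes))
}

# All 4^n leaf labelings of an n-leaf tree, as a matrix of base characters.
allLeafLabelings <- function(n) {
  g <- as.matrix(expand.grid(rep(list(c("A", "C", "G", "T")), n)))
  dimnames(g) <- NULL
  g
}

# A random rooted binary topology with positive branch lengths, wrapped as
# a TimeTree.
randomTimeTree <- function(n, seed) {
  set.seed(seed)
  phy <- ape::rtree(n, br = function(k) stats::runif(k, 10, 100))
  phy$tip.label <- paste0("s", seq_len(n))
  TimeTree(phy)
}
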