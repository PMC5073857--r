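---
title: "Evolutionary context and E-rank prioritization of GWAS variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary context and E-rank prioritization of GWAS variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evorank)
```

## The model

`evorank` scores each human genomic position by two quantities computed
from a multi-species alignment on a rooted, time-calibrated phylogeny
(branch lengths in millions of years, My), and uses them to re-rank GWAS
association results.

**Evolutionary rate.** At one alignment column, the species in which the
position exists (residue A/C/G/T; a `-` means the position is absent from
that species, an `N` means no data) define a spanning subtree of the full
tree. The rate is the minimum number of nucleotide substitutions on that
subtree consistent with the observed leaf bases, divided by the subtree's
total branch time, expressed per billion years (Gy):

$$\widehat{r} = \frac{S_{\min}}{T_{\text{pruned}} / 1000},$$

with $T$ in My. $S_{\min}$ is the classical small-parsimony (Fitch) count.
We compute it by uniform-cost dynamic programming over the four bases
(per node, the minimal cost of each ancestral state given its children),
which returns the exact minimum for any rooted tree, including
multifurcations, and is deterministic. Parsimony *underestimates* the true
number of substitutions when multiple hits occur on one branch; the
estimator is therefore monotone in, but biased below, the true rate at
high rates — the test suite asserts monotone recovery, not unbiasedness.

**Choice of denominator.** Substitutions are only observable on lineages
where the position exists, so the rate denominator is the *pruned*
subtree's time. Using the full tree's time would systematically deflate
rates at short-span positions. The alternative reading (full-tree time)
exists; we document ours as this package's definition.

**Evolutionary timespan.** The span is the pruned subtree's total time,
reported in My and as a fraction of the *full* tree's total time — the
full-tree denominator makes the fraction comparable across positions. All
species present gives fraction 1. Pruning collapses degree-2 nodes and
sums their branch durations, so the span is exactly the evolutionary time
over which the position has existed among the sampled lineages.

**Degenerate positions.** A position carried only by the reference lineage
permits no cross-species comparison: its rate is *undefined* (`NA`, class
`"unclassified"`), never 0 — a zero would assert perfect conservation —
and its span is 0. Such positions are excluded from downstream ranking,
with the exclusion reported. `N` (missing data) is treated as "position
not observed": excluded from substitution counting and, conservatively,
counted as absent for the span. How missing data were treated in
comparable resources is generally unstated; we document our choice rather
than guess.

**Conservation classes.** Sites are *ultra*-conserved at rate exactly 0,
*well*-conserved in (0, 1], *less*-conserved above 1 subs/site/Gy. Only
"greater than one" is unambiguous as a boundary phrase, so 1.0 itself goes
to "well" (closed upper bound); the boundary behaviour is pinned by tests.

## E-rank

For a set of $N$ rankable SNPs — the set supplied by the caller, normally
one study's results; there is no global re-ranking across studies — each
SNP gets

$$\text{E-score} = \frac{P}{\text{MAF}} \cdot \frac{1}{K_r K_t},$$

where $K_r$ is the midrank of its Evol_Rate taken **descending** (the
fastest-evolving site ranks 1, the most conserved ranks $N$) and $K_t$
the midrank of its Evol_Span taken **ascending** (the longest-lived site
ranks $N$). The rank directions are the single most consequential design
choice here: they are set so that conserved, long-lived positions receive
a large $K_r K_t$, hence a small score, hence promotion — the direction
that makes the adjustment enhance the discovery of SNPs at conserved
sites. Ties use midranks (deterministic and sum-preserving:
$\sum K = N(N+1)/2$); ordinal P-rank and E-rank are assigned ascending
with a lexicographic rsid tie-break so output is reproducible. Useful
identities, all enforced by tests: both ordinal ranks are permutations of
$1..N$; rank differences sum to zero; scaling every P by a common constant
leaves the E ordering unchanged; and when all SNPs share identical rate,
span and MAF, E-rank equals P-rank exactly.

Records with missing or zero MAF, or undefined rate/span, are excluded
from the ranked set and returned separately with reasons. Silently
assigning them extreme ranks would distort every other SNP's $K$ values.
A P-value of exactly 0 (occasionally produced by underflow in source
tables) is clamped to the smallest positive double with a warning.

## The association store

Ingest accepts TSV/CSV with case-insensitive headers; required columns are
`rsid`, `pmid`, `phenotype`, `p_value`. Rules: P must parse, be positive
and be ≤ 0.05 (the inclusion threshold of the emulated GWAS catalogue);
`(rsid, pmid, phenotype)` must be unique. Every dropped row is reported
with its reason — rejects are visible, never silent. Filtering is
conjunctive over P cutoff, E-score cutoff (requires a `RankedSNPSet`
computed for the set; the "E-value cutoff" of the emulated interface is
interpreted as a cutoff on the E-rank *score*, the only E-quantity
defined), region type from a small closed vocabulary (intron, missense,
synonymous, 3'UTR, 5'UTR, intergenic, other — extensible per call),
phenotype and gene (case-insensitive exact match). Summaries count
distinct studies/phenotypes per SNP with min/max P, and distinct
SNPs/phenotypes/genes per study. Sorting is stable, keyed to the
controlled column list, breaks ties by rsid, and places missing values
last regardless of direction. The storage engine is a plain in-memory
data.frame with positional indexes; the query semantics, not the engine,
are the contract.

## Rank-comparison outputs

`erankVsPrank()` (E-rank on x, P-rank on y, identity line as metadata) and
`erankMinusPrank()` (one bar per SNP; negative bars mark promoted SNPs)
return plot-ready tables that are pure functions of the ranked set and
serialize byte-identically; `plotRankScatter()` / `plotRankDiff()` render
them with ggplot2. Displays are capped at 1000 records
(`capForDisplay()`), preserving the caller's sort order so pre-sorting
chooses what survives the cap; `writeBulkCsv()` exports everything without
a limit.

## What the simulator emulates — and what it does not

The generator produces every input kind the package consumes, with known
ground truth:

- **Trees**: Yule (pure-birth) ultrametric trees rescaled to an exact
  root-to-leaf depth. Default study conditions: 8 taxa, 100 My depth.
- **Columns**: a root base uniform on {A,C,G,T}; per branch a Poisson
  number of substitutions with mean rate × branch time (Gy), each a
  uniform change to a different base — a Jukes-Cantor-like model, the
  simplest sufficient to exercise a counting-based estimator. Gaps are
  clade-level: each internal edge deletes its subtending clade with
  probability `gapProb`, matching the interpretation of span as
  lineage-level position presence; edges ancestral to the reference are
  exempt, so the reference always keeps a base. Default rate grid
  {0, 0.25, 0.5, 1, 2, 4} subs/site/Gy, 200 columns per rate.
- **Association tables**: one record per SNP; a fraction `signalFraction`
  (default 0.1) of SNPs draw $P = 10^{-U}$, $U \sim \mathrm{U}[5, 10]$,
  the rest draw P uniform on (1e-5, 0.05]; MAF uniform on (0.01, 0.5).
  Outputs always satisfy the ingest invariants.

Everything is seeded; per-column substream seeds are derived as
`(seed + 7919·i) mod (2^31 − 1)` so any single fixture is reproducible in
isolation. The simulator does **not** model transition/transversion bias,
rate variation along branches, alignment error, linkage disequilibrium,
genotype sampling or realistic GWAS power. Passing tests therefore show
that the estimators and rankings behave correctly under a clean generative
model — not that rates estimated from real alignments are unbiased, nor
that E-rank improves replication on real studies.

## Numerical choices and problem sizes

Site-metric TSVs are written at 6 significant digits and round-trip at
that precision. Branch lengths are carried in My end to end; the single
unit conversion (×1000) happens in the rate. Newick input must carry a
length on every edge — a missing length is an error, not a default — and
syntax errors report the character offset. The test suite validates the
parsimony count against exhaustive enumeration over all internal-node
labelings on trees of 2–6 leaves (all $4^n$ leaf labelings up to $n=4$;
500 random labelings for $n = 5, 6$; three random topologies each) and
against an independent Fitch implementation (phangorn); rate recovery uses
200 columns per grid rate on the default 8-taxon tree. These sizes keep
the whole suite in the tens of seconds while covering the tree shapes
where parsimony counting has edge cases (cherries, root polytomies after
pruning, full ties).

## Known limitations

- Parsimony counting saturates: above ~2–4 subs/site/Gy on trees of this
  depth the estimated rate flattens well below the truth. Ranks (the K's)
  are less affected than the rates themselves, which is one reason E-rank
  uses ranks rather than raw rates.
- The rate denominator and span definitions above are this package's
  documented readings of quantities that admit alternatives (full-tree
  time; human-to-most-distant-species time).
- Strand handling assumes reference-strand-oriented alignments (as UCSC
  MAF provides); there is no reverse-complement logic and no liftover.
- The store is desk-scale: flat files and in-memory indexes, not a
  database; genome-scale MAF streaming is out of scope.
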