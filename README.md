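# evorank

Evolutionary context and rank-based prioritization of GWAS variants.

Genome-wide association studies (GWAS) order variants by the P-value of
their trait association, but a small P-value alone is weak evidence that a
SNP is functionally important. `evorank` adds an orthogonal, purely
evolutionary axis: for each human genomic position it computes, from a
multi-species alignment on a time-calibrated phylogeny,

- **Evol_Rate** — the per-site evolutionary rate: the minimum number of
  nucleotide substitutions on the tree (uniform-cost small parsimony,
  i.e. the Fitch count) divided by the total time elapsed on the subtree of
  species in which the position exists, in substitutions per site per
  billion years (Gy). Low rates mark conserved, likely functional sites.
- **Evol_Span** — the evolutionary timespan: the fraction of the tree's
  total time covered by the spanning subtree of species in which the
  position is alignable (non-gap). Long-lived positions are older and more
  constrained.
- a conservation class: *ultra* (rate = 0), *well* (0 < rate ≤ 1),
  *less* (rate > 1).

These feed the **E-rank** adjustment of association results. For a set of
N SNPs (typically one study),

```
E-rank score = (P / MAF) × 1 / (K_r · K_t)
```

where P is the association P-value, MAF the minor allele frequency, K_r
the within-set rank of Evol_Rate (descending: the fastest-evolving site
ranks 1, the most conserved ranks N) and K_t the rank of Evol_Span
(ascending: the longest-lived site ranks N). Conserved, long-lived
positions get a large K_r·K_t, a small score, and therefore move up in the
E-rank ordering relative to the raw P-value ordering. The package also
provides the association store (ingest with a P ≤ 0.05 inclusion rule,
filtering, per-SNP and per-study summaries, sorting, keyword search), the
E-rank vs P-rank and E-rank − P-rank plot data with a 1000-record display
cap, and a fully seeded simulator for trees, alignment columns and
association tables.

## Worked example

```r
library(evorank)

# A 4-species time tree (branch lengths in My) and one alignment column
tree <- readTimeTree("((H:100,B:100):400,(C:100,D:100):400);")
col  <- SiteColumn(c(H = "A", B = "A", C = "G", D = "G"), "H")
siteEvolution(tree, col)
#> SiteEvolution: rate 0.8333333 subs/site/Gy; span 1 (1200 My); 4 taxa; well-conserved
```

One substitution (A↔G needs a single change on this topology) over
1200 My = 1.2 Gy gives 0.83 substitutions/site/Gy; all four species carry
the position, so the span fraction is 1.

```r
fixture <- system.file("extdata", "toy_associations.tsv", package = "evorank")
assoc <- loadAssociations(fixture)
assoc
#> AssociationSet: 5 record(s); 5 SNP(s); 3 study(ies); 2 rejected at ingest

rec <- associationRecords(assoc)
rec$evol_rate <- c(0.0, 0.4, 1.2, 2.5, 0.1)   # from siteEvolutionTable()
rec$evol_span <- c(1.0, 0.9, 0.3, 0.15, 0.95)
computeRankings(rec)
#> RankedSNPSet: 5 ranked SNP(s), 0 excluded
#>    rsid p_value  maf k_r k_t      e_score p_rank e_rank_ordinal rank_diff
#>  rs1001   1e-08 0.30   5   5 1.333333e-09      1              1         0
#>  rs1002   1e-06 0.12   3   3 9.259259e-07      2              2         0
#>  rs1003   1e-04 0.45   2   2 5.555556e-05      3              3         0
#>  rs1005   4e-02 0.25   4   4 1.000000e-02      5              4        -1
#>  rs1004   1e-03 0.05   1   1 2.000000e-02      4              5         1
```

The two ingest rejections are a row with P = 0.2 (above the 0.05 inclusion
threshold) and a duplicate (rsid, pmid, phenotype) key. In the ranking,
rs1005 (a conserved, long-lived site: rate 0.1, span 0.95) overtakes
rs1004 (rate 2.5, span 0.15) despite its 40× larger P-value — the negative
`rank_diff` marks the promotion. `plotRankScatter()` and `plotRankDiff()`
draw the corresponding figures; `erankVsPrank()` / `erankMinusPrank()`
return the plot-ready tables.

A command-line front-end over the same functions is installed at
`system.file("scripts", "evorank-cli.R", package = "evorank")` with
subcommands `simulate`, `site-metrics`, `erank`, `filter`, `summarize`
and `plot-data`.

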