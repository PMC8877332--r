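# fnmotif

Functional network motifs (FNMs) from integrated protein–protein and
genetic interaction networks.

## The problem

Network motifs — small connected graphlets of k = 3–6 nodes that recur more
often than chance — have shaped our understanding of feedback circuits in
cellular networks, but defined purely by over-representation they occur in
overwhelming numbers and mostly lack biological context. `fnmotif`
implements a stricter definition that integrates genetic interactions (GIs,
epistatic fitness effects of double deletions) as a direct readout of
functional relatedness: a PPI graphlet is a **functional network motif**
when

- GIs are present on at least 50% of all k(k−1)/2 node pairs
  (`gi_count >= ceiling(0.5 * k(k-1)/2)`), and
- the source node of the layered search has a direct GI with every node of
  the motif's most distant layer.

The package is aimed at systems biologists who want to prioritize candidate
feedback and cross-talk interactions from genome-scale interaction data:
it enumerates graphlets exhaustively by layered depth-first search over the
integer compositions of k, filters them by GI content, quantifies
over-representation against degree-preserving null models, and runs the
downstream analyses — motif clustering by node overlap, complex-merged
consensus interaction maps, complex-pair-restricted betweenness of
auxiliary genes, transcriptional co-regulation scoring, and enrichment
statistics (Fisher exact, Wilcoxon–Mann–Whitney with GI-matched controls).

A seeded synthetic-fixture generator emulates every required input (PPI
edge table, GI score table, complex annotations, gene lists, suppressor
pairs, expression matrix), so the full pipeline builds and tests offline.

## Worked example

```r
library(fnmotif)

# synthetic input bundle with 6 planted FNMs (k = 3,3,4,4,5,6)
fx  <- generate_fixture(fixture_spec(seed = 1))

# build the enumeration network: drop intra-complex edges, then hubs
net <- filter_degree(remove_intracomplex_edges(fx$ppi, fx$cmap), d_max = 50)
gi  <- threshold_gi(fx$gi_scores, tail_fraction = 0.05)

occ <- enumerate_graphlets(net, k = 3)
fnm <- find_fnms(occ, gi, threshold = 0.5)
dd  <- dedup_fnms(fnm)

nrow(occ); sum(fnm$is_fnm); nrow(dd)
#> [1] 327
#> [1] 39
#> [1] 27
head(dd[, c("source", "node_set", "composition", "graph6", "gi_count")], 3)
#>   source          node_set composition graph6 gi_count
#> 1  G0016 G0001;G0006;G0016         1,2     Bo        2
#> 2  G0020 G0001;G0012;G0020         1,2     Bw        2
#> 3  G0001 G0001;G0016;G0020         1,2     Bo        2
```

327 per-source occurrences of size-3 graphlets exist in the filtered
network (three per unique subgraph — one per member source); 39 of those
occurrence records pass the GI filter, collapsing to 27 distinct gene sets.
Each row reports the layer composition (`1,2` = source plus two nodes at
distance 1), the canonical induced topology in graph6 (`Bo` is the 3-path,
`Bw` the triangle), and the number of GI edges among the genes.

Over-representation against the degree-preserving null:

```r
s <- randomized_motif_summary(net, gi, k = 3, mode = "gi_random", R = 30, seed = 1)
s[, c("graph6", "observed", "null_mean", "null_sd", "z")]
#>   graph6 observed null_mean   null_sd         z
#> 1     Bo       21 2.0333333 2.2047493  8.602641
#> 2     Bw       18 0.4666667 0.7760792 22.592197
```

Observed FNM counts exceed the rewired-GI null by more than eight null
standard deviations for both size-3 topologies — the planted GI structure
is picked up as strongly non-random.

The whole analysis, end to end, with outputs written to a run directory:

```r
cfg <- pipeline_config(fx$paths, seed = 1)   # k = 3:6, d_max = 50, R = 30, ...
res <- run_pipeline(cfg, "fnm_run")
readLines(res$summary_path)
```

A thin command-line wrapper is provided at `inst/cli/fnm.R`
(`Rscript fnm.R synth --out DIR`, `Rscript fnm.R run --ppi ... --out DIR`).

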