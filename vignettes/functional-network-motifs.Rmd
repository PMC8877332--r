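---
title: "Functional network motifs: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional network motifs: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnmotif)
```

## The problem and the model

Network motifs — small connected graphlets of k = 3–6 nodes — are classically
defined by statistical over-representation in a network relative to a
degree-preserving null. In a protein–protein interaction (PPI) network this
definition finds enormous numbers of occurrences, most of which carry no
specific biological meaning. `fnmotif` implements a stricter, biologically
anchored definition: a **functional network motif (FNM)** is a PPI graphlet
whose gene set is additionally dense in **genetic interactions (GIs)** —
epistatic fitness effects of double deletions that directly report on
functional relationships between genes.

An occurrence is produced by a layered exhaustive search: from a chosen
*source* node, the remaining nodes are organized in layers by breadth-first
distance within the induced subgraph. The layer sizes follow an integer
composition (1, c₁, …, c_L) of k, of which there are 2^(k−2) for each k
(`layer_compositions()`). During the depth-first search, candidates for
layer i+1 are neighbours of layer i that are neither already placed nor
adjacent to any earlier layer; this guarantees each connected induced
k-subgraph containing the source is visited exactly once, with its unique
BFS layering. Across all sources, every unique subgraph therefore appears
exactly k times, a relation the test suite checks against a brute-force
subset census.

An occurrence qualifies as an FNM when

1. GIs are present on at least a fraction t (default 0.5) of all k(k−1)/2
   node pairs, implemented as `gi_count >= ceiling(t * k(k-1)/2)` — so k = 3
   needs 2 of 3 pairs, k = 5 needs 5 of 10, and k = 6 needs 8 of 15; and
2. the source node has a direct GI with *every* node of the most distant
   layer (the motif is "spanned" by GIs).

The ceiling convention is this package's choice: "at least 50%" leaves the
rounding direction open, and the ceiling is the conservative reading. GI
sign (positive/negative epistasis) never enters the FNM decision; signs are
carried through as annotations and aggregated later. Induced topologies are
reported as canonical graph6 strings; canonicalization is by exhaustive
search over all k! orderings (at most 720 for k = 6), selecting the
lexicographically maximal upper-triangle bit string, so no external
canonical-labeling code is needed.

## Inputs and the filters applied before enumeration

The enumeration network is derived from the raw PPI edge table in three
steps, in this order:

1. deduplication, self-loop removal, optional restriction to physical
   interactions (BioGRID-style input);
2. removal of intra-complex edges — edges between two genes annotated to the
   same protein complex — because the aim is cross-complex feedback, not
   complex architecture. Removal triggers when the genes share *any*
   annotated complex, the conservative reading; multi-complex genes
   participate in the trigger;
3. removal of hub nodes with degree ≥ d_max (default 50; 25 and 100 are
   conventional variants). Degrees are computed once, before any deletion.

Placing the degree filter last means d_max constrains the network actually
searched; the alternative order is available via
`pipeline_config(dmax_before_intracomplex = TRUE)`. The GI network is built
by thresholding a quantitative score table at its empirical tails: the top
and bottom `tail_fraction` (default 0.05) of scores become positive and
negative GI edges respectively. Quantiles use linear interpolation between
order statistics with inclusive comparisons. When a gene pair is measured
more than once, the score of maximal absolute value is retained before
thresholding (strongest evidence). By default the GI network used in the
FNM test is *not* degree-filtered (`filter_gi_degree = FALSE` switches this).

## Null models

`rewire_network()` implements degree-preserving randomization by repeated
double-edge swaps (u–v, x–y) → (u–x, v–y), rejecting swaps that would create
self-loops or duplicate edges, with `ceiling(10 * |E|)` attempts by default.
For signed GI networks the sign and score ride with the swapped edge, so the
sign multiset is conserved exactly. `randomized_motif_summary()` compares
observed per-topology counts against R randomized replicates (replicate r is
seeded `seed + r`, so runs reproduce across machines): mode `ppi_random`
re-enumerates graphlets on rewired PPI networks; mode `gi_random` keeps the
PPI occurrences fixed and re-tests FNM status against rewired GI networks.
R = 30 replicates is the default; on the bundled fixtures the null mean of
total counts changes by well under 10% between R = 15 and R = 30, which is
the stabilization the default is based on.

## Downstream analyses

**Clustering.** FNM node sets are agglomerated greedily: the pair of current
clusters with the largest gene-set intersection is merged while the
intersection has at least `min_overlap` genes (default 2 — the weakest
non-trivial overlap; the metric is an absolute shared-gene count, not
Jaccard). Ties go to the smallest pair of cluster indices, making the output
deterministic. Both choices are assumptions: published descriptions of
"iteratively merging maximally overlapping motifs" fix neither the metric
nor the stopping rule.

**Complex-merged network.** Every PPI and GI edge inside any FNM is mapped
through the complex annotation: single-complex genes collapse into their
complex node, unannotated genes remain as *auxiliary* nodes, multi-complex
genes are dropped entirely. Repeated occurrences of the same gene-level edge
in different FNMs each count, so edge multiplicities reflect FNM support.
Per complex pair, the consensus GI score is (n_pos − n_neg)/(n_pos + n_neg)
in [−1, 1]; complex-pair edges are also partitioned into PPI-and-GI,
PPI-only, and GI-only fractions.

**Restricted betweenness.** For auxiliary nodes, centrality is summed only
over shortest paths whose endpoints are complex nodes (unweighted paths,
raw unnormalized pair dependencies; rankings are scale-invariant, so no
normalization is applied). The implementation is a Brandes-style single
source accumulation restricted to endpoint targets; the test suite checks
it against explicit enumeration of all shortest paths.

**Co-regulation.** A motif's transcriptional co-regulation score is the mean
pairwise cosine similarity of its genes' expression-change profiles.
Missing values are handled pairwise-complete (the cosine for each pair uses
only conditions where both genes have values, requiring at least two);
profiles are used as given, without centering, because the inputs are
already log-ratio changes. Scores are pooled across k before taking the top
5% / 1% flags (inclusive thresholds); per-k empirical CDFs are also emitted.

**Enrichment.** Fisher's exact test (minimum-likelihood two-sided, via
`fisher.test`) compares suppressor-pair content of FNMs against PPI motifs,
with a control sample of non-FNM motifs matched on the (k, gi_count)
histogram of the FNMs. The Wilcoxon–Mann–Whitney test compares per-motif
fractions (not per-gene indicators) of essential genes and complex
subunits; it is exact by enumeration up to a combined n of 12 and uses the
tie-corrected normal approximation with continuity correction beyond that.

## The synthetic fixture generator

`generate_fixture()` emulates the full input bundle — PPI edge list, GI
score table, complex annotations, essential/TF/metabolic gene lists,
suppressor pairs, and a gene × condition expression matrix — from a seeded
specification, together with a ground-truth manifest. Its defaults define
the package's standard test conditions and were chosen once:

- 90 genes, Erdős–Rényi background at p = 0.008 — a sparse background, as
  after hub filtering, sized so the full pipeline with 30 randomizations
  per mode completes in about two minutes;
- 4 complexes of 3–5 genes, added as cliques (their intra-complex edges
  exercise the removal filter);
- 6 planted FNMs with k = 3, 3, 4, 4, 5, 6. Each planted motif has a random
  connected topology, GI edges covering the source-to-distant-layer span,
  and a total GI count *exactly at the ceiling* ceiling(0.5·k(k−1)/2) — the
  hardest case that still qualifies. Planted GI scores are placed beyond
  the empirical tails of the background score distribution, so they are
  significant at any background;
- motifs alternate between a "direct" design (the two embedded complex
  subunits share a PPI, populating the PPI-and-GI overlap class) and a
  "mediated" design (the subunit pair is kept a non-edge, so the complexes
  communicate only through fresh auxiliary genes, which then carry non-zero
  restricted betweenness). A pair-state registry prevents two motifs from
  imposing contradictory designs on the same subunit pair;
- background PPI edges inside a planted node set are suppressed, so planted
  topologies and layerings survive verbatim into the enumeration;
- suppressor pairs are drawn from planted GI edges at 3× a background rate;
  expression profiles of the first half of planted motifs share a latent
  condition response (effect 2, noise SD 1, 20 conditions).

What the generator does **not** emulate: the heavy-tailed degree
distribution of real PPI networks, correlated GI profiles, measurement
noise structure, or realistic complex overlap. Passing tests therefore
demonstrate algorithmic correctness and end-to-end reproducibility on
controlled inputs, not biological performance on genome-scale data.

## Numerical choices and degenerate inputs

- Empirical quantiles everywhere are `stats::quantile` type 7 with inclusive
  comparison at the threshold; a GI table with all-identical scores is
  rejected as degenerate.
- Cosine similarity is undefined (NA) for zero vectors or fewer than two
  shared conditions; motifs with fewer than two expressed genes get NA
  scores and are excluded from quantile computation.
- Zero-margin 2×2 tables return p = 1 with an undefined odds ratio.
- `rewire_network` on fewer than two edges returns its input with a warning;
  a triangle admits no valid swap and passes through unchanged.
- All node iteration is in sorted identifier order and every stochastic step
  takes an explicit seed, so every pipeline output is byte-reproducible;
  outputs carry a configuration hash and a run directory refuses
  intermediates from a different configuration.

## Problem sizes used in tests

Enumeration correctness is verified exhaustively against a brute-force
subset census on 20 seeded Erdős–Rényi graphs (n = 25, p = 0.15) for
k = 3–5, and on smaller graphs for the remaining properties. The
determinism check runs the complete pipeline twice on the standard fixture.
These sizes keep the whole suite in the minutes range while exercising
every code path; they are scaled-down study conditions, not performance
benchmarks.

## Known limitations

- Enumeration is exact and exhaustive; there is no sampling mode, so very
  dense networks at k = 6 are expensive. The intended workflow applies the
  hub filter first, which is also what makes k = 6 feasible on the yeast
  PPI scale.
- Occurrence tables are held in memory as plain data frames (hundreds of
  thousands of rows at study scale fit comfortably); there is no
  disk-backed occurrence store. Pipeline stages persist their outputs with
  a configuration hash — a run directory refuses intermediates from a
  different configuration — but stages are re-executed rather than resumed
  on a re-run.
- Canonicalization by permutation search is limited to k ≤ 8.
- The clustering is greedy and order-stable but, like any greedy
  agglomeration, not guaranteed to find a globally optimal merge sequence.
- graph6 encoding supports up to 62 nodes (single size byte), which covers
  all motif sizes here.
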