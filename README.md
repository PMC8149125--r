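# xconcord

Cross-species concordance and network analysis of disease transcriptomes.

## What problem this solves

Transcriptomic studies of neurodegenerative disease — Huntington's disease
being the motivating case — produce long lists of differentially expressed
genes (DEGs) in each model system: post-mortem patient striatum, knock-in
mouse striatum, and *Drosophila* expressing mutant Huntingtin in neurons or
glia. The scientific questions this package addresses are:

1. Which expression changes are **conserved**: dysregulated in the same
   direction in all three species, allowing for evolutionary divergence
   and convergence in gene families?
2. Is that overlap **larger than chance** for gene sets of these sizes?
3. What **biological modules** do the conserved genes form in a
   protein-protein interaction (PPI) network, and are those networks more
   connected and cluster-rich than random draws from the expressed
   proteome?
4. Which module members are the best **candidate modifiers**, and did
   perturbing them **improve behavior** in a longitudinal climbing
   (negative geotaxis) screen?

It is written for computational biologists running or reanalyzing this
kind of multi-species screen design.

## The core model

**Concordance by homology components.** Each pairwise ortholog map is a
bipartite graph whose nodes are species-tagged genes; merging the
fly–human, fly–mouse and mouse–human maps gives one undirected graph *G*.
For a direction *d* (up or down), induce *G* on the per-species DEG sets
and take connected components. A component whose members cover all
required species (default: human, mouse, fly) is concordant, and every
gene in it is a concordant DEG — no one-to-one mapping is forced, so a
single human gene may be vouched for by several fly paralogs.

**Overlap null.** For each species, draw a uniform random gene set of the
observed DEG-set size from the species' full gene universe, recompute the
concordance statistic (concordant human genes by default), and repeat
(20,000 draws by default). The observed statistic is summarized as
`z = (obs − mean)/sd` with a normal-approximation tail probability plus
the empirical tail fraction `(r + 1)/(n + 1)`.

**Networks.** Interaction edges are kept when confidence > 0.7 (0–1000
STRING-style integer scores are auto-scaled); communities come from the
map equation (InfoMap, best of 10 seeded trials by codelength); clusters
with fewer than four nodes are dropped. Connectivity (mean degree, mean
betweenness) and post-filter cluster counts are compared against
size-matched random draws from a background proteome (e.g., 471 from
15,884 striatum-expressed proteins, 1000 times). Clusterings of the glial
and neuronal networks are compared pairwise by upper-tail hypergeometric
tests (match at p < 1e-5); clusters are tested for enrichment in external
gene lists by one-sided Fisher tests; candidates are ranked within
clusters by the cumulative rank-score of node degree and betweenness.

**Screen scoring.** Percent improvement of a modifier genotype over the
positive control is the day-averaged relative difference of mean climbing
speeds over a 9-day trial, with a within-day label-permutation p-value and
a replicate-bootstrap confidence interval.

A synthetic-data generator (`simulate_study()` and the `gen_*` functions)
produces all pipeline inputs with planted ground truth, so every stage is
testable end-to-end without external data.

## Worked example

```r
library(xconcord)

maps <- list(
  data.frame(species_a = "human", gene_a = c("SYT13", "NRXN3"),
             species_b = "fly",   gene_b = c("Syt-b", "nrx-1")),
  data.frame(species_a = "mouse", gene_a = c("Syt13", "Nrxn3"),
             species_b = "fly",   gene_b = c("Syt-b", "nrx-1")),
  data.frame(species_a = "human", gene_a = "GRM1",
             species_b = "mouse", gene_b = "Grm1"))
graph <- build_merged_graph(maps)
fit <- concordant_components(
  graph,
  deg_sets = list(human = c("SYT13", "NRXN3", "GRM1"),
                  mouse = c("Syt13", "Grm1"),
                  fly   = c("Syt-b", "nrx-1")),
  direction = "down")
fit
#> Concordance (down-regulated; requires human+mouse+fly)
#>   3 induced components, 1 concordant
#>   concordant genes: human=1, mouse=1, fly=1
```

Only the `SYT13` component is concordant: its human, mouse and fly members
are all downregulated. The `NRXN3` component misses the mouse DEG set and
the `GRM1` component has no fly ortholog, so neither counts.

The same machinery at study scale, on simulated data with planted signal:

```r
sim  <- simulate_study(preset = "study-shape", seed = 1)
pipe <- run_study_pipeline(sim, n_overlap_samples = 1000, rng_seed = 2)

pipe$overlap_null$down
#> Resampling null for 'concordant_human_genes_down' (1000 samples, upper tail)
#>   null mean 16.98, sd 4.199
#>   observed 191  ->  z = 41.441, p(normal) = 0, p(empirical) = 0.000999

pipe$condition$down$counts
#>        glia      neuron        both   glia_only neuron_only       union
#>         137         132          78          59          54         191

unlist(planted_recovery(sim, pipe))
#>       up     down  overall
#> 0.987500 0.993750 0.990625
```

191 human genes are called concordantly downregulated against a chance
expectation of ~17 (z ≈ 41; the normal tail underflows double precision,
which is why the empirical tail is reported alongside), split across the
glial and neuronal fly conditions; 99% of the planted concordant
components are recovered through the DEG filters and the homology graph.

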