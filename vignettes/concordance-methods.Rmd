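---
title: "Cross-species concordance analysis: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species concordance analysis: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xconcord)
```

# The analysis

`xconcord` implements a comparative-transcriptomics workflow for asking
whether a disease signature is conserved across evolutionarily distant
models — here framed around Huntington's disease, with human striatal
tissue, knock-in mouse striatum, and *Drosophila* expressing mutant
Huntingtin in neurons or glia. The pipeline has six analytic stages plus a
synthetic-data generator that reproduces their statistical structure so the
whole chain can be exercised and benchmarked without external downloads.

## Differential-expression filtering

Upstream model fitting (negative-binomial GLMs, microarray summaries) is
out of scope; the package consumes summary tables and applies this screen
design's decision rules:

* **Probe-level (microarray) rule** — `call_degs_human()`: a gene is
  dysregulated in a direction if *any* mapped probe has linear |FC|
  strictly > 1.2 (equivalently |log2FC| > 0.263) and BH-FDR strictly <
  0.05. The fold-change dialect (`linear` vs `log2`) must be declared;
  silently mixing them shifts the threshold. When significant probes
  disagree in sign the gene is emitted in *both* directions with
  `conflict_flag = TRUE` — the existence rule is kept literal and the
  ambiguity made visible, with downstream set extraction dropping flagged
  genes by default. Analyses of glial-progenitor (hESC-derived OPC/APC)
  DEG lists conventionally use FDR < 0.1; that is a per-input threshold
  argument, not a separate rule.
* **Any-contrast union rule** — `call_degs_any_contrast()`: a gene is
  dysregulated if FDR < 0.05 in at least one contrast (model × driver ×
  timepoint, or a single continuous-trait contrast), taking only the sign
  of the change. Genes whose significant contrasts disagree in sign are
  excluded from both direction sets and reported in a side channel:
  direction-specific concordance needs one direction per gene per species.
  Both comparisons are strict inequalities, as the thresholds are printed.

`bh_adjust()` wraps the Benjamini–Hochberg step-up procedure; when a table
arrives with raw p-values only, FDR is computed within each contrast.

## Homology concordance

The three pairwise ortholog maps (fly–human, fly–mouse, mouse–human) are
merged into one simple undirected graph over species-tagged gene nodes
(`build_merged_graph()`). No one-to-one mapping is imposed: divergence and
convergence appear as components with several genes per species. Inducing
this graph on the direction-matched DEG sets and taking connected
components (`concordant_components()`), a component containing nodes of
all required species (default: all three) marks *every* member gene as
concordant. Ortholog scores are carried but unused by default
(`min_score = 0` keeps low-confidence edges — excluding them would
re-impose near-one-to-one mappings); a score floor is available. `partition_by_fly_condition()`
repeats the computation with the fly set taken as the glial-driver set,
the neuronal-driver set, and their union, reporting the human-gene
concordant sets per condition and their intersection.

## Resampling overlap null

Could the concordant overlap arise by chance from sets of these sizes?
`overlap_null_test()` draws, for each species, a uniform random gene set
of the observed DEG-set size from that species' full universe, re-runs the
concordance computation, and records a statistic — by default the number
of concordant human genes (matching how concordant DEGs are counted and
displayed), with the concordant-component count behind a switch. This
"resample the inputs, recompute the output" scheme makes the observed
statistic exchangeable with the null draws; the alternative reading
(draw sets sized like the observed *output*) is available as
`scheme = "output_sizes"`. Significance is summarized two ways, always
together: a z-score with a normal-approximation tail (required to express
extreme separations — an empirical tail can never fall below
`1/(n_samples + 1)`) and the empirical tail fraction `(r + 1)/(n + 1)`.
The default is 20,000 resamples; 2 × 10^5 is in routine use for the same
analysis and is just `n_samples = 2e5`. A zero-variance null (e.g., a
saturated universe) is an explicit error rather than a silent `Inf`.

## Interaction networks

`build_ppi_network()` thresholds a weighted interaction table at
confidence strictly > 0.7, auto-detecting the 0–1000 integer score dialect
(a score of 700 is 0.700 and is *not* retained; 701 is). Confidence gates
edge existence only: degree, betweenness and clustering treat retained
edges uniformly, because the connectivity proxies are reported unweighted
(a weighted-traversal switch exists on `node_centrality()`).
`detect_communities()` optimizes the map equation (InfoMap) with 10
independent trials by default, keeping the lowest-codelength partition;
per-trial seeds are derived from one seed so longer trial sequences extend
shorter ones, making best-of-n monotone. Exact equivalence with any
specific optimizer build is deliberately not a contract — recovery of
planted partitions is the test surface. `filter_small_clusters()` reads
"fewer than four nodes" literally: sizes 1–3 are removed, size 4 kept.
`connectivity_null()` rebuilds size-matched networks from random
background draws (e.g., 471 proteins from a 15,884-protein striatal
background, 1000 times) and locates the observed mean degree, mean
betweenness, and post-filter cluster count in those nulls, upper-tailed:
the question is whether the observed network is *more* connected and
*more* cluster-rich than chance. Z-scores are reported per network;
aggregation across networks is left to the caller.

## Cluster comparison, enrichment, prioritization

`pairwise_cluster_similarity()` compares two clusterings by upper-tail
hypergeometric overlap of every cluster pair, with a raw p < 1e-5 match
threshold — the stringent cutoff substitutes for multiplicity adjustment,
so none is applied. The universe is a parameter; the union of the two
networks' node sets is the default (the smallest set containing every
comparable gene; there is no canonical choice, so it is explicit and
changeable). `fisher_enrichment()` tests a cluster
against an external gene list (GMT input supported); its one-sided exact p
equals the hypergeometric tail on the same 2×2 counts, and the odds ratio
is the unconditional sample OR with a Haldane–Anscombe value for display
only when the plain ratio is 0/0. `centrality_rank_score()` ranks nodes
within each cluster by degree and by betweenness (rank 1 = largest,
average ranks on ties) and sums the two ranks; low cumulative rank-scores
mark candidates central by both measures, ordered with ties broken by
higher degree then node id.

## Behavioral screen scoring

Climbing (negative geotaxis) trajectories are summarized per genotype and
day as mean ± SEM (`summarize_trajectory()`; SEM is reported as 0 with a
flag when n = 1). The screen effect size is the **percent improvement**
over the positive control: the day-averaged relative difference of the
day-mean speeds, `100 · mean_d[(m_exp(d) − m_ctrl(d))/m_ctrl(d)]`, over
the shared days clipped to a 9-day window from trial start. "Percent
improvement over a trial" admits several formalizations; this one was
chosen as the simplest unit-free summary of the quantity, and an
area-between-curves alternative is available (`method = "auc"`). Days with a control mean of
exactly 0 are excluded with a warning. Inference is a within-day
label-permutation test on `|percent improvement|`
(`trajectory_permutation_test()`, p = (r+1)/(n+1)) — deliberately a
design-free substitute for nonlinear random mixed-effects curve modelling,
which is out of scope here; this substitution is intentional and should be
kept in mind when comparing p-values with curve-based analyses.
`screen_score()` adds a within-day replicate bootstrap percentile CI.

# The synthetic-data generator

The generator is first-class, tested code. Its defaults are the simulated study
conditions used throughout the tests and the acceptance script:

* `gen_universe()`: three gene universes joined by a mixed-topology
  homology map — fractions 0.5 / 0.2 / 0.1 / 0.2 of one-to-one /
  one-to-many / many-to-many / orphan genes by default. Every non-orphan
  component is connected across all its species pairs.
* `gen_deg_stats()`: planted concordant components receive p ~
  Uniform(0, 1e-4) with a component-wide direction (concordance holds by
  construction; a `discordant_fraction` switch flips mouse signs to
  exercise conflict paths); everything else is a pure null with uniform p
  and sign-symmetric fold-changes. Only the rank/threshold structure of
  summary statistics matters downstream, so no parametric alternative is
  modelled. Condition labels (both / glia-only / neuron-only) are
  allocated deterministically within each direction so planted counts are
  parameters, not draws.
* `gen_ppi_edges()`: a planted-partition module (default 5 blocks × 20
  nodes, within-edge probability 0.3, between 0.01) embedded in a larger
  proteome; true within-block edges draw weights from U(0.75, 0.999)
  (clearing the 0.7 threshold), spurious edges from U(0.2, 0.8) (mostly
  not). Optional dense sub-threshold blocks exercise the size filter.
* `gen_behavior()`: vial-mean speeds `max(0, s0 − rate·day + ε)`, with
  s0 = 20 mm/s, positive-control decline 1.5 mm/s/day (a rapid but still
  age-dependent collapse over a 9-day trial), healthy-control decline
  0.35, replicate noise SD 1 mm/s, 6 replicates × 9 days. A modifier's
  mean curve is `(1 + improvement)` times the positive-control curve, so
  the planted improvement is exactly the day-averaged relative difference
  — noiseless generation recovers it to machine precision.

`simulate_study(preset = "study-shape")` assembles a desk-scale study:
3,000 / 3,600 / 3,200 human/mouse/fly genes; 160 concordant components
planted per direction, split 40/30/30% across both/glia-only/neuron-only;
human probe-level, mouse continuous-trait, and fly 2-driver × 2-model ×
3-timepoint tables; interaction blocks (three shared, one glia-specific,
one neuron-specific) over planted human genes inside a 15,884-protein
background; and a six-genotype screen with improvements from +40% to
−15%. These sizes are the package's chosen dress-rehearsal scale: large
enough that filter calibration, null separation and cluster matching
behave as they would at full scale, small enough to iterate on freely.

What the generator does *not* emulate: read-level data, normalization and
batch effects, correlated genes within a contrast, probe cross-
hybridization, annotation errors in ortholog maps, or real interaction-
network degree heterogeneity. Passing tests therefore demonstrate that the
decision rules, graph algorithms and resampling machinery are correct and
calibrated under the assumed structure — not that the biological
conclusions of any particular dataset would replicate.

# Numerical and degenerate-input choices

* All threshold comparisons are strict (`>` / `<`), matching how the
  cutoffs are printed; boundary values (FC = 1.2, score = 700, p = alpha)
  are excluded by construction and covered by tests.
* Hypergeometric tails come from `phyper` with a log-space option; the
  Fisher enrichment p is computed as that tail (they are the same test on
  fixed margins) and cross-checked against `fisher.test` in the suite.
* A resampling null with zero variance raises an error naming the cause
  rather than returning an infinite z.
* Community labels are contiguous integers in order of first appearance;
  unassigned (filtered) nodes are `NA`, never label 0.
* Ties in centrality ranks use average ranks; candidate ordering breaks
  ties by higher degree, then lexicographic node id, so output is
  deterministic and row-order invariant.
* Every stochastic function takes an explicit seed and is bit-reproducible
  given it; derived per-trial/per-stage seeds stay within R's 32-bit
  integer range.

# Known limitations

* The merged homology graph treats gene identifiers as opaque strings per
  species; identifier translation (Entrez/FlyBase/MGI) must happen
  upstream.
* The permutation screen test conditions on day and ignores
  autocorrelation along a vial's trajectory; with very few replicates its
  p-values are coarse (resolution 1/(n_perm + 1)).
* The normal-approximation overlap p extrapolates far beyond the resampled
  support; it is reported for comparability, with the empirical tail
  always alongside.
* `detect_communities()` inherits the two-level map equation's resolution
  behaviour; very small, sparsely connected modules may merge, which is
  why planted-recovery (not partition identity) is the tested contract.
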