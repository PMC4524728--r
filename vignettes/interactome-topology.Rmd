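---
title: "Rich-club, knotty-centre and module architecture of disease interactomes"
author: "netarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rich-club, knotty-centre and module architecture of disease interactomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netarch)
library(igraph)
```

## Scope and model

`netarch` characterises the architecture of an undirected, unweighted
protein–protein interaction network. Edge confidence scores (e.g. STRING
combined scores) act only as a load-time filter — `read_scored_edges()`
keeps edges with score ≥ `score_min` (default 0.4, the conventional
medium-confidence cutoff), auto-rescaling integer-dialect scores by 1/1000 —
after which every measure is computed on the simple unweighted graph.
Self-loops are dropped (the node is kept) and duplicate pairs merge on the
maximum score. Node identifiers are opaque case-sensitive strings; no
accession validation or mapping is attempted.

## Global topology

* **Average path length** is the mean geodesic distance over *connected*
  unordered pairs. Restricting to the largest component instead is exposed
  as `scope = "largest_component"` because both conventions circulate in
  the interactome literature and they differ on fragmented networks.
* **Global efficiency** sums inverse distances with disconnected pairs
  contributing 0, so it is well defined on fragmented networks; it equals 1
  exactly on a complete graph.
* **Clustering** is the local triangle density, 0 for degree < 2; the
  network-level value is the unweighted mean over nodes.
* **Degree power law**: discrete MLE with KS-minimising `xmin` (the
  `plfit` approach, via `igraph::fit_power_law`). A log–log regression on
  the degree spectrum is selectable as a fallback; MLE is the default
  because regression on binned log frequencies is known to bias the
  exponent. Degenerate degree sequences (fewer than 10 positive degrees or
  3 distinct values) raise an error rather than returning a meaningless fit.

## Null models

Rich-club normalisation and the small-world index compare against
degree-preserving randomisations: double-edge swaps that reject self-loops
and multi-edges, 10 attempted swaps per edge per member by default.
Connectedness is *not* enforced — enforcing it biases null clustering on
sparse graphs, and nothing in the analysis requires connected nulls. Member
`i` of an ensemble uses seed `seed + i - 1`, so ensembles are reproducible
to machine precision and could be generated in parallel without changing
the result. The small-world index is the Humphries–Gurney sigma,
`(C / C_rand) / (L / L_rand)` with ensemble-mean denominators; sigma > 1
indicates small-world organisation, and a clique (degree-rigid, its own
null) scores exactly 1.

## Rich-club detection

With `S(k) = {i : deg(i) > k}` (strictly greater throughout),

$$\varphi(k) = \frac{2\,|E(S(k))|}{|S(k)|\,(|S(k)|-1)},\qquad
\rho(k) = \frac{\varphi(k)}{\varphi_{\mathrm{random}}(k)}$$

where the denominator is the ensemble mean. `phi` is reported as an
explicit `NA` when fewer than two nodes qualify. The profile covers every
`k` from 0 to the maximum degree minus one; because rewiring preserves
degrees exactly, the ks defined in the observed network are defined in
every member.

**Regime calling.** Published analyses typically shade the rich-club range
on a plot without stating a rule. The package's rule: the *longest
contiguous run* of `rho(k) > rho_min` (default 1), ties resolved to the
lowest degree, `NULL` when no k qualifies; undefined `rho` breaks a run.
Interval endpoints are inclusive. Club membership is `deg > k_lo`, the
lower regime bound, exposed as the regime argument of `club_members()`.

**Significance.** Per k in the regime, a one-sided one-sample t-test of
the null `phi(k)` sample against the observed value (alternative: observed
exceeds the null mean); zero-variance nulls fall back to direct comparison
with a warning. The pooled value is the arithmetic mean of per-k p-values
across the regime — the "average p-value across the range" convention.
This is the method as practised; users should know its limitation: with
hundreds of ensemble members the t statistic scales the observed excess by
the standard error of the null *mean*, so essentially any excess at a
regime k is certified as significant. Against a network's own null
ensemble, where `rho` hovers around 1, the regime ks are by construction
the ks where the observed value exceeds the null mean, and the pooled
p-value is therefore small even in the absence of genuine structure (an
empirical z-score against the null standard deviation would behave more
conservatively; the package deliberately implements the t-test as the
method specifies). Planted-structure recovery, not self-null calibration,
is the meaningful validation of this statistic.

## Centrality battery

Degree, unnormalised Brandes betweenness, Wasserman–Faust closeness
(`((n_c-1)/(N-1)) · ((n_c-1)/\sum d)`, well defined on disconnected
networks, 0 for isolated nodes) and the brokering coefficient
`(deg_i/(N-1))(1 - C_i)`. The brokering formula is the
normalised-degree-times-one-minus-clustering reading of the "broker"
concept — nodes that connect many neighbours which are not connected to
each other; the originating literature gives no printed formula, so the
choice is documented here prominently. z-scores standardise over connected
nodes only (isolated nodes would otherwise drag the mean). The central
core is the set of nodes above `sd_mult` standard deviations on *all
three* centralities; the default is 3, with 2 also in circulation for more
permissive cores — the threshold is a parameter, not a hidden constant.

## Knotty centrality

$$KC(S) = \underbrace{\frac{2|E(S)|}{|S|(|S|-1)}}_{\text{internal density}}
\times \underbrace{\frac{\sum_{i \in S} b_i}{\sum_{i \in V} b_i}}_{\text{betweenness share}}$$

with raw betweenness (normalisation cancels in the share). The search runs
on the largest component; a graph whose betweenness is identically zero
(e.g. disjoint edges) has no connective core and returns `NULL`. The
heuristic is a deterministic steepest-ascent hill-climb over single
add-or-remove moves, restarted from every pair among the five
highest-betweenness nodes. Score ties resolve toward the *larger* subset —
on a clique with a pendant node, `{two clique members}` and the full
clique tie exactly, and the full clique is the scientifically meaningful
core — implemented as a terminating plateau-expansion pass after the
climb. Exhaustive subset enumeration (default limit 12 nodes) provides the
exact optimum for validation; on the shipped test battery the heuristic
stays above 90% of it and finds the exact maximiser on the barbell
fixture.

## Modules (MCODE-style)

Vertex weight = core number of the highest k-core of the node's closed
neighborhood × that core's density; nodes under `degree_cutoff` (default
2) are unscored. Complexes grow from unvisited seeds in decreasing weight
order, including neighbours whose weight is ≥ `(1 − node_score_cutoff)`
(default 0.2) of the seed weight, bounded by `max_depth`, each node
joining at most one complex; complexes lacking a 2-core are discarded and
modules score density × size. One deliberate refinement: growth only
traverses *triangle-supported* edges (endpoints sharing at least one
neighbour). With equal-weight dense regions, a plain weight-threshold rule
lets a complex leak across a single bridge edge and fuse two unrelated
cliques; requiring triangle support blocks single-bridge leakage while
leaving growth inside dense regions untouched (every edge of a clique of
size ≥ 3 is triangle-supported). No fluff/haircut post-processing is
applied by default. Size filtering is strict (`> min_size`, default 3 —
"more than three nodes"), and the applied cutoff is recorded on the
result.

Collapsing replaces each module by a supernode (weight = member count),
leaves other nodes — or nodes outside `restrict_to`, e.g. non-rich-club
nodes — as singletons, and weights superedges by the count of original
cross-group edges; intra-module edges are dropped, so cross weights plus
intra counts conserve the source edge count. Overlapping assignments
resolve toward the higher-scoring module, then lexicographic id. Collapsed
networks are analysed unweighted downstream.

## Perturbation experiment

`triad_experiment()` removes a targeted 3-node set, measures absolute
changes in global efficiency, path length and clustering (a metric
undefined after removal is recorded `NA`, not an error), and compares with
`n_random` (default 100) *distinct* random triads from a comparison pool —
typically the rich-club members minus the targeted triad. Reported per
metric: the ratio of targeted change to mean random change, and a
one-sided one-sample t-test of the random-change distribution against the
targeted change. Changes are absolute deltas because a removal experiment
reports magnitudes of disruption without a sign convention. Ratios are
scale-free (common rescaling of all changes cancels), and on
orbit-equivalent triads — e.g. the alternating triad of a 6-cycle versus
its complement — the ratio is exactly 1 by symmetry. Note that on a
vertex-transitive graph generally the ratio is *not* identically 1: the
damage of removing three nodes depends on their relative positions, not
just on each node's orbit.

## Enrichment

Over-representation of a node set against a GMT collection:
hypergeometric upper tail `P(X ≥ k)` ("fisher") or the EASE variant with
one hit removed ("ease", the default, matching DAVID's convention since
the tooling this emulates defaults to it). The background defaults to all
network nodes; term sets are intersected with it. Benjamini–Hochberg
adjustment across terms; results carry `enrichment_score = log10(1/p)`
(so the common display threshold p < 1e-10 corresponds to score > 10).
The pathway-interaction network maps each term to a supernode weighted by
its member count and weights term-pair edges by the number of network
edges running between the two sets; an edge whose endpoints lie in both
terms of a pair counts once for that pair — a stated rule, since plotted
figures of this kind never specify one.

## Synthetic study conditions

The generators define the conditions under which the pipeline is
validated; their defaults are fixed, not tuned:

* `gen_scale_free(1050, 21)` — preferential attachment at the scale of a
  ~1,050-node, ~22,000-interaction curated interactome.
* `gen_planted_club(300, 30, p_in = 0.8, p_out = 0.02)` — a 30-node club
  wired at density 0.8 over a 0.02-density periphery. Two parameters are
  not fixed by the emulated conditions and were chosen once as realistic
  for a hub-dominated interactome: club→periphery attachment 0.1 (so club
  degrees dominate the periphery's, as hubs dominate a scale-free
  interactome) and a 0.4 periphery-attachment boost for the first three
  club nodes, planting a dominant central triad analogous to a disease
  network's top hubs.
* `gen_planted_modules(3, 6, bridges = 2)` — disjoint cliques plus
  inter-clique bridges with pairwise distinct endpoints, so no bridge is
  triangle-supported and ground truth is unambiguous.
* `gen_meta_proteome(1083, 10.5)` — per-accession literature frequencies
  from a rounded-up lognormal (`sdlog = 1`, right-skewed like report
  counts per protein), mean-calibrated so the sample mean lands within 10%
  of the target; distinct synthetic report IDs back each count. With
  `degrees` supplied, frequencies are rank-blended with degree (weight
  0.5), emulating hubs being more heavily studied.

Every generator is reproducible from its parameters and seed. What passing
recovery tests show — and do not show: the planted structures are idealised
(clean density contrast, clique modules, a single dominant triad), so
recovery demonstrates correctness of the algorithms, not robustness to the
noise, annotation bias and score heterogeneity of real interactome builds.
Real curated networks also carry literature ascertainment bias that no
generator here models beyond the optional degree–frequency association.

## Numerical choices and problem sizes

Regime runs break on undefined `rho`; t-tests fall back to direct
comparison under zero null variance (warning recorded); greedy moves use a
1e-12 tolerance so floating-point plateaus do not cycle; module and broker
ties break lexicographically by node id, making every result deterministic
for a given seed. The shipped validation uses problem sizes chosen to
exercise each property cleanly: 50-graph oracle batteries at ≤ 12 nodes
(where exhaustive enumeration is exact), 100–200-member null ensembles on
300-node planted networks, and a 1,050-node scale-free graph for the
global-topology summary.

## Known limitations

* The pooled rich-club p-value inherits the anticonservatism of the
  one-sample t-test discussed above; treat it as a ranking device, not a
  calibrated error rate.
* MCODE parameters are the tool's canonical defaults; the triangle-support
  refinement means chain-like (triangle-free) complexes are not grown,
  which is intended for interaction networks but makes the detector blind
  to sparse path-shaped modules.
* The knotty heuristic is greedy and can in principle lodge in a local
  optimum; the exhaustive mode exists precisely to quantify that gap on
  small instances.
* Enrichment is purely local: no live annotation retrieval, no term
  hierarchy, no weighting by evidence codes.
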