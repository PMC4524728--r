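# netarch

Topology analysis for disease protein–protein interaction networks:
rich-club organization, knotty centres, MCODE-style modules, centrality and
brokering profiles, and targeted-removal perturbation experiments.

## The problem

A curated disease interactome — the network of interactions among proteins
reported as dysregulated in a condition, assembled from the literature and a
scored interaction database — is typically scale-free and small-world: a few
heavily connected hub proteins dominate its wiring. `netarch` asks the
questions a systems biologist asks of such a network:

* Do the hubs interconnect more densely than degree-matched chance — is
  there a **rich club**, a "powerhouse" of mutually interacting hubs?
* Where is the **knotty centre**, the subgraph that combines internal
  density with a dominant share of shortest-path traffic?
* How does the network decompose into dense **modules**, and how do those
  modules (or annotated pathways) interact once collapsed into supernodes?
* Which individual nodes form the **central core** (extreme on degree,
  closeness and betweenness simultaneously), which are the top **brokers**
  (high degree, low clustering — linkers of otherwise unconnected
  neighborhoods), and how much damage does deleting the central triad do
  compared with removing random hub triads?

## The statistics at the core

For a degree cutoff `k`, with `S = {i : deg(i) > k}`, the rich-club
coefficient is

    phi(k) = 2 |E(S)| / ( |S| (|S| - 1) )

and is normalized against degree-preserving random networks:

    rho(k) = phi(k) / phi_random(k),

where `phi_random(k)` is the mean coefficient over an ensemble of
double-edge-swap rewirings (1000 by default). A contiguous run of
`rho(k) > 1` is the rich-club regime; per-`k` one-sided one-sample t-tests
of the null `phi(k)` distribution against the observed value are averaged
across the regime into a pooled p-value. Knotty centrality of a subset `S`
is internal edge density times the fraction of total betweenness carried by
`S`; the search is a deterministic greedy hill-climb (exact exhaustive
enumeration is available for small graphs). The brokering coefficient is
`(deg_i / (N - 1)) (1 - C_i)`, and over-representation of node sets against
GMT annotation collections uses the hypergeometric tail (optionally DAVID's
conservative EASE variant) with Benjamini–Hochberg adjustment and the
display transform `log10(1/p)`.

Because public interactome builds are not redistributable, the package
ships generators that plant each structure with recorded ground truth
(`gen_scale_free`, `gen_planted_club`, `gen_planted_modules`,
`gen_meta_proteome`), so the whole pipeline is validated end-to-end by
recovery of known structure.

## Worked example

```r
library(netarch)

pn  <- gen_planted_club(seed = 42)          # 300 nodes, planted 30-node club
cfg <- netarch_config(network = pn$network, n_null = 200, seed = 42)
rep <- run_pipeline(cfg)
print(rep)
```

```
netarch analysis report
  network: 300 nodes, 2171 edges
  rich club: regime k = 6..52, 262 members, pooled p = 8.74e-46
  central core (3): P0001, P0002, P0003
  modules: 4 found, 4 after size filter
```

The rich-club regime `k = 6..52` is the longest contiguous degree range
with `rho(k) > 1`; its pooled p-value (8.7e-46) says the observed `phi(k)`
far exceeds the 200-member null ensemble across that range, and the
returned members cover the entire planted club. The central core is exactly
the planted triad (the three boosted hubs `P0001..P0003`): they exceed 3
standard deviations above the mean on degree, closeness and betweenness at
once. The perturbation stage quantifies their importance:

```r
rep$perturbation$ratio["global_efficiency"]    # 105.08
rep$perturbation$p_value["global_efficiency"]  # 8.6e-201
```

removing the central triad degrades global efficiency about a hundred times
more than removing a random club triad. Individual stages are all exported
(`rich_club_profile()`, `detect_regime()`, `find_knotty_centre()`,
`mcode_find()`, `collapse_modules()`, `triad_experiment()`, `enrich()`, ...)
and accept any named undirected `igraph` object, e.g. one loaded from a
scored STRING-style edge list with `read_scored_edges(path, score_min = 0.4)`.

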