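# diffcornet

Differential Spearman correlation networks for two-group clinical cohorts.

## The problem

In systems physiology, disease is often visible not in any single marker but
in how markers move together. Given two groups of subjects measured on a
shared panel of variables — here a 30-variable panel of blood-pressure
indices, cognitive test scores, depression symptoms, body-composition
indicators, physical-performance tests, serum adipokines/myokines/trophic
factors, and demographic/activity covariates — one can ask whether the
*correlation network* of the diseased group is more densely interconnected
than that of controls ("dyshomeostasis"). `diffcornet` implements that
analysis end to end for anyone comparing correlation-network topology
between two cohorts:

1. **Networks.** For each group, all pairwise Spearman rank correlations
   ρ<sub>S</sub> are computed with pairwise-complete observations; the
   two-sided p-value uses the t approximation
   *t* = ρ√((n−2)/(1−ρ²)) on n−2 df. An undirected edge joins two variables
   iff p &lt; α (default 0.05); edges carry sign(ρ) and weight |ρ|, and all
   panel variables stay in the network as nodes, so both group networks have
   the same node count.
2. **Topology.** Per node: degree, neighbourhood connectivity (mean degree
   of neighbours), stress (the count of all-pairs shortest paths passing
   through the node as an interior vertex), betweenness and closeness; per
   edge: edge betweenness. Shortest-path metrics use the unweighted graph.
3. **Comparison.** Each metric's per-node (per-edge) values from the two
   networks are compared with a tie-corrected Mann–Whitney U test,
   Z = (U − n₁n₂/2)/σ<sub>U</sub> with
   σ<sub>U</sub> = √[(n₁n₂/12)((n+1) − Σ(t³−t)/(n(n−1)))], and effect size
   r = Z/√N where N is the total number of compared values (e.g. N = 60 for
   two 30-node networks). Differential edges (present in only one group) are
   listed for qualitative inspection.
4. **Synthetic cohorts.** Because participant-level data of such studies are
   rarely deposited, a Gaussian-copula generator draws cohorts with any
   target Spearman structure (latent Pearson = 2 sin(πρ<sub>S</sub>/6),
   exact for the copula) and realistic marginals, including a default
   two-group scenario (31 hypertensive vs 18 normotensive subjects).

## Worked example

```r
library(diffcornet)

res <- run_pipeline(pipeline_config(seed = 1, out_dir = "run1"))
glance(res$comparison)
#> # A tibble: 2 × 8
#>   network n_nodes n_edges density n_isolated alpha n_only_here n_shared
#>   <chr>     <int>   <int>   <dbl>      <int> <dbl>       <int>    <int>
#> 1 a            30      52   0.120          0  0.05          24       28
#> 2 b            30      88   0.202          0  0.05          60       28
cat(render_summary(res$comparison), sep = "\n")
#> Network topology comparison (A = reference): 6 metrics, alpha = 0.05
#> degree                      3.47 ± 1.43 vs 5.87 ± 2.69, Z = -3.74, p = 0.000184, r = -0.48
#> neighbourhood_connectivity  3.97 ± 0.8 vs 6.71 ± 1.91, Z = -5.36, p = 8.44e-08, r = -0.69
#> stress                      53.5 ± 38.97 vs 46.27 ± 50.04, Z = 1.02, p = 0.31
#> betweenness                 29.5 ± 23.08 vs 13.47 ± 16.17, Z = 2.90, p = 0.00377, r = 0.37
#> closeness                   0.34 ± 0.04 vs 0.51 ± 0.12, Z = -6.11, p = 1e-09, r = -0.79
#> edge_betweenness            25.38 ± 14.15 vs 8.61 ± 5.92, Z = 7.58, p = 3.52e-14, r = 0.64
#> Edges: 24 only in A, 60 only in B, 28 shared
```

Network A is the normotensive reference, network B the hypertensive group:
B has more edges per node (5.87 vs 3.47) and higher neighbourhood
connectivity, and the negative Z (reference stochastically smaller) with
r = −0.48 / −0.69 quantifies that the hypertensive network is the more
interconnected one — the dyshomeostasis signature. Non-significant rows
(e.g. stress here) print no effect size. `run1/` receives, per group, the
cohort CSV, edge list, node metrics, GraphML and SIF exports (Cytoscape-
ready, with |ρ| as layout weight), plus the comparison JSON/text and a run
log. `autoplot()` works on networks, comparisons and correlation matrices.

Lower-level pieces are exported individually: `default_panel()`,
`correlation_structure()`, `sample_group()`, `correlation_matrix()`,
`build_network()`, `node_metrics()`, `stress_centrality()`,
`compare_networks()`, `mann_whitney()`, `effect_size_r()`,
`compare_groups()` (Shapiro–Wilk/Levene-gated t vs Mann–Whitney),
`assign_group()` and the blood-pressure composites `pulse_pressure()` /
`mean_arterial_pressure()`.

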