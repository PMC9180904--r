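---
title: "Differential correlation networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential correlation networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffcornet)
```

This vignette documents the statistical model behind `diffcornet`, the
tunable parameters, the synthetic-cohort generator, the numerical choices,
and the known limitations. It is the reference for *why* the package works
the way it does; the README shows *how* to run it.

## The procedure

The pipeline compares the correlation structure of a shared variable panel
between two groups of subjects — in the default scenario, older adults with
poorly managed hypertension (PMHTN, n = 31) versus a normotensive reference
group (NTN, n = 18) over a 30-variable panel of blood-pressure indices,
cognitive scores, depression symptom intensity, body composition, physical
performance, serum biomarkers and social/demographic covariates.

**Correlation.** For every pair of variables, the Spearman rank correlation
is the Pearson correlation of mid-ranks on pairwise-complete observations
(ties get average ranks). Its two-sided p-value uses the t approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom, where $n$ is
the pairwise-complete count recorded per pair. The approximation is accurate
for the cohort sizes involved (n ≥ 18) and degenerates gracefully
($|\rho| = 1 \mapsto p = 0$). An exactly computed permutation p-value was
considered and rejected as default: at n ≈ 30–50 the t approximation errs by
far less than the edge-threshold granularity, and determinism matters for
byte-identical reruns.

**Network.** An undirected edge joins a pair iff its raw p-value is
*strictly* below α = 0.05. No multiple-testing correction is applied by
default across the 435 pairs: the method's edge definition *is* "a
significant correlation at α", and the downstream topology comparison is
explicitly a comparison of networks built that way. A Benjamini–Hochberg
mode (`build_network(..., adjust = "BH")`) is available for users who want
FDR-controlled edges. Every panel variable remains a node whether or not it
has edges, so both group networks always have the same node count — the
topology comparison then reflects connectivity, not panel coverage.

**Topology.** Node metrics follow the unweighted NetworkAnalyzer-style
definitions: degree; neighbourhood connectivity (mean degree of neighbours,
undefined for isolated nodes); stress (the integer count of all-pairs
geodesics passing through the node as interior vertex, each distinct
geodesic counted once per unordered endpoint pair); betweenness (fractional
geodesic load, unnormalized by default); and closeness as
(nodes reachable)/(sum of distances), i.e. reciprocal mean distance within
the node's component, which stays well-defined on the visibly disconnected
networks this analysis produces (isolated node → 0). Edge betweenness is
offered in both the standard fractional form and a literal count form.
Shortest paths are computed on the **unweighted** graph even though edges
carry |ρ| weights: the weights are retained for layout/export, but the
metric definitions used for group comparison are count-based. Stress is
accumulated from geodesic counts obtained as powers of the adjacency
matrix — $\sigma_{st} = (A^{d_{st}})_{st}$, since any walk whose length
equals the graph distance is a shortest path — and a geodesic passes
through $v$ iff $d_{sv}+d_{vt}=d_{st}$, contributing
$\sigma_{sv}\sigma_{vt}$ paths. The test suite verifies stress, betweenness
and edge betweenness against an exhaustive geodesic-enumeration oracle on
hundreds of random graphs.

**Comparison.** For each metric, the per-node (per-edge) values of the two
networks form two samples compared by the Mann–Whitney U test with
mid-ranks, tie-corrected variance
$\sigma_U^2 = \frac{n_1 n_2}{12}\big[(n{+}1) - \sum_j (t_j^3-t_j)/(n(n-1))\big]$,
and the normal approximation without continuity correction (the back-story
of that choice: printed Z-values in this literature reproduce exactly
without it). The first sample is the reference group, so Z < 0 means the
comparison group's values are stochastically larger. The effect size is
$r = Z/\sqrt{N}$ with $N$ the total number of compared values — 60 when two
full 30-node networks are compared node-wise — reported only for p < α, to
2 decimals.

## The synthetic-cohort generator

Participant-level data for such studies are typically available only on
request, so the generator is a first-class module: every downstream stage
is tested against cohorts whose ground truth is known.

It is a Gaussian copula. A latent multivariate normal draw with Pearson
correlation $\rho_P = 2\sin(\pi\rho_S/6)$ is transformed by
$\Phi$ and then by each variable's marginal quantile function. The
conversion is the exact latent-Gaussian/Spearman relationship, and because
every marginal transform is monotone, the *population* Spearman of the
output equals the target exactly; the test suite verifies recovery within
±0.03 at n = 5000 across the grid {−0.9, −0.5, 0, 0.5, 0.9}. Marginal
families are normal, lognormal, truncated normal and discrete uniform;
declared fidelity is checked by Kolmogorov–Smirnov statistic < 0.05 at
n = 5000.

The default panel has 30 variables in seven categories. Enumerating the
study's figure-legend abbreviations plus abstract-level covariates yields
31 candidates; "sit and reach" (a flexibility subtest administered but
absent from every network figure) is dropped to reach the stated 30-node
panel, and chronological age is carried in the social/demographic category.
The panel is user-overridable, so none of this is load-bearing.

The default two-group scenario uses a factor model for the latent
correlation: each variable loads 0.7 on its category factor (0.85 for the
four arithmetically entangled blood-pressure indices) plus a global
cardiometabolic-aging factor — loading 0.3 (NTN) vs 0.4 (PMHTN), positive
on pressure, adiposity, age, depression and pro-inflammatory adipokines,
negative on cognition, performance and protective biomarkers. A factor
model keeps the implied matrix positive semi-definite by construction; any
user-supplied target whose implied latent matrix is not PSD is rejected
naming the offending eigenvalue. The loadings were fixed so that the
expected network densities sit near the reported group mean degrees
(≈ 4.7 edges/node hypertensive vs ≈ 3.3 normotensive); group marginals for
age, BMI, body fat and visceral fat use the reported group means/SDs, the
rest are clinically plausible values for community-dwelling older adults.
Missingness, when requested, is MCAR per cell (how the original analysis
handled missing data is unstated), with each column guaranteed at least 4
observed values so every pair stays estimable. Sub-seeds for the two groups
and the missingness stream derive from the master seed by a fixed LCG step
(`(1103515245·seed + 12345 + i) mod (2^31−1)`), so groups are independent
yet the whole study is byte-reproducible from one integer.

What the generator does *not* emulate: instrument-specific measurement
error, floor/ceiling effects of bounded questionnaires beyond truncation,
informative missingness, and medication effects. Passing tests therefore
demonstrate correctness of the *pipeline* under a known joint distribution,
not fidelity of any particular clinical dataset.

## Group assignment and descriptive comparison

Subjects are labelled from hypertension history and the mean of two office
readings: PMHTN requires a diagnosis history AND mean sBP > 140 or mean
dBP > 90 mmHg; NTN requires no history AND both below. All other
combinations — treated hypertensives at goal, untreated elevated readings,
and values exactly at 140/90 (which satisfy neither strict inequality) —
are UNCLASSIFIED and excluded. Pulse pressure is sBP − dBP; mean arterial
pressure uses the standard clinical estimate dBP + PP/3 (no formula is
universal; this one reflects the diastolic-weighted cardiac cycle and is
overridable by supplying the column directly).

The descriptive table gates each variable *per variable*: Shapiro–Wilk
within each group and Levene across groups at α = 0.05; both pass → pooled
t-test, else Mann–Whitney. With three independent gate tests the expected
t-branch rate under ideal normal data is 0.95² × 0.95 ≈ 0.86, which the
test suite checks empirically. Effect sizes: r = Z/√N for the Mann–Whitney
branch; for the t branch the point-biserial conversion
$r = \mathrm{sign}(t)\sqrt{t^2/(t^2+df)}$ — an extension, since Z-based r
is only defined for rank tests.

## Numerical and design choices

- **Strict threshold** p < α (not ≤): ties at exactly α are excluded.
- **Constant columns** have no rank correlation; their pairs are flagged
  missing and can never form edges.
- **Pairwise-complete** observation counts are carried into each pair's
  p-value rather than using a single list-wise n.
- **Isolated nodes** contribute zeros to degree/stress/betweenness and 0 to
  closeness, but are excluded (undefined) from neighbourhood connectivity
  and hence from that metric's comparison samples.
- **Determinism**: every stochastic step takes an explicit seed;
  `run_pipeline()` outputs are file-hash identical across reruns with the
  same configuration, and scenario YAML serialization uses 17 significant
  digits so a round-tripped configuration reproduces the same cohorts
  bit-for-bit.
- **Simulation sizes**: the shipped checks use 200 replicates for
  calibration and power curves, 200 random graphs for the
  metric-vs-enumeration equivalence, and n = 5000 draws for copula
  calibration — sizes at which Monte-Carlo error is comfortably below the
  asserted tolerances while the whole suite stays quick to run.

## Known limitations

**Nodes are not independent observations.** The between-network comparison
treats the 30 per-node metric values of each network as an i.i.d. sample.
They are not: a chance fluctuation in overall edge density shifts every
node's degree, neighbourhood connectivity and closeness together. The
package implements the method as defined — that assumption is intrinsic to
it — but surfaces the caveat in every comparison report, and the test suite
measures its consequence empirically: comparing two networks generated
under *identical* independence structures, the Mann–Whitney comparison
flags the degree distributions at about 3× the nominal 5% rate and
neighbourhood connectivity at ~7×. An independent re-derivation (raw
Bernoulli adjacency sampling with `stats::wilcox.test`) reproduces the same
inflation, confirming it is a property of the procedure rather than of this
implementation. Conclusions drawn from a single pair of networks should
therefore lean on effect sizes and on the qualitative differential-edge
analysis, not on the nominal p-values alone; a permutation-based network
null would control this and is a deliberate non-goal here.

**Power behaviour.** Injecting k disjoint strongly-correlated pairs
(ρ_S = 0.6) into one group produces cleanly monotone detection power for
the degree comparison (≈ 0.16 at k = 0 rising to ≈ 0.70 at k = 15 with the
study's group sizes). Neighbourhood connectivity responds only weakly to
this perturbation: disjoint pairs add degree-1 nodes whose neighbourhood
connectivity is low, partially offsetting the density gain, so its power
curve is nearly flat on top of the inflated null. The power simulations use
common random numbers across k (same replicate sub-seeds for every k) so
the curves reflect signal rather than Monte-Carlo noise.

**Marginal-correlation networks.** Edges are marginal associations;
confounding (e.g. age driving many variables) produces edges that a
partial-correlation or graphical-model analysis would remove. That is by
construction: the method under study is marginal, and partial-correlation
inference is out of scope.

## A small worked run

```{r, eval = FALSE}
res <- run_pipeline(pipeline_config(seed = 1))
glance(res$comparison)
cat(render_summary(res$comparison), sep = "\n")
autoplot(res$analyses$PMHTN$network)
```
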