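---
title: "Methods: network pharmacology of multi-target compounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network pharmacology of multi-target compounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The analysis in one paragraph

Given (i) a disease drug class with its protein targets, (ii) a pathway
collection with per-gene node multiplicities, (iii) a protein–protein
interaction (PPI) network, and (iv) an inverse-docking hit table for a
query compound, the pipeline asks: *which pathways carry the drug class's
therapeutic action, which of the compound's putative targets sit inside
them, and how do those targets organize in the interactome?* The stages
are: three-type hypergeometric pathway enrichment → key-pathway selection →
candidate protein universe → putative targets (docking hits ∩ universe) →
bipartite drug/target/pathway networks with degree diagnostics → minimal
constrained PPI sub-network → simulated-annealing modularity decomposition
→ machine-readable report.

## Enrichment model

All three statistics are upper tails of the hypergeometric law,
$P(X \ge k)$ for $X \sim \mathrm{Hyper}(N, K, n)$, computed by
`stats::phyper`. The upper tail (not the CDF) is forced by the enrichment
semantics: small probabilities mean *more* targets than chance. The three
counting schemes are:

| type | population $N$ | marked $K$ | draws $n$ | observed $k$ |
|------|----------------|------------|-----------|--------------|
| I    | genes in any pathway | pathway members | target genes | targets in pathway |
| II   | all node occurrences | pathway's occurrences | target occurrences | target occurrences in pathway |
| III  | background drugs mapped to ≥1 pathway | background drugs hitting pathway | class drugs mapped | class drugs hitting pathway |

Assumptions worth making explicit:

* **Universe choice (Type I).** $N$ is the set of genes appearing in any
  pathway of the supplied collection, not the genome: targets that map to
  no pathway are uninformative for pathway ranking and are dropped with a
  warning. For the same reason the Type II population spans the whole
  supplied collection — restricting it to target-containing pathways would
  silently change $N$ with the input's composition.
* **Type II exchangeability.** The occurrence-level test treats every node
  occurrence as an independent draw. Occurrences of one gene are not
  independent — a member gene contributes all of its nodes at once — so
  Type II is anti-conservative whenever multiplicities exceed 1. The
  acceptance battery measures this directly: under null synthetic data with
  the default multiplicity level the empirical type-I rate of key-pathway
  selection exceeds the nominal 5% (see `null_typeI_rate` in the acceptance
  output), driven entirely by the Type II component, while the Type I
  component alone is conservative because of discreteness. This is a
  property of the occurrence-level statistic itself and users comparing
  Types I and II should read Type II significance accordingly.
* **Type III background.** Without an explicit background table the class
  is its own background and the statistic is degenerate ($p = 1$
  everywhere); it becomes informative only for a class-vs-all-drugs
  comparison. This keeps the default honest instead of inventing a
  background the data does not contain.
* **Selection rule.** A pathway is key when $\min(p_1, p_2, p_3) < \alpha$
  with raw p-values by default — reproducing the conventional "at least one
  p-value < 0.05" practice — with per-type Benjamini–Hochberg available via
  `correction = "bh"` for modern use. Ranking ties break lexicographically
  by pathway id so output order is deterministic. The selected-pathway
  percentage is reported against the pathway set that entered enrichment.

## Synthetic data: what is emulated, what is not

`synth_config()` defaults define a desk-scale study and are fixed once:

* `n_drugs = 174`, `drug_degree_alpha = 2.5`: per-drug target counts follow
  a truncated discrete power law (inverse-CDF sampling on support
  `1..n_targets`), reproducing the heavy-tailed degree structure of
  drug–target networks; target choice is mildly rank-weighted so the target
  side is heavy-tailed too.
* `n_targets = 50`, `n_proteins = 2000`, `n_pathways = 200`,
  `pathway_size_range = c(20, 120)`: a pathway universe in realistic
  proportion to a curated collection (a few percent of genes are
  drug-class targets; pathways of tens to a hundred members).
* `n_enriched_pathways = 10`, `enrichment_odds = 10`: planted enrichment
  multiplies each target's inclusion weight in the chosen pathways;
  odds 1 is the null.
* `node_count_geometric_p = 0.6`: member node multiplicity is
  $1 + \mathrm{Geom}(p)$ — most genes occupy one node, a minority several,
  emulating repeated boxes on curated pathway maps.
* `sbm_modules = 4`, `sbm_module_size = 15`, `p_in = 0.6`, `p_out = 0.05`:
  the PPI is a planted-partition stochastic block model, giving ground
  truth for module recovery.

One master seed expands into fixed per-generator offsets so stages can be
regenerated independently; generators save and restore the caller's RNG
state.

Deliberately **not** emulated: real pathway topology (memberships are
exchangeable draws, not reaction graphs), drug chemistry and ATC structure
(codes are synthetic labels), PPI degree heterogeneity within blocks
(hubs arise only from block densities), and any correlation between a
gene's multiplicities across pathways. Passing tests therefore demonstrate
correctness of the statistics and algorithms under controlled conditions,
not that real databases would reproduce any particular published count.

## Degree diagnostics

`degree_fit()` histograms one side of a bipartite network (zeros included
in the histogram) and fits OLS to $(\log k, \log p(k))$ over positive
degrees with nonzero counts, mirroring the conventional log–log
presentation; the fit is skipped (exponent `NA`) below 3 distinct positive
degrees. Logarithmic binning and maximum-likelihood exponent estimation are
deliberately omitted — the diagnostic supports a qualitative heavy-tail
claim, not a precise exponent. Users should know the estimator's known
bias: degrees observed once sit above the true line and flatten the slope,
so exponent recovery is only reliable on large samples (the test suite
demonstrates recovery of a planted exponent at twenty thousand drugs, and
agreement with an independent fit at two thousand).

## Minimal sub-network under the one-intermediate rule

The constraint — two targets may be linked directly or through exactly one
non-target protein — bounds useful intermediates to single "connectors" at
graph distance ≤ 2 from two targets. A general Steiner-tree solver is
therefore unnecessary: feasible groupings are the connected components of
the direct-or-shared target adjacency, and within each component the
minimum-connector problem is a set cover, solved greedily. Each step picks
the connector merging the most currently disconnected target groups; ties
break by total target coverage, then lexicographically by protein id, so
output is deterministic. Direct target–target edges cost nothing and
connector–connector edges are never included, which enforces the
alternation constraint by construction. Targets linkable to no other
target remain as singleton components and are reported in
`excluded_targets`; targets absent from the PPI are reported as unmapped
rather than raised as errors. Per-component solutions are merged into one
output graph — nothing in the constraint couples components, so a global
tree would only add unjustified connectors. Greedy set cover carries the
classical $(1 + \ln m)$ guarantee; the test suite checks the much stronger
empirical behavior that on hundreds of random instances the greedy count
matches the exhaustive optimum ≥ 90% of the time and never exceeds it by
more than one.

## Modularity and annealing

Modularity is the standard undirected Newman form
$Q = \sum_s [\, l_s/L - (d_s/2L)^2 ]$ — the sub-network is an undirected
PPI graph, so the directed ("arc") formulation would double-count
symmetrically. `sa_partition()` anneals each connected component
independently (modularity is separable across components at fixed total
$L$): starting from singletons, each temperature step attempts
`move_factor · n²` single-node reassignments and `move_factor · n`
collective moves (merge of two random modules, or a random bisection of
one module followed by one greedy refinement sweep), accepting worsening
moves with probability $\exp(\Delta Q / T)$.

Numerical choices, all exposed in `sa_params()`:

* `t0 = NULL` calibrates the initial temperature to the mean $|\Delta Q|$
  of a short sample of random moves, so initial acceptance is high and the
  schedule adapts to graph size; a fixed `t0` can be supplied instead.
* `cooling_factor = 0.995` (geometric), `frozen_threshold = 50`
  improvement-free temperature steps to stop, floor `t_min = 1e-8`.
* The number of modules $r$ is not fixed anywhere; it emerges from the
  optimization (empty module labels are always reachable by single-node
  moves).
* The returned $Q$ is always recomputed from scratch on the final
  assignment (self-consistency asserted to 1e−12 in the suite), and the
  best-seen partition is returned, not the last-visited one.
* Degenerate inputs: edgeless graphs are a domain error (Q undefined);
  single-vertex components get their own module.

The suite validates the optimizer against exhaustive enumeration of all
set partitions on connected graphs up to $n = 8$ (Bell(8) = 4140) and on
the two bridged 5-cliques ($n = 10$, 115,975 partitions), against a
label-propagation baseline on random graphs, and against planted
stochastic-block-model labels by normalized mutual information.

## Report arithmetic and determinism

Percentages and potency ratios round half away from zero (half-up), the
convention used when such values are printed; `round_half_up()` is exposed
because base R rounds half to even. Potency ratios compare half-maximal
concentrations in a shared unit per row; values above 1 mean the test
compound is that many fold weaker than the reference. Putative targets are
defined as docking-hit genes intersected with the candidate universe, which
reproduces a docking screen restricted to the universe up front while
accepting unrestricted hit tables; hits outside the universe are listed
separately, and genes with several docked structures collapse to one
putative target by gene symbol. `run_full_analysis()` writes every stage
artifact plus `report.json`; all stochastic stages take explicit seeds, so
reruns are byte-identical, and a failing stage removes its partial
artifacts.

## Problem sizes in the shipped suite

The test and acceptance batteries run at sizes chosen to keep every oracle
exhaustive and every check fast: hypergeometric enumeration to $N \le 40$
(thousands of instances), 2,000 null pathways for the empirical type-I
rate, 200 random connector instances against exhaustive subset search,
modularity brute force to $n = 10$, and a 60-protein planted PPI for
module recovery. These are the package's own validation conditions;
nothing prevents running the pipeline itself at database scale.

## Known limitations

* Type II enrichment is anti-conservative under node multiplicity
  (measured above); a permutation null over gene memberships would fix
  this but is out of scope for the hypergeometric formulation implemented
  here.
* The degree-exponent estimator is biased on small samples by design
  (unbinned OLS), and reported exponents should be read qualitatively.
* Greedy connector selection can exceed the optimum by one connector on
  rare instances (never more, empirically, on the shipped batteries).
* Gene identity is a bare case-sensitive symbol: no identifier mapping is
  attempted, and callers must harmonize drug-target, pathway and PPI
  namespaces before loading.
* The docking stage consumes a precomputed hit table; no docking, scoring
  or structure handling is performed.
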