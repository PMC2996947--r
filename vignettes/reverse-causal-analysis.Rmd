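---
title: "Reverse causal analysis on signed knowledge graphs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse causal analysis on signed knowledge graphs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcanet)
```

## The problem

Transcriptomic and phosphoproteomic profiling of a perturbed biological
system (a drug-treated cell line, a xenograft, a knockout) yields hundreds of
differential measurements, but the measurements themselves rarely name the
mechanism. Reverse causal analysis turns the question around: given a
literature-curated network of signed cause-and-effect assertions among
biological entities, every node of that network is evaluated as a candidate
upstream explanation — a *hypothesis* — for the observed changes, and scored
by how many changes it predicts and how directionally consistent those
predictions are. Hypotheses that hold up across several independent
experiments are merged into a causal network model (CNM) whose explanatory
coverage of each experiment can be quantified. This is explicitly an
explanation of data in the context of existing knowledge, not inference of
novel edges from data.

`rcanet` implements the full pipeline: knowledge-graph I/O, state-change
quantification, hypothesis scoring, cross-experiment model assembly, and a
planted-perturbation simulator that stands in for proprietary knowledge bases
and unreleased primary data.

## The knowledge substrate

A `kam` is a signed directed multigraph. Nodes are (entity, aspect) pairs:
the same protein appears separately as `protein_activity`,
`protein_abundance` or `protein_modification`, and its transcript as
`rna_abundance`; `compound` and `process` cover perturbagens and phenotypes.
Keeping activities distinct from abundances matters because causal assertions
in the literature usually constrain activity, while microarrays measure RNA.

Edges carry a sign: non-inverting (+1) or inverting (−1). Contradictory
assertions (same endpoints, opposite signs) are retained as parallel edges —
they are the mechanism behind *ambiguous* downstream polarity, not a data
error. Evidence strings ride along and merge when duplicate assertions
collapse. Self-loops are rejected at load time: a node cannot be its own
cause under the path semantics below.

### Polarity propagation

For a root node assumed *increased*, the polarity transmitted to a
downstream node is the product of edge signs along a causal path. The search
enumerates **directed simple paths of at most `depth` edges** and records,
per reachable node, the set of attainable sign products: `{+1}`, `{−1}`, or
both (ambiguous). Two choices here were genuinely open:

* **Simple paths.** With cycles permitted in the graph, unrestricted paths
  are infinite; forbidding repeated nodes within one path bounds the search
  while preserving every polarity a bounded-length causal chain can carry.
* **Default depth 2.** One step covers direct transcriptional control
  (activity → RNA); two steps cover the common
  activity → activity → RNA chain. Deeper searches dilute predictions
  rapidly (every added step multiplies the reachable set) and are available
  via the `depth` argument, but 2 is the default everywhere.

Polarity is kept as a *set* per node rather than a collapsed "ambiguous"
token so downstream consumers can make their own calls; ambiguity is simply
a set of size two.

## State-change quantification

Measurements are reduced to ternary calls — `increase`, `decrease`,
`no_change` — before any graph work.

**RNA.** Per gene, a treated-vs-control test on the log2 expression matrix:
Welch's *t* by default (the study design is two groups; for two groups the
equal-variance F-test offered as `one_way_anova` is the classical ANOVA
equivalent). P-values are Benjamini–Hochberg adjusted within the experiment.
The default criteria call a change at adjusted p ≤ 0.05 **and** linear fold
change `max(r, 1/r) ≥ 1.3` where `r = 2^(mean_treated − mean_control)`; an
alternative regime (raw p ≤ 0.01, no fold criterion) suits comparisons with
very large change counts where FDR adjustment plus a fold floor would be
needlessly conservative. The 1.3 criterion is interpreted on the linear
scale, the standard reading for microarray fold-change floors.

Numerical choices: genes with identical values in both groups get p = 1 by
convention (no evidence of change); a small ε = 1e−9 is added to the
variance of the mean difference so that exact zero-variance fixtures with
differing means yield p ≈ 0 rather than 0/0. Calling is monotone in both
thresholds by construction.

**Phosphoproteins.** Treated/vehicle ratios are thresholded directly: a 20 %
decrease (ratio ≤ 0.80) calls `decrease`, a 50 % increase (ratio ≥ 1.50)
calls `increase`. The asymmetry is deliberate — these cutoffs are empirical
operating points for ratio data, not a symmetric confidence band — and the
boundaries are inclusive, the natural reading of "a 20 percent decrease".

**Merging.** RNA and phospho calls live on disjoint aspects and simply
union. If the same node is called in opposite directions (e.g. two
timepoints of the same analyte), the node is dropped with a recorded
conflict: keeping either direction would bias the concordance statistic,
and the contradiction itself is worth surfacing. Pooled-timepoint designs
are handled upstream by listing all timepoint samples as replicates of one
group.

## Hypothesis scoring

For root *A* assumed increased, with measured universe size *N* (every gene
on the array plus every phospho analyte — measured entities that do not map
into the graph still count, since *N* is a property of the experiment, not
of the knowledge base), *M* observed changes, *P* predictions (measured
nodes in the depth-bounded neighborhood), and *Q* nodes both predicted and
observed changed:

* **Richness** is the hypergeometric upper tail
  `Pr[X ≥ Q]` with population *N*, successes *M*, draws *P* — the
  significance of over-representation of observed changes among the
  predictions. Direction plays no role, so ambiguous predictions count in
  *P* and *Q*.
* **Concordance** restricts to unambiguous predictions over changed nodes:
  *K* agree with an increased root, *J* with a decreased root. With
  `H = max(J, K)` and null success probability 0.5, concordance is the
  binomial upper tail `Pr[X ≥ H]` out of `J + K`. The reported root
  direction is the majority side; a tie (J = K) reports `increase` with an
  explicit `tie` flag rather than dropping the hypothesis — the flag
  prevents silent arbitrariness while keeping the hypothesis inspectable.
* Both tails are inclusive (`≥ observed`), and both return 1 on empty
  evidence (Q = 0, or J + K = 0).

A hypothesis is **significant** when both p-values are ≤ 0.05 and
**marginal** when both are ≤ 0.1. These are raw per-hypothesis cutoffs, as
the method defines them; an optional BH-across-hypotheses mode exists
(`adjust_across = "BH"`) but is off by default since the two statistics are
screening scores feeding expert vetting, not terminal inference. Ranking is
deterministic: tier, then concordance, richness, *Q*, root id.

Only one search per root is needed: the decreased-root hypothesis is the
exact mirror (J and K swap; both p-values are invariant).

## Cross-experiment assembly

`common_hypotheses()` intersects per-experiment results: a (root, direction)
survives only if it meets the tier floor in *every* experiment, with a
consistent direction. `change_overlap()` counts shared changed
(entity, direction) pairs — the contrast the method is built on is a small
raw-change overlap against a much larger shared-mechanism coverage.
`coverage()` classifies each changed node against the selected roots:
*explained* iff some selected root unambiguously predicts the observed
direction and none predicts the opposite; *contradicted* for the reverse;
*conflicted* when selected roots disagree — conflicted nodes are never
counted as explained, since "correctly explained" should not depend on which
of two contradictory selected mechanisms one prefers.

`assemble_cnm()` merges the selection into one network (inter-root causal
paths plus each root's paths to the changes it explains) and annotates every
root with the computable vetting criteria: downstream of the designated
perturbation node, causally connected to another selected root, and whether
the root entity is itself an observed state change. The remaining selection
criteria in the original methodology are scientist judgment by design;
`rcanet` deliberately computes flags, not decisions.

## The synthetic benchmark

No public knowledge base or primary dataset accompanies the method, so the
generator is a first-class module. It emulates exactly the statistical
structure the method assumes and nothing more:

* **Topology.** A layered DAG: a top regulator layer wiring into a second
  regulator layer and RNA leaves, the second layer wiring into leaves. A
  layered DAG keeps planted ground-truth polarity well-defined; cyclic
  stress tests of the path search use the separate random-graph helpers in
  the test suite, which carry no direction ground truth.
* **Defaults** (chosen once, as study-realistic operating points): 200
  entities with 120 RNA leaves; regulator out-degree 6; 30 % inverting
  edges (repression is common but minoritary in curated signaling
  networks); 2 % contradictory edge pairs (curation conflicts are real but
  rare); planted linear fold 2.0 over log2-normal replicate noise of
  sd 0.25 with 4 replicates per group — a standardized effect of
  log2(2)/0.25 = 4, comfortably detectable at n = 4, matching a clear
  planted perturbation rather than a borderline one; background change rate
  1 % for off-target drift.
* **Ground truth** (expected leaf directions, conflicted leaves) is computed
  from the generator's own layer wiring by direct edge composition —
  independently of the package's search engine — so the consistency test
  between generator and engine is a genuine two-route check.
* **Expression noise** is log2-additive Gaussian, the simplest model
  consistent with RMA-scale data. The generator does **not** emulate probe
  effects, batch structure, correlated genes, or realistic curated-network
  topology; passing benchmarks demonstrates correct method behavior under
  the method's own assumptions, not performance on real arrays.
* **Multi-experiment fixture.** Common-mechanism regulators (cycled with
  direction-consistent feedback signs so each carries comparable directional
  evidence) drive an exactly shared core of changed (entity, direction)
  pairs — 17 by default, about one third of each experiment's changes —
  while private regulators and background changes draw from per-experiment
  disjoint leaf pools, making the remaining change sets non-overlapping by
  construction. The generator guarantees the core against the default
  calling criteria by re-drawing a core gene's replicate noise (bounded
  retries) when sampling noise would have missed it: the fixture's contract
  is the planted structure, not a particular noise realization. A
  distinguished `CMPD` compound node feeds the common regulators and serves
  as the perturbation for the CNM vetting flags.

A null configuration (no planted roots) is obtained with a zero-row
`planted_roots` data frame; the separate `effect_fold` parameter is kept
strictly > 1 so that "planted but null-sized effect" cannot be configured
ambiguously.

## Problem sizes and runtime

The shipped benchmarks use the default 200-node graphs with 50 independent
seeds for recovery and null calibration, 1000-gene matrices for calling
calibration, exhaustive statistic sweeps to N = 60, and 200 random ≤ 12-node
graphs for the path-search oracle. These sizes give stable rates (binomial
s.e. ≈ 4 % at 50 seeds) while keeping the full suite under a minute on one
core; all of them scale linearly if larger runs are wanted.

## Known limitations

* Aspect vocabulary is fixed to six tokens; namespace/ontology mapping
  (HGNC, BEL) is out of scope, so entity symbols must already agree between
  graph and measurements.
* Edge metadata is sign + citations only; edge types beyond sign
  (transcriptional vs. post-translational) are not modeled.
* The per-gene tests assume independent genes; no gene–gene correlation
  model is applied, which makes the BH false-call guarantees nominal in the
  simulator and approximate on real data.
* Multiple timepoints of one analyte are either pooled upstream or resolved
  by the conflict-dropping merge; no longitudinal model is attempted.
* Coverage fractions are computed over changed-and-measured nodes; mapping
  losses between platform identifiers and graph entities will shrink both
  numerator and denominator on real data.
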