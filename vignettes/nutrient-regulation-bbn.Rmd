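---
title: "Modelling the nutrient-regulation ecosystem service with a discrete Bayesian belief network"
author: "nutribbn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the nutrient-regulation ecosystem service with a discrete Bayesian belief network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutribbn)
```

## The problem

Nutrient regulation is the capacity of ecosystems to retain and recycle
nutrients — here nitrogen — before they leak into ground and surface
waters. Landscape planners want three maps: the *potential* of each grid
cell to supply this service, the *demand* for it (indexed by the local
nitrogen surplus of agricultural nutrient budgets, in kg N/ha), and their
*budget* — whether supply exceeds demand (sustainable) or not.

A common first-pass supply estimate is the ecosystem-service (ES) matrix:
every land-use/land-cover (LULC) class receives an expert score from 0
("no relevant potential") to 5 ("very high potential"). The matrix ignores
site conditions: two arable cells score identically whether they sit on
retentive loam or on leaky sand. `nutribbn` implements the refinement of
that estimate with a discrete Bayesian belief network (BBN) that combines
the matrix score with soil, relief and erosion information, propagates
evidence exactly, and quantifies how strongly each input drives the
result.

## The model

The network has 14 discrete nodes connected by a directed acyclic graph
(`model_nodes()`, `model_arcs()`):

* **landscape type** (Hügelland, Geest, Marsch) is the root describing the
  three natural regions of Schleswig-Holstein: hilly fertile moraines,
  sandy outwash plains, and flat marine marshlands;
* landscape type drives **soil texture** (sand, peat, silt/clay, other)
  and **slope** (three quantile classes, default breaks 0.2039° and
  0.6581°), as well as the LULC-derived **preliminary potential**
  (P_no … P_5) and the **demand** (nitrogen-surplus classes ≤ 40 /
  41–60 / > 60 kg N/ha);
* soil texture drives **field capacity** (< 200 / 200–300 / > 300 mm),
  **natural nutrient availability** (< 300 / 300–600 / > 600 kmol_c/ha),
  **nitrate leaching potential** and **wind erosion**; slope drives
  **water erosion**; wind and water erosion combine into an overall
  **erosion** class;
* field capacity, nutrient availability, leaching, erosion and the
  preliminary potential jointly determine the modelled
  **nutrient-regulation potential** (P_no … P_5), which is
  **reclassified** to low/medium/high and balanced against the demand in
  the **budget** node (sustainable/unsustainable).

Given evidence $B$ (observed states of some nodes), the posterior of any
node $A$ follows Bayes' rule,
$\Pr(A \mid B) = \Pr(B \mid A)\,\Pr(A)/\Pr(B)$, computed exactly from the
factored joint $\Pr(X_1,\dots,X_{14}) = \prod_i \Pr(X_i \mid \mathrm{pa}(X_i))$.

The published account of the model shows the graph only as a figure, so
the exact arc set cannot be read mechanically; the default DAG above is a
reconstruction from the described dependencies (landscape strongly driving
soil texture and slope, weakly driving the preliminary potential; demand
responding to landscape evidence; the target being driven by the site
variables and the preliminary potential). `build_network()` accepts any
acyclic replacement, so the arc set is configuration, not dogma.

## Discretization

`default_discretization()` carries the published class boundaries. Two
closure conventions are used so that every boundary value belongs to
exactly one class:

* *middle-closed* ("< 200 / 200–300 / > 300"): the middle class contains
  both breakpoints — used for field capacity (mm) and natural nutrient
  availability (kmol_c/ha);
* *right-closed* ("≤ 40 / 41–60 / > 60"): each class contains its upper
  breakpoint — used for nitrogen surplus (kg N/ha, negative surpluses are
  legal and map to demand "low") and slope (degrees).

Slope classes come from a quantile classification; `quantile_breaks()`
implements the deterministic rule that the $k$-th break is the
$\lceil kn/3 \rceil$-th order statistic, and the shipped default breaks
(0.2039°, 0.6581°) reproduce the published class bounds. The ES matrix is
deliberately **not** shipped with real per-class scores — those belong to a
separate publication — and must be supplied via configuration
(`es_matrix()`); the synthetic generator carries a toy table for its six
synthetic LULC codes.

## Learned and expert CPTs

Ten of the fourteen nodes are backed by grid data; their conditional
probability tables (CPTs) are estimated by maximum likelihood with an
optional pseudocount (`learn_cpts()`):

$$\hat P(s \mid p) = \frac{n(s,p) + \alpha}{n(p) + \alpha\,|S|}.$$

The pipeline default is $\alpha = 1$: it guards the strata that never
occur in a study area (the Marsch is absent from the local-scale region,
so every Marsch-conditioned column would otherwise be undefined).
$\alpha = 0$ gives raw relative frequencies and is used in the parameter
recovery tests, where an unobserved parent combination is an error rather
than a silently uniform column. Missing values are handled per node by
complete-case deletion (the processed input tables this design targets are
complete); EM-style latent-variable learning is out of scope.

Four nodes — erosion, the modelled potential, the reclassified potential
and the budget — have no direct data column and carry expert-style CPTs
generated by documented heuristics (`default_expert_cpt()`):

* **erosion** takes the ordinal maximum of wind and water erosion
  (no/low → low, medium → medium, high → high) with mass 0.7 on that class
  and 0.15 on each neighbour (clipped at the ends and renormalized);
* **nutrient-regulation potential** shifts the preliminary potential by
  −1/0/+1 according to a site-favourability score — the sum of the ordinal
  ranks (1–3) of field capacity and nutrient availability minus those of
  nitrate leaching and erosion, with default shift thresholds at ±2 — and
  places mass 0.5 on the shifted state and 0.25 on each neighbour. The
  conditional therefore peaks at (a shift of) the former matrix state with
  less-than-certain mass, producing exactly the broadening of the
  potential distribution that motivates the approach, and the expected
  ordinal potential is provably non-decreasing in the favourability score;
* **reclassified potential** and **budget** are deterministic point-mass
  encodings of `reclassify_potential()` (default: P_no/P_1 → low,
  P_2/P_3 → medium, P_4/P_5 → high) and `budget_state()` (sustainable iff
  potential rank exceeds demand rank).

Three of these choices are genuinely open in the source material and are
therefore explicit configuration: which four nodes are expert-specified
(the published figure encodes this only in colour), the exact 0–5 →
low/medium/high reclassification split, and the budget tie rule (the
higher/lower dichotomy leaves equality undefined; the default treats a
balanced budget as sustainable, the conservative alternative is one
switch away).

## Exact inference

Posteriors are computed by variable elimination over the CPT factors
(`infer_posterior()`): evidence slices the factors, the remaining
variables are summed out along a min-fill elimination order, and the
result is normalized. The network is small (14 nodes, at most 6 states),
so exact inference is cheap and sampling would add noise for no benefit.
Numerical choices:

* products are taken in linear space with per-elimination-step
  renormalization; the extracted constants are accumulated in log space,
  which bounds underflow for the ≤ 14-factor products that occur here and
  lets `evidence_probability()` return exact evidence masses;
* correctness does not depend on the elimination order (the test suite
  checks two opposite orders to 1e-10, and all posteriors against
  full-joint enumeration);
* evidence with probability zero raises an explicit "impossible evidence"
  error rather than returning NaNs;
* `map_state()` breaks posterior ties by the declared state order (first
  state wins), which keeps per-cell classification maps deterministic.

## Model interrogation

**Arc strength.** Published figures display arc influence by line width
without defining the measure; `arc_strength()` realizes it as the mutual
information $I(\text{parent}; \text{child})$ in bits under the network's
joint — symmetric, non-negative, zero exactly at independence, and
verifiable against brute-force enumeration.

**Sensitivity analysis.** `sensitivity_analysis()` differentiates each
target-state posterior with respect to every CPT entry under proportional
covariation (the remaining entries of a perturbed column are rescaled to
preserve normalization — the standard convention in BN sensitivity
analysis). Derivatives are central finite differences with step
$h = 10^{-4}$; because posteriors are linear-fractional in a single
parameter, the finite-difference error is far below the reporting
precision. Parameters of nodes d-separated from the target given the
evidence are set to exactly zero via an auxiliary-parent d-separation test
on the moralized ancestral graph, rather than relying on a numerical
difference of two equal quantities. Per-node aggregates (maximum absolute
derivative) give the influence ranking.

**Cross-validation.** `kfold_cv()` shuffles the records with a fixed seed,
splits them into $k$ near-equal folds, relearns the data-backed CPTs on
$k-1$ folds and predicts the held-out node for the remaining fold by its
MAP state given all other observed columns as evidence (the Markov blanket
would suffice; full evidence is equivalent and simpler). It reports
per-fold accuracy and log-loss and their averages, and is reproducible:
same seed, same folds, same scores.

## The synthetic landscape generator

The original grids (≈ 200 m spacing; > 300,000 cells at the regional
scale, ≈ 1,500 locally) are GIS extractions that cannot be redistributed
here, so `generate_grid()` produces synthetic grids with the statistical
structure the analysis assumes: ancestral sampling through generating
conditional tables (texture, slope class, LULC and surplus class given
landscape; site variables given texture; water erosion given slope),
continuous values drawn uniformly within per-class emission ranges that
nest inside the discretization intervals — so discretizing a generated
record returns exactly the sampled classes — and cosmetic row-major
coordinates at 200 m spacing.

`default_generator_config()` encodes the documented qualitative structure:
Geest cells are predominantly sandy with low field capacity and nutrient
availability, high leaching and wind-erosion risk, and above-average
demand; the Marsch is flat and silt/clay-dominated; the Hügelland is hilly
(driving water erosion). The `"bornhoeved"` preset removes the Marsch and
shifts the surplus distribution toward medium/high, mirroring the
local-scale pattern. The numerical values (landscape proportions
0.40/0.45/0.15 regionally, 0.55/0.45/0 locally, and the conditional
tables) are package fixtures chosen once as realistic for this kind of
landscape — they are **not** calibrated to any published map, so passing
tests demonstrate correctness of the machinery and of qualitative
orderings, not numerical agreement with the original study, whose headline
percentages depend on unpublished expert CPTs and the original spatial
data. Uniform within-class emissions are sufficient because every
downstream computation operates on the discretized classes; the generator
also models no spatial autocorrelation, as the network treats cells as
exchangeable rows.

## A worked run

```{r example, eval = FALSE}
cfg <- default_generator_config("schleswig-holstein", n = 5000, seed = 1)
grid <- generate_grid(cfg)
states <- discretize_records(grid, matrix = cfg$matrix)
net <- learn_cpts(build_network(), states, nodes = observed_nodes(), alpha = 1)
infer_posterior(net, c("soil_texture", "budget"),
                evidence = c(landscape_type = "Geest"))
sensitivity_analysis(net, "nutrient_regulation_potential",
                     nodes = observed_nodes())$node_aggregate
kfold_cv(build_network(), states, k = 5, node = "soil_texture", seed = 1)
```

`run_pipeline()` executes the same stages end to end from one YAML/JSON
configuration and writes the learned network, scenario posteriors, arc
strengths, per-cell MAP classifications, sensitivity and cross-validation
reports, plus a manifest (configuration hash and seed) that makes every
run reproducible bit for bit.

## Problem sizes and defaults

The package's own test and reporting runs use 5,000-cell grids for
scenario and sensitivity work, 2,000 cells for cross-validation and
50,000 cells for parameter-recovery checks — sizes at which every learned
CPT cell that matters has hundreds of supporting observations while a full
run stays interactive. The pipeline default (`default_run_config()`) is
5,000 cells, $\alpha = 1$, $k = 5$ folds, the three landscape-type
scenarios, and sensitivity over the ten data-backed nodes.

## Limitations

* The model treats one nutrient (nitrogen); other nutrients would need a
  different structure and data.
* The nitrogen surplus is an input (taken from prior nutrient-budget
  work), not computed from fertilizer, deposition and yield terms.
* Real ES-matrix scores, the original expert CPTs and the GIS extractions
  are not included; reproducing the published posterior percentages is
  therefore out of scope by construction.
* Only complete discrete evidence is supported — no soft/virtual evidence,
  no continuous nodes, no structure learning.
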