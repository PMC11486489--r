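---
title: "Predicting trophic dependencies with constraint-based community succession"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting trophic dependencies with constraint-based community succession}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(troponet)
```

## The problem

Soil bacteria rarely live off a single external carbon source. In the
rhizosphere, plant roots secrete a characteristic cocktail of exudates —
sugars, organic acids, amino acids, phenolics — that feed a first tier of
microbes; the by-products those microbes release then feed a second tier,
and so on. The structure of this hierarchy matters: which organisms sit at
which trophic level, and which compounds mediate the hand-offs, determines
community-level functions such as suppression of soil-borne disease.

`troponet` predicts these hierarchical trophic dependencies from
genome-scale metabolic models (GSMMs). Each organism is a stoichiometric
model with a biomass objective; the community is simulated by letting every
organism grow in a *shared, growing* environment and tracking which secreted
compounds unlock the growth of which other organisms. The result is a
directed bipartite metabolite-exchange network that can be untangled into
small path motifs and tested for association with sample-level labels
(e.g. healthy- vs sick-soil association from an upstream
differential-abundance analysis).

## The model and its assumptions

Each organism is analysed with standard constraint-based machinery:

* **FBA** (`solve_fba`) maximizes the biomass flux $v_{bio}$ subject to
  steady-state mass balance $S\,v = 0$ and flux bounds
  $lb \le v \le ub$ (mmol/gDW/h). The biomass flux is the growth rate in
  $h^{-1}$.
* **FVA** (`run_fva`) computes, per exchange reaction, the flux range
  $[\min v_j, \max v_j]$ subject to $v_{bio} \ge f \cdot v_{bio}^\*$. The
  community simulator uses $f = 0.9$: holding the objective at 90%
  optimality deliberately admits the *less restricted* secretion profile,
  so an organism's secretion set reflects everything it could release while
  still growing well, not a single arbitrary optimal vertex.
* A medium (`medium`, `apply_medium`) is a set of extracellular compounds
  with uptake bounds. Applying a medium opens the uptake (lower) bound of
  matching exchange reactions and closes all others; secretion bounds are
  never touched.

The **community succession simulation** (`run_mcsm`) then iterates:

1. any injection scheduled for this iteration is added to the medium;
2. an uptake/secretion profile (`exchange_profile`) is computed for
   *every* organism on the cumulative medium — organisms that already grew
   are re-simulated, because an enriched medium can extend the secretion
   repertoire of early growers;
3. every compound secreted by a growing organism and not yet present enters
   the medium at the saturating 1000 mmol/gDW/h bound — it is the
   *presence* of a compound in the environment that carries the trophic
   effect, not its predicted quantity;
4. the run stops at the trophic fixed point: an iteration with no new
   grower, no new compound and no pending injection. Because growers and
   compounds only accumulate, the run is guaranteed to terminate.

Key simplifications, inherited from the modelling tradition this package
belongs to: each organism is optimized individually (there is no community
objective function); bounds are per-organism, so organisms do not compete
for finite resource pools; there are no abundances, kinetics, dilution or
spatial structure. The output is a map of *potential* exchanges, not a
dynamical prediction.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `fraction` | 0.9 | — | FVA fraction of optimum for exchange profiles |
| `secretion_bound` | 1000 | mmol/gDW/h | bound given to newly secreted / medium compounds |
| growth threshold | 1e-6 | 1/h | an organism "grows" when FBA exceeds this |
| flux threshold | 1e-6 | mmol/gDW/h | an exchange is "active" when \|FVA endpoint\| exceeds this |
| `growth_target` | 0.1 | 1/h | minimum growth the minimal medium must sustain |

The global bound of 1000 mmol/gDW/h also caps non-finite reaction bounds at
load time. The two 1e-6 thresholds are the package's own numerical choice:
the internal solver reproduces objective values far more precisely than
this, so the thresholds only guard against round-off, not solver noise.

## Media, compound classes and the rhizosphere environment

`build_rich_medium` offers every exchangeable compound at the global bound;
`compute_minimal_medium` finds the smallest compound subset sustaining
growth at `growth_target`. Minimality is found by exact enumeration over
candidate subsets of increasing cardinality, scanned in lexicographic
compound order — this makes the result deterministic and resolves ties
toward the lexicographically first subset. The combinatorial search is
exact for the candidate-set sizes the package targets (toy organisms with a
handful of exchanges); for larger sets a greedy removal pass (in
lexicographic order) is used instead and flagged `approximate`.

Compounds are classified by `classify_compound`: *organic* means at least
one carbon atom and not on the inorganic-carbon exclusion list (CO2, CO,
bicarbonate, carbonate, cyanide family); *organic-P* additionally requires
phosphorus. The exclusion list exists because "contains carbon" alone would
misclassify CO2 as organic; it is configurable. Compounds with no formula
are classified inorganic with a warning — the conservative choice, since it
keeps an organic-only network claim true at the price of possibly dropping
a node.

The bundled rhizosphere environment unions 33 apple-root exudates (the sole
organic carbon sources, from published metabolomics of apple rootstock
exudation) with a 60-compound inorganic backbone, giving 93 compounds in
total. The exudate table is genuine; the inorganic list is a synthetic
stand-in for a study-specific file and is labelled as such
(`synthetic_inorganic_medium.tsv`). `build_rhizosphere_environment`
re-checks the contract at assembly time: the two lists must be disjoint,
every exudate must classify organic, and no organic compound may hide in
the inorganic list.

## From succession to network to motifs

`build_network` pools each grower's uptake and secretion sets by union over
all iterations and emits a strictly bipartite directed graph: uptake edges
point metabolite → organism, secretion edges organism → metabolite. Only
organic compounds become metabolite nodes (by default); subtypes record
provenance (exudate / secreted / injected). Pooling across iterations is a
deliberate choice — restricting uptake edges to the iteration of first
growth would hide exchanges that only become possible in later, richer
media.

`enumerate_motifs` untangles the network into paths from an exudate to a
*terminal* metabolite (one no organism consumes):

* **PM** (plant–microbe): exudate → microbe → metabolite (2 edges);
* **PMM** (plant–microbe–microbe): exudate → microbe → intermediate
  metabolite → microbe → metabolite (4 edges).

The default semantics enumerate *all shortest paths* per
(exudate, terminal) pair, so a pair contributes PMM motifs only when no
2-edge path connects it. This is the stricter reading of "unique" PMM
motifs; because the phrasing is genuinely open, an `exhaustive` mode (all
simple 2- and 4-edge paths regardless of shortestness) is available for
sensitivity analysis. Paths are unique node sequences in both modes.

## Label association

Three statistical views connect motifs to sample-level H/S/NA labels:

* `position_statistics` — per-organism counts at PMM positions one
  (primary exudate consumer) and two (secondary consumer), with a Pearson
  correlation across organisms (p from the t distribution, n−2 df). A
  negative correlation indicates trophic-level specialisation.
* `classify_and_count` — one-way ANOVA over per-organism motif counts
  grouped by label, followed by Tukey's HSD. The count universe is every
  organism appearing at either position, zero-filled, so a class is not
  silently dropped when its members initiate nothing.
* `metabolite_enrichment` — for each compound at the consumed (exudate) or
  secreted (end-metabolite) position of PM motifs, a one-sided upper-tail
  hypergeometric test of over-representation in H- (or S-) labeled motifs
  against the class+NA reference population, with Benjamini–Hochberg
  adjustment *within each (class, role) family* and significance called at
  q ≤ 0.05. The NA-labeled motifs are the reference by design (they are the
  "no signal" background); `reference = "all"` switches the population to
  all motifs for users who prefer the pooled convention. Only PM motifs are
  tested: in a PMM path the end-product is separated from the exudate by an
  intermediate organism, so exudate→product attribution is confounded.

## The synthetic community generators

Real GSMM collections are hundreds of organisms with thousands of
reactions; the package instead ships generators that plant *known* trophic
structure so every pipeline stage is testable end to end:

* `generate_chain_community(depth)` — organism $M_i$ converts $S_{i-1}$ to
  $S_i$ at 2:1 biomass stoichiometry; the medium carries only $S_0$. Ground
  truth: $M_i$ first grows at iteration $i$; the run fixes after
  $depth + 1$ iterations.
* `generate_cellulose_fixture()` — hydrolyzer, fermenter and oxidizer
  guilds reproduce the canonical cellulose cascade
  (oligosaccharides → glucose → ethanol + acetate → CO2) in exactly three
  productive iterations.
* `generate_random_community(n, k, p, seed)` — a random dependency DAG in
  which each organism feeds on an exudate or, with probability `p`, on a
  previously generated organism's unique secretion. Constructed
  sequentially, so every planted dependency is realizable and recovery can
  be asserted at 100%.

All generated organisms share a common template (import, one biomass
reaction, export, water as the shared inorganic by-product) and pass the
closed-exchange consistency test: with every exchange shut, maximal biomass
is zero. What the generators deliberately do **not** emulate: redundant
internal pathways and alternate optima, realistic exchange repertoires
(hundreds per organism), auxotrophy networks with multiple simultaneous
requirements, and noisy formula annotations. Tests passing on these
fixtures therefore validate the *algorithms* — succession bookkeeping,
network construction, motif semantics, statistics — not the biological
fidelity of any particular GSMM collection.

## Numerical choices

No linear-programming package being available in the deployment
environment, the package ships its own dense two-phase primal simplex
(`R/simplex.R`) behind the flux-analysis functions. Bland's rule (smallest
eligible index enters, smallest basis index leaves on ties) guarantees
termination on the heavily degenerate systems FBA produces (mass-balance
rows with all-zero right-hand sides are the norm). Artificial variables
left basic at zero level after phase 1 are pivoted out or their rows
dropped as redundant before phase 2. Tolerances: 1e-9 on reduced costs and
pivots, 1e-7 on the phase-1 feasibility residual. The solver was validated
against an independent brute-force vertex-enumeration oracle (part of the
test suite) and is deterministic: identical inputs give bit-identical
results, and FBA objective values are reproducible to well below 1e-6.

Other numerical conventions: infeasible FBA reports objective 0 by
convention and a distinct status; FVA refuses to run on a non-growing model
(callers must check growth first); degenerate statistics (fewer than three
organisms, zero-variance counts, empty enrichment families) raise typed
errors rather than returning NaN.

## Problem sizes used in tests and the acceptance script

The shipped test suite and `scripts/acceptance.R` run on chains of depth
1–6, the three-guild cellulose fixture, randomized communities of 3–12
organisms over 2–4 exudates, and randomized bipartite networks of at most
40 nodes (20 seeds). These sizes were chosen so that the independent
oracles — vertex enumeration for LPs, exhaustive subset search for minimal
media, recursive DFS for motifs — remain exact, which is the property that
makes them trustworthy; all checks complete in well under a minute on one
core.

## Known limitations

* Exchange compound identity is exact string match on extracellular ids;
  models drawn from different namespaces must be harmonized upstream.
* The dense simplex targets small models (tens of reactions); genome-scale
  inputs with thousands of reactions would need a sparse industrial LP
  backend behind the same `solve_lp` contract.
* Terminal-metabolite status is relative to the analysed community: a
  compound is "unconsumed" only with respect to the organisms present.
* The hypergeometric test treats motifs as exchangeable observations;
  motifs sharing an organism are not independent, so q-values should be
  read as a ranking device, as is conventional for enrichment screens.
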