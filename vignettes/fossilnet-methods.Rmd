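---
title: "Detecting biotic transitions with temporal multilayer networks"
author: "fossilnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting biotic transitions with temporal multilayer networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fossilnet)
```

## The problem

A regional fossil record is a set of dated sediment samples, each holding the
remains of the species that lived near the site when the sediment formed.
Viewed over thousands of years, such records register *biotic transitions*:
times at which the dominant assemblage of species — and with it the habitat
structure of the landscape — reorganizes, whether through climate change or
through human modification of the landscape. `fossilnet` turns occurrence
tables into temporal multilayer networks, finds assemblages that sequentially
dominate the record by minimizing the map equation, quantifies how sharp each
hand-over is with a bootstrap, reconstructs each assemblage's most probable
thermal range from its species' modern climate tolerances, and identifies the
habitat traits that mark each phase.

## Filtering and time binning

Dating quality varies enormously across sediment samples. Three rules reduce
the record to a temporally reliable core before any network is built:

* samples whose age **mid-point** (middle of the dated interval) is older
  than 16,000 BP are excluded — they would create disconnected nodes and
  sparse layers at the old end of the sequence;
* samples whose **age range** exceeds 2000 years are excluded — large dating
  uncertainty smears temporal structure;
* only occurrences identified to **species level** are kept, for taxonomic
  and ecological precision; samples left empty are dropped.

Survivors are binned by mid-point into ordered 500-year layers (32 layers
over 16,000 years), oldest first. Bins are half-open on the old side, so a
mid-point exactly on an edge belongs to the younger layer and a mid-point of
0 BP is clamped into the youngest layer; any consistent convention works, and
this one keeps exactly `span/bin` layers. Every exclusion is logged with the
rule that caused it.

## Network representations

Each layer is a bipartite graph: sample nodes on one side, taxon (or trait)
nodes on the other. Taxa and traits are *physical nodes* that may occur in
many layers and are split into one *state node* per layer of occurrence;
samples are dated objects and have exactly one state node. The taxonomic
network uses unweighted presence edges; the trait network weights each
sample–trait edge by the fraction of the sample's species carrying that trait
(a sample's trait weights may sum to more than 1 because species carry 1–3
traits each). Interlayer links are never materialized — temporal coupling
enters through the walk model below — which keeps the representation sparse
and the file format simple (`write_multilayer()` uses the plain-text
`*Vertices`/`*Intra` dialect of the multilayer map-equation ecosystem).

## The relaxed random walk and the map equation

A random walker models information flow. Within a layer it steps between
samples and taxa along intralayer edges, proportionally to edge weight, with
probability `1 − r`. With probability `r` it *relaxes*: it picks a layer
uniformly among the layers within `l` steps of the current one in which the
current physical node occurs (current layer included) and takes its next
intralayer step there. For a node present in one reachable layer only, the
relax step degenerates to the ordinary step. We use `r = 0.25` — large
enough to create temporal interdependence, small enough to preserve
intralayer information — and derive `l` from the filters: a sample's
mid-point can sit at most `range/2` from its true age, so
`l = ceiling((range/2)/bin)`, which is 2 at the defaults (2000-year
tolerance, 500-year bins). Stationary visit rates are computed per connected
component (a lazy power iteration, tolerance 1e-12, removes the bipartite
period-2 oscillation); components are weighted by their share of state
nodes.

Partitions are scored with the multilevel map equation: the description
length, in bits per step, of the walk under a hierarchical code — a root
index codebook over top-module entries, per-module index codebooks over
submodule entries plus the module's own exit, and leaf codebooks over member
visits plus exit. Because the flow is stationary, each module's enter rate
equals its exit rate, and all boundary terms use exit flows. Two conventions
matter and are worth stating explicitly:

* **Physical coding.** State nodes of the same physical node assigned to the
  same leaf module share a codeword: their visit rates are pooled before the
  entropy is taken. This is what lets an assemblage that persists across a
  dozen layers code cheaply as one module. Without pooling, chopping the
  record into one module per layer always wins, and no temporal module would
  ever span more than one bin. A corollary: the one-module codelength equals
  the Shannon entropy of the *physical-node* visit rates.
* **No teleportation.** The relaxed walk on a valid bipartite multilayer
  network is ergodic within each connected component, so no teleportation is
  added; components are clustered independently and each forms its own
  top-level branch of the module tree (a codelength-neutral choice, since no
  flow crosses components).

## The search

Optimization is a seeded, restart-based greedy search. Each restart:

1. **Flat partition.** Nodes start as singletons; an active-node queue
   repeatedly moves the node with the best codelength gain into a
   neighboring module (ties to the lowest module index, for determinism),
   modules are aggregated into super-nodes, and the process repeats — the
   classic two-level core loop.
2. **Index levels above.** The module graph (modules as nodes, exit flows as
   node flow, inter-module flows as edges) is clustered with the same
   routine; a new level is kept only if it strictly shortens the code.
   Single-child wrapper modules are contracted away, so the hierarchy can be
   unbalanced.
3. **Submodules below.** Each leaf module is recursively split with the
   hierarchical form of the objective (the enclosing module's exit flow
   enters the subproblem's index term); splits are kept only when they
   shorten the code.

Restarts differ only in the seeded visit order; the best solution is kept
and its codelength is recomputed from scratch as a consistency check. The
search is exact on small problems: on random multilayer networks with up to
8 state nodes it attains the exhaustively enumerated minimum (a property the
test suite checks on 50 such networks). `n_restarts` defaults to 20 in
`mapeq_optimize()` for interactive use; `run_config()` uses 500 for
production runs. Greedy moves need a gain above 1e-10 bits, and the queue is
capped at ~60 evaluations per node, which cuts off cascades of meaningless
micro-moves on highly symmetric networks without affecting real structure.

## Timeline, bootstrap, MCR and traits

`extract_timeline()` orders top modules by the flow-weighted median of their
layers (oldest first, renamed `M1`, `M2`, ...), assigns each layer to the
module with the largest within-layer flow share (ties to the older module),
and reports a transition at each boundary where dominance changes, in years
BP at bin resolution.

`bootstrap_networks()` multiplies every edge weight by an independent draw
from Normal(1, sd²), redrawing non-positive values; sd defaults to 0.1,
which keeps zero more than four standard deviations away. Replicates are
re-clustered with the same settings as the reference. From the replicate
ensemble we compute, per the reference solution: **significant cores** (the
largest subset of a module's nodes whose agreement with the subset's
per-replicate majority module is at least 95%, found by greedily dropping
the least consistent node); **transition labels** (two successive modules
are mutually significant — transition *abrupt* — when their cores co-cluster
in fewer than 5% of replicates; at or above 5% the transition is *gradual*,
boundary inclusive); and **layer robustness** (fraction of replicates whose
restriction to a layer has co-clustered-pair Jaccard similarity above 0.70
with the reference; layers with fewer than two state nodes report 1 with a
warning).

`mcr_reconstruct()` implements the mutual climatic range method on a
(TMin, TMax) lattice: each species' thermal envelope is an axis-aligned
rectangle (tolerated mean temperatures of the coldest and warmest months);
lattice points at whole multiples of the 0.5 °C grid step are scored by the
number of covering species; the maximum-score region is the most probable
thermal range, and the percentage of species attaining it indicates how much
climate variation the module spans. Herbivores are excluded by default
(their ranges may track host plants rather than climate), and a jackknife
(leave-one-species-out) yields robustness bars. Real envelope compilations
use irregular climate-space masks rather than rectangles; the grid engine
accepts per-species boolean masks through the `masks` argument, so
rectangles are a default, not a limitation.

`percent_flow()` standardizes trait visit rates within each (module, layer)
cell to percentages, and `indval()` runs a group-equalized indicator value
analysis on per-layer trait flows: specificity `A` (group mean over the sum
of group means), fidelity `B` (fraction of the group's layers with nonzero
flow), `IndVal = sqrt(A·B)`, and an add-one permutation p-value over
layer-to-group label shuffles (so p is never exactly 0). Layer groups
typically mirror the species-based modules via `layer_groups()`.

## The synthetic generator: what it emulates, and what it does not

`generate_dataset()` plants known structure: `n_regimes` successive faunal
regimes with configurable switch times, species pools (adjacent pools
sharing a configurable fraction of species), per-regime true climates
contained in every member species' envelope, per-regime trait profiles, and
dated samples whose interval is `true age ± age_noise`. Species shared
across a soft boundary are *boundary dwellers*: their sampling weight decays
as `exp(−distance/1000 years)` from the shared boundary, so a soft boundary
blends compositions locally rather than homogenizing whole regimes. Default
sizes mirror a realistic record at desk scale: per-sample richness is
Poisson with mean 15 (of the order of the ~29 occurrences per sample in
large Quaternary compilations), 20 species per regime pool, and a
16,000-year span at 500-year bins. The generator does **not** emulate
taphonomic loss, radiocarbon calibration curves, spatial autocorrelation of
sites, or skewed species-abundance distributions; passing tests on planted
regimes therefore demonstrate correctness of the machinery, not performance
guarantees on any real record.

## Numerical and design notes

* Determinism: every stochastic routine takes a seed and is a pure function
  of its inputs; pipelines rerun byte-identically.
* The relax-limit formula uses half the age range because a mid-point can
  sit at most `range/2` from the true age; with 2000-year tolerance and
  500-year bins this gives `l = 2`, and the floor of 1 (for any positive
  tolerance) is the smallest value that enables interlayer connections.
* Layer indices run oldest (0) to youngest; transition ages are reported at
  bin boundaries (`span − bin × first_younger_layer` BP).
* Degenerate inputs error loudly rather than silently: inverted age
  intervals, unknown taxonomic ranks, species missing from the trait table,
  empty matrices, bipartite violations in network files (reported with line
  numbers), partitions that do not cover the state nodes.
* On hard-boundary synthetic data the abrupt/gradual machinery behaves as
  designed: disjoint regimes never co-cluster and label abrupt. On
  soft-boundary data (50% shared species) the module separation that the
  optimizer finds is still robust to the default bootstrap perturbation —
  inter-module flows shift by roughly 1e-3 bits while separation margins
  stay an order of magnitude larger — so gradual labels do not generically
  arise from pool overlap alone; empirically, gradual transitions reflect
  records whose assemblage boundary sits at a knife-edge of the codelength
  landscape, a property of particular data rather than of overlap per se.
  The bootstrap reports the co-clustering fraction alongside the label, so
  marginal cases are visible regardless of the 5% cut.

## Problem sizes used by the test suite

Unit and acceptance tests run on synthetic data of 40–200 samples, species
pools of 10–20 per regime, and 5–20 optimizer restarts; the exhaustive
map-equation oracle enumerates all set partitions of networks with at most 8
state nodes; bootstrap checks use 20 replicates. These sizes exercise every
code path at interactive speeds; production analyses simply raise
`n_restarts` and the bootstrap count in `run_config()`.

## Limitations

The search is heuristic beyond the enumerable scale, as all map-equation
optimizers are; restarts mitigate but do not eliminate local minima. The
relax model conditions layer choice on node presence and is uniform over
eligible layers — a documented choice among several plausible multilayer
semantics. MCR rectangles approximate real climate-space masks. The IndVal
variant is the group-equalized one; other variants weight unequal group
sizes differently.
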