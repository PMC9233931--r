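# fossilnet

Temporal multilayer network analysis of dated fossil occurrence records.

`fossilnet` detects **biotic transitions** — times at which the taxonomic or
ecological composition of a regional fossil record reorganizes — from tables
of dated sediment samples and the species (or habitat traits) found in them.
It is aimed at palaeoecologists working with Quaternary occurrence databases
(insect, plant or invertebrate records with radiocarbon-scale dating), and at
anyone who wants a self-contained, tested R implementation of map-equation
clustering for temporal multilayer networks.

## The method

Dated samples are filtered (age mid-point ≤ 16,000 BP, age range ≤ 2000
years, species-level identifications only) and binned into ordered 500-year
layers. Two multilayer networks are assembled:

* **taxonomic** — each layer is a bipartite graph of sample nodes and taxon
  nodes joined by unweighted presence edges;
* **trait** — samples connect to habitat-trait nodes with weights equal to
  the fraction of the sample's species bearing each trait.

A taxon or trait occurring in several layers is one *physical node* with one
*state node* per layer; samples are layer-bound and have a single state node.
Interlayer coupling is not drawn as edges: a random walker follows intralayer
edges with probability `1 − r` and *relaxes*, with probability `r = 0.25`, to
a uniformly chosen layer within `l` layers of the current one where the same
physical node occurs (the relax limit `l = ⌈(range/2)/bin⌉ = 2` at the
default filters, so dating uncertainty and temporal reach are matched).

Partitions of the state nodes into (nested) modules are scored with the
multilevel **map equation**,

```
L(M) = q H(Q) + Σ_m p_m H(P_m)
```

the expected per-step description length of the walk under a two-part code:
an index codebook over module entries plus per-module codebooks over member
visits and exits, applied recursively for nested modules. State nodes of the
same physical node share a codeword within a module, so assemblages that
persist across many layers code cheaply. A seeded greedy search (node moves,
module aggregation, index levels above, submodule splits below) minimizes
`L`. Module significance is assessed with bootstrap replicate networks
(edge weights × Normal(1, sd²)): significant cores, abrupt vs gradual
transition labels at the 5% level, and per-layer partition robustness
(Jaccard similarity of co-clustered pairs, threshold 0.70). Modules of the
taxonomic network get a **mutual climatic range** (MCR) palaeotemperature
reconstruction from their species' thermal envelopes (with jackknife), and
trait modules are characterized by percent flow and an **IndVal** indicator
analysis with permutation p-values.

A synthetic fossil-record generator with planted temporal regimes (known
species pools, thermal envelopes, trait profiles and switch times) makes
every stage testable without any external database.

## Worked example

```r
library(fossilnet)

cfg  <- regime_config(3, boundaries = c(10000, 4000), n_species_per_regime = 20)
ds   <- generate_dataset(cfg, n_sites = 25, n_samples = 200, age_noise = 0, seed = 42)
filt <- ingest_filter(ds)
net  <- build_taxonomic_network(filt$occ, filt$samples)
net
#> multilayer network (taxonomic): n = 260 physical nodes (200 samples, 60 taxa),
#>   m = 2967 intralayer links, t = 32 layers

part <- mapeq_optimize(net, r = 0.25, l = compute_relax_limit(2000, 500),
                       n_restarts = 5, seed = 1)
tl   <- extract_timeline(part, net)
tl
#> module timeline (oldest first):
#>   M1: layers 0-11, 84 samples, 20 taxa/traits, flow 0.384
#>   M2: layers 12-23, 67 samples, 20 taxa/traits, flow 0.364
#>   M3: layers 24-31, 49 samples, 20 taxa/traits, flow 0.252
#> transitions:
#>   M1 -> M2 at 10000 BP (layer boundary 12)
#>   M2 -> M3 at 4000 BP (layer boundary 24)

mcr_by_module(part, tl, ds$envelopes)[, c("module", "tmin_lo", "tmin_hi",
                                          "tmax_lo", "tmax_hi", "percent_overlap")]
#>   module tmin_lo tmin_hi tmax_lo tmax_hi percent_overlap
#> 1     M1   -13.5     -11       3     5.0             100
#> 2     M2    -6.0      -4      10    12.0             100
#> 3     M3     1.0       3      17    19.5             100
```

The three top-level modules recover the three planted faunal regimes
exactly: the transitions fall on the planted switch times (10,000 and 4,000
BP), and each module's reconstructed thermal range (`tmin_lo..tmin_hi` is
the tolerated mean temperature of the coldest month, `tmax_*` of the
warmest) brackets that regime's true climate (−12/4, −5/11 and 2/18 °C here).
`percent_overlap` is the share of climate-indicator species whose envelopes
cover the maximum-overlap region of climate space — 100% on clean synthetic
envelopes, lower when a module mixes climates.

`run_pipeline()` chains every stage (filter → networks → clustering →
bootstrap → MCR → trait flows/IndVal) and writes TSV artifacts plus a JSON
manifest; `inst/scripts/run_pipeline.R` is a small command-line wrapper
around it.

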