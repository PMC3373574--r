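# ppialign

Pairwise **local alignment of protein–protein interaction (PPI) networks**:
given two species' weighted interaction networks and a scored, possibly
many-to-many ortholog map, `ppialign` finds *conserved modules* — candidate
protein complexes supported by interactions in both species — together with
the evaluation protocol (complex-catalog recovery, enrichment, topological
significance) and a synthetic paired-network generator for fully offline
benchmarking.

## Method in brief

Inputs are merged into a **union graph** whose composite nodes are ortholog
pairs and whose simple nodes are unmatched proteins; every input edge is
carried over with its species support, and an interaction conserved in both
species is stored once with the **sum** of the two reliabilities. An
**alignment graph** over composite nodes is then scored per edge (a, b)
with a Jaccard-style measure over the pair's *extended local interactome*:

    c_dir = w1(a,b) / (S1(a) + S1(b) − w1(a,b))
    c_ind = P2(a,b) / (S2(a) + S2(b) − P2(a,b))
    score = c_dir + c_ind  ∈ [0, 2]

where `w1` is the direct union-edge score, `P2` the total score of valid
length-2 paths (paths whose two edges are supported by a common species;
cross-species-only paths are spurious and ignored), and `Sk(n)` node *n*'s
total path mass to composite endpoints. Edges of proteins with multiple
ortholog candidates are divided by their within-group rank, then pruned
locally: an edge survives only if it reaches a fraction *t* (default 0.5)
of the best corrected score at **both** endpoints.

Modules are grown seed-and-extend: every connected 4-subgraph is enumerated
exactly once (anchored ESU-style enumeration), scored additively, and
node-disjoint top scorers become seeds. Each seed expands in batches — a
candidate subgraph joins the module when its frontier connects to the
module with more reliable weight than to the rest of the graph
(`W_M > W_N`), and all accepted candidates are added at once. Emitted
modules have ≥ 5 nodes and may overlap.

Evaluation mirrors the standard protocol: per-complex best-match
precision/recall/F1 against a CYC2008/CORUM-style catalog (F1 > 0.3 flags
high quality, complexes < 4 proteins analysed separately via the
small-complex rule), hypergeometric enrichment with Benjamini–Hochberg
correction, and per-module Z-scores of induced connectivity against
degree-preserving (double-edge-swap) random networks with an empirical
p-value `(r + 1) / (R + 1)`.

## Worked example

```r
library(ppialign)

sim <- simulate_paired_networks(sim_config(rng_seed = 7))
res <- align_ppi(sim$net1, sim$net2, sim$hom, verbose = TRUE)
#> union graph: 390 nodes (390 composite), 1066 edges (92 conserved)
#> raw alignment graph: 377 nodes, 3763 edges
#> pruned alignment graph (t=0.5): 344 nodes, 375 edges
#> enumerated 1191 connected 4-subgraphs
#> selected 44 node-disjoint seeds
#> emitted 14 modules of >= 5 nodes

res$modules[[1]]
#> ppi_module M001: 15 ortholog-pair nodes (11+14 proteins), score 12.65

rep <- recovery_report(res$modules, sim$truth)
#> mean best F1 0.752 | matched at F1>0.3 0.90 | mapping accuracy 0.768
```

The log lines are the per-stage shape of the data: the union graph carries
all 390 ortholog-pair nodes and every input edge (92 of them conserved in
both species); ELI scoring connects 377 pairs, and rank correction plus
local pruning cut the 3763 raw edges to 375 reliable ones. Of the planted
10 complexes, 90% of (complex, species) pairs are recovered above
F1 = 0.3 on this seed, and 77% of module nodes map proteins to their true
ortholog (spurious map pairs inside a complex are the main contaminant).

On real data, use the readers and the same pipeline:

```r
net1 <- read_network("yeast.tsv", "Scer")
net2 <- read_network("fly.tsv", "Dmel")
hom  <- read_homology("inparanoid.tsv")
res  <- align_ppi(net1, net2, hom)
write_modules(res$modules, "modules.tsv")

catalog <- read_complexes("cyc2008.tsv")
best_matches(catalog, res$modules, species = 1,
             universe_size = length(net1$nodes))
connectivity_significance(res$modules, net1, net2, R = 1000, rng_seed = 1)
```

A command-line front end with `align`, `evaluate` and `simulate`
subcommands is installed under `inst/scripts/ppialign`.

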