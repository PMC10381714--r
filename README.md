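# localign

Local alignment of cross-species protein–protein interaction (PPI)
networks, with functional validation of the aligned modules.

## The problem

Comparing the interactome of a model organism (e.g. *C. elegans*)
with the human interactome around disease proteins asks a local
question: which small subnetworks are conserved between the two
networks? Local network alignment (LNA) answers it with a many-to-many
mapping: starting from seed pairs of similar proteins (typically
orthologs such as apl-1/APP or ptl-1/MAPT), it extracts groups of
cross-species protein pairs whose interactions agree in both networks.
`localign` implements this workflow end to end, for networks supplied
as plain edge-list or STRING-export TSV files, and validates the
extracted modules functionally with Gene Ontology semantic similarity
against size-matched random alignments.

## The method

**Alignment graph.** Given networks `G1 = (V1, E1)`, `G2 = (V2, E2)`
and a scored seed-pair table, each alignment-graph node is a pair
`(a, b), a ∈ V1, b ∈ V2`; under the default `best_match` strategy each
protein keeps its highest-similarity partner(s), ties included. For
two composite nodes `u = (a1, b1)`, `v = (a2, b2)` let `d1, d2` be the
unweighted shortest-path distances of their proteins within each
network. The edge `u–v` is classified as

| class | condition |
|---|---|
| match | `d1 = 1` and `d2 = 1` |
| mismatch | direct edge in one network, `1 < d ≤ δ` in the other |
| gap | direct edge in one network, `d > δ` (or disconnected) in the other |

and carries one of seven configurable weights depending on its class
and on whether all four proteins share one node color (homogeneous) or
not (heterogeneous). Defaults are the published operating point:
`δ = 2`, weights `1 / 0.9 / 0.5 / 0.4 / 0.2 / 0.1` for
homogeneous/heterogeneous match, mismatch, gap.

**Module mining.** The weighted alignment graph is clustered by a
from-scratch Markov clustering (MCL) implementation: column-stochastic
matrix with per-node self-loops, alternating expansion (matrix power 2)
and inflation (entrywise power 2 with renormalization and pruning)
until convergence; clusters are read off the attractor structure.
Clusters with at least two composite pairs become alignment modules
and project to one protein set per species.

**Functional scoring.** Modules are scored with ontology semantic
similarity: Resnik `IC(MICA)`, Lin `2·IC(MICA)/(IC1+IC2)`, Jiang
`1 − (IC1 + IC2 − 2·IC(MICA))` (clamped to [0, 1] in reports), and
Wang's S-value measure (edge weights 0.8 for `is_a`, 0.6 for
`part_of`). Term pairs aggregate to gene pairs by best-match average
(BMA) and to a module by the mean over all annotated protein pairs of
the pooled two-species set. Information content is computed from a
user-supplied annotation corpus (GAF or two-column TSV) over an OBO
ontology, with annotations propagated to ancestors and natural-log
frequencies.

**Significance.** Each module's score is referenced against
size-matched random alignments: proteins drawn uniformly without
replacement from the pooled node set (9 replicates by default). The
empirical exceedance fraction `#(random ≥ real)/replicates` is the
reported evidence; 0 means the real module beat every random one.

## Worked example

Everything below is generated in code — no downloads. The synthetic
generator plants mirrored conserved modules in two networks at the
scale of the Alzheimer-related *C. elegans* (33 nodes / 82 edges) and
human (41 / 157) input pair, and annotates planted proteins coherently
in a toy ontology (coherence 0.9):

```r
library(localign)
spec <- synthetic_spec(preset = "ad", rng_seed = 1)
fix  <- generate_coherence_fixture(spec)

ag   <- build_alignment_graph(fix$net1, fix$net2, fix$seeds)
#> alignment graph: 22 composite nodes, 89 edges (hom_match=79, ...,
#>                  hom_mismatch=5, ..., hom_gap=5, het_gap=0)
mods <- extract_modules(ag)
score_modules(mods, fix$onto, fix$corpus)
#>   module size resnik_bma   lin  wang
#> 1      1   24      0.817 0.774 0.818
#> 2      2   18      0.899 0.726 0.761

nc <- compare_real_vs_random(mods, fix$net1, fix$net2,
                             fix$onto, fix$corpus, rng_seed = 1)
nc$summary
#>     measure module size real_score exceedance
#>  resnik_bma      1   24      0.817          0
#>  resnik_bma      2   18      0.899          0
#>         lin      1   24      0.774          0
#>         lin      2   18      0.726          0
#>        wang      1   24      0.818          0
#>        wang      2   18      0.761          0

module_recovery(mods, fix$truth)
#> [1] 1.0000000 0.8888889
```

The two extracted modules are the two planted ones (Jaccard 1.0 and
0.89 against ground truth), their pooled protein counts (24, 18) match
the planted sizes, and every module outscores all nine random
alignments under all three measures — the "real beats random"
signature. `plot_null_comparison(nc, "lin")` draws the real-vs-random
dot plot.

Real data enter the same way through files:
`read_network("human.tsv", "string_tsv", min_confidence = 0.7)`,
`read_seed_pairs("orthologs.tsv")`, `load_ontology("go.obo")`,
`read_annotations("goa.gaf", onto)`, then
`pipeline_config(...)` + `run_pipeline(config)`, or the shell wrapper

```sh
Rscript inst/cli/localign.R all --net1 ce.tsv --net2 hs.tsv \
  --seeds orthologs.tsv --obo go.obo --gaf goa.gaf --seed 1 --out results/
```

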