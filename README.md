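# gcppi — ab initio PPI networks from genomic context

`gcppi` predicts protein–protein interaction (PPI) networks for bacterial
and archaeal genomes directly from their protein sequences — no reference
interaction database, no alignments, no structures. It is aimed at
researchers working on newly sequenced or poorly annotated genomes, where
interolog- or annotation-based predictors have nothing to map onto.

## The method

Each protein is summarized by a **60-value propensity descriptor**: for each
of 10 physicochemical scales (basicity, acidity, polarity, non-polarity, two
mass scales, and four AAindex-style indices), the raw sum of per-residue
values over the whole sequence and over its start/middle/end thirds
(4 × 10 = 40 values), plus the counts of the 20 standard amino acids.

Two proteins are *similar* either by

- **Features mode** — at least 25 of the 60 coordinates agree within a
  tolerance of 1 (configurable to 2), or
- **ML mode** — a random forest (500 trees, depth ≤ 30, 10 candidate
  features per split, trained on 3:1 negative:positive pairs encoded as
  element-wise absolute feature differences) classifies the pair as similar;
  pairs already passing the Features threshold are accepted directly.

Similarity across genomes yields, for every protein, a **phylogenetic
profile** — the presence/absence vector of detected homologs across the
input genomes. Interaction evidence is then:

- *conserved phylogenetic profiles*: proteins of a genome whose profiles
  differ in at most `diff_tolerated` positions are linked;
- *conserved gene neighborhoods*: gene `g` is linked to the genes of its
  `w1 = 10`-gene window that have similar counterparts inside the window of
  a similar gene in another genome, provided at least `cw1 = 4` window genes
  are conserved.

A profile group of `x` identical profiles would contribute the complete
graph of `x(x−1)/2` edges (the accounting diagnostic
`f(x) = (x−1)(x−2)/2` is also provided — `f(500) = 124251`). Groups larger
than a trigger (default 100) are instead sparsified by a stochastic
**shuffle–subdivide sampler**: shuffle the members, partition them
round-robin into `⌊0.9·x⌋` sublists, add 2 randomly drawn connector
proteins to every sublist, and keep only within-sublist edges. A
**replicate-stability suite** (weighted global presence mean, pairwise
Jaccard, adapted Fleiss' kappa, Kendall ratio positive, multi-sample KS
distance over top-N central nodes) quantifies how well sampling preserves
hub rankings.

## Worked example

```r
library(gcppi)

# three synthetic genomes, 40 gene families, ~90% within-family identity
sim <- simulate_proteome_set(simulation_config(n_genomes = 3,
                                               genes_per_genome = 40,
                                               family_identity = 0.9,
                                               seed = 7))
run <- infer_ppi_networks(sim$genomes, mode = "features", seed = 3)
summary(run)
#> Interaction networks (mode=features, seed=3)
#>    genome proteins profile_edges neighborhood_edges nodes edges
#>  genome01       40           178                 90    30   233
#>  genome02       40           196                103    32   254
#>  genome03       40           157                 91    31   215

cmap <- compute_centrality(run$networks[["genome01"]], "degree")
head(select_top_n(cmap, 3))
#>   rank      node value
#> 1    1 g01_f0008    21
#> 2    2 g01_f0014    21
#> 3    3 g01_f0016    21
```

Per genome: `proteins` is the proteome size, `profile_edges` /
`neighborhood_edges` the evidence-specific counts before merging, and
`nodes`/`edges` the final deduplicated network (proteins without any edge
are excluded by default, so `nodes < proteins`). `write_run_dot(run, dir)`
exports one DOT file per genome plus a JSON manifest that reproduces the
run exactly. The same pipeline is scriptable from a shell via
`inst/cli/genppi.R` (subcommands `run`, `features`, `train-model`,
`evaluate`, `topn`, `stability`, `compare`, `simulate`).

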