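---
title: "Genomic-context PPI inference: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic-context PPI inference: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcppi)
```

## The model

`gcppi` infers protein–protein interaction networks *ab initio* from
genomic context: the only inputs are one protein multi-FASTA file per
genome, with record order taken as gene order. The method rests on two
classic evolutionary signals:

1. **Phylogenetic profiling.** Proteins that are jointly present or absent
   across genomes tend to take part in the same process. For each protein
   we record, per input genome, whether a *similar* protein exists there
   (the bit for the protein's own genome is fixed to true). Proteins of a
   genome whose profiles agree — exactly, or within a Hamming tolerance —
   are linked.
2. **Conserved gene neighborhoods.** Genes that stay close on the
   chromosome across genomes are likely functionally coupled. A gene is
   linked to the members of its local window that are conserved, as a
   block, around a similar gene in another genome.

Both signals need a similarity notion that works without alignments.
Proteins are described by a 60-value propensity descriptor and compared
either by a counting rule ("Features mode") or by a random-forest
classifier ("ML mode").

### The 60-feature descriptor

For each of the 10 scales of the propensity table (in table row order) we
compute the *raw sum* of per-residue values over the whole sequence and
over its start, middle and end regions — 40 values — followed by the counts
of the 20 standard amino acids in alphabetical order. Regions are split as
`floor(n/3)` residues for each flank with the remainder assigned to the
middle; this makes `start + middle + end` reconstruct the sequence exactly
and gives the additive invariant `whole = start + middle + end` per scale.

Two deliberate choices:

- **Raw sums, not means.** The Features-mode rule counts coordinates that
  agree within ±1 unit; length-normalized sums would compress most
  coordinates into a narrow band and destroy the rule's discriminative
  power. Raw sums keep count-like coordinates on an integer-ish scale where
  a one-unit tolerance is meaningful.
- **Non-standard residues (B, J, O, U, X, Z)** are accepted but contribute
  zero to every scale sum and are excluded from the 20 counts, with a
  warning. The descriptor is deliberately restricted to the 20 standard
  residues so that the count block has a fixed, model-compatible layout.

The bundled propensity table (`inst/extdata/propensity.tsv`) provides
indicator scales (BASIC, ACID, POLAR, NONPOLAR), residue masses (MASS
monoisotopic, MASSMR average) and four AAindex-style numeric scales
(PARJ860101, JOND750101, EISD840101, JURD980101). These values are
*configuration*, not ground truth: any table in the same dialect can be
swapped in, and the feature layout is versioned (`gcppi-60-v1`) so that a
serialized classifier refuses to run against a different layout.

### Similarity decisions

**Features mode** declares two proteins similar when at least
`min_matches = 25` of the 60 coordinates differ by at most
`tolerance = 1` unit (2 is a supported looser setting). The rule is
symmetric and monotone: loosening the tolerance or lowering the match
count can only add similar pairs.

**ML mode** uses a random forest over a symmetric pair encoding — the
element-wise absolute difference of the two descriptors. We chose this
encoding because it is symmetric by construction, keeps the attribute count
at 60 (matching univariate-split trees well), and aligns with the
per-coordinate comparison of Features mode; a concatenation encoding is
available as a non-default option but is not symmetric. The default
hyperparameters are 500 trees, maximum depth 30, 10 candidate features per
split, bagging fraction 1.0 with replacement, and minimum leaf size 1. The
depth default is kept at the conventional value 30 even though the
"half the features plus one" heuristic would give 31 for 60 features; the
difference is immaterial for forests of this size and the round value is
retained as the fixed default. Training tables put all negatives before all
positives and downsample negatives (seeded, without replacement) to a 3:1
negative:positive ratio, the ratio at which sensitivity and specificity
balance best in our synthetic-recovery tests. Prediction thresholds the
positive-class probability at 0.5 (majority vote).

Operationally, ML mode is a *union*: a pair that already passes the
Features threshold is accepted without consulting the forest, and the
forest decides the remaining pairs. This guarantees ML-mode similarity is a
superset of Features-mode similarity.

### Profile and neighborhood evidence

Profile linking uses a single uniform rule: proteins of the target genome
at profile Hamming distance ≤ `diff_tolerated` (default 0) are linked.
Proteins present only in their own genome are uninformative and generate
no edges. Identical-profile groups of size `x ≤ ris_trigger` contribute
their complete graph (`x(x−1)/2` edges); the diagnostic
`profile_edge_estimate(x) = (x−1)(x−2)/2` is reported for accounting and
is a strict underestimate of the complete graph by `x−1` edges — it is
never used as the generative rule.

The neighborhood rule is a reconstruction from its parameter semantics,
isolated behind `neighborhood_interactions()` so it can be swapped without
touching the rest of the pipeline: for gene `g` with window `W` of
`w1 = 10` consecutive genes centered on it (truncated at contig ends, no
circular wraparound), if another genome holds a gene similar to `g` whose
own window contains similar counterparts for at least `cw1 = 4` distinct
genes of `W`, then `g` is linked to each of those conserved partners within
its own genome. `fixed` expansion keeps the window at `w1`; `dynamic`
expansion starts at 3 genes and grows by one while the quota keeps being
met, up to `w1`.

Edges from both evidence channels are merged per genome into an
undirected, deduplicated network with unioned evidence labels. Isolated
proteins are excluded from the node set by default (so reported node
counts are below proteome sizes); `include_isolated = TRUE` restores them.

### The interaction sampler

Large conserved profiles are the computational hazard of sensitive
similarity: a group of 500 identical profiles implies ~125k edges on its
own. Groups with *more than* `trigger = 100` members are therefore
sparsified:

1. shuffle the member list (seeded);
2. partition it round-robin into `k = max(2, floor(0.9 · x))` disjoint
   sublists;
3. draw 2 connector members uniformly and append them to every sublist;
4. emit the union of within-sublist complete graphs, deduplicated.

Two design notes. First, the sublist *count* (not size) is set to 90% of
the group size: setting sublist sizes to about half the group would make
every pair co-occur in some sublist with high probability and regenerate
nearly the complete graph, defeating the reduction; the count-based rule
yields sublists of 1–2 members plus connectors and an order-of-magnitude
edge reduction. Both the fraction and the connector count are configurable.
Second, the partition is round-robin after the shuffle rather than fully
random, bounding the worst-case sublist size; the shuffle already
randomizes membership. Outputs are sets: no duplicates, no self-loops,
always a subset of the complete pair set, and identical under the same
seed. Because members are exchangeable, expected degree is uniform within
a group — the tests verify this with a Kruskal–Wallis check across seeds —
which is why hub *rankings* survive sampling even though individual edges
are stochastic.

### Stability evaluation

To quantify what sampling does to downstream topology we compare replicate
networks generated under different seeds. For a chosen centrality (degree;
betweenness, unnormalized since rankings are scale-invariant; or bridging
centrality `betweenness(v) · (1/deg(v)) / Σ_u 1/deg(u)` over neighbors
`u`), the top-N nodes of each replicate are selected with deterministic
id-based tie-breaking, and five statistics are computed:

- **MGP (weighted global presence mean)**: with `f_i` the fraction of
  replicates containing node `i`, `MGP = 100 · Σf_i² / Σf_i`. The
  functional form is our reconstruction of a frequency-weighted presence
  mean: it is 100 exactly iff every appearing node appears in all
  replicates, and sparsely appearing nodes are down-weighted by their own
  frequency, mitigating sparse-node bias.
- **Pairwise Jaccard** of top-N sets (mean over replicate pairs).
- **Fleiss' kappa (adapted)** with items = the union of all replicate
  network nodes (not just top-N unions, so non-selection is informative;
  configurable), raters = replicates, two categories. Degenerate
  expected-agreement-1 cases return 1 with a flag.
- **Kendall ratio positive**: per replicate pair, the proportion of
  concordantly ordered node pairs among nodes shared by both rankings,
  ties dropped from the denominator; mean over pairs.
- **Multi-sample KS**: the maximum (conservative; mean available) over
  replicate pairs of the two-sample sup-ECDF distance of the centrality
  values.

A fully deterministic pipeline (Features mode with no group above the
trigger) reaches the exact limit MGP = 100, Jaccard = 1, kappa = 1,
KS = 0 — the suite's calibration point. On stochastic sampled replicates
all statistics improve as top-N grows: small top-N slots are dominated by
connector proteins whose identity is redrawn every replicate, while larger
top-N sets are dominated by the stable core of the network.

`run_stability_experiment()` orchestrates the full grid — operational mode
× input-file count × top-N × metric; the full-scale grid of 2 modes ×
5 file counts × 6 top-N values × 3 metrics gives 180 configurations at 50
replicates each, and is available behind flags. The test suite exercises
the identical orchestrator at reduced scale (single-configuration grids,
3 replicates) to keep runtimes in seconds.

### Network comparison arithmetic

`count_intersect()` reports, for a query network against a reference edge
list: the query's unique undirected pairs; the intersection counted at the
reference's *record* level in its native orientation convention; their
ratio; and the intersection as a proportion of the reference's unique
pairs. The record-level convention exists to reproduce the arithmetic of
references that list both orientations of every pair (self-comparison then
gives ratio 0.5 and proportion 2.0); the normalized both-undirected
variant, which we recommend reading instead (self-comparison gives 1
and 1), is always reported alongside.

## The synthetic-data generator

`simulate_proteome_set()` generates multi-genome proteome sets with full
ground truth: one ancestral protein per family drawn from a residue
composition model (uniform by default; lengths uniform on 120–360
residues), orthologs derived by seeded point substitution, gene order
conserved up to seeded adjacent swaps, and presence/absence following a
per-family genome pattern that directly shapes the true phylogenetic
profiles — including groups larger than the sampling trigger when desired.

Substitutions always replace a residue with a *different* one (drawn from
the renormalized composition), so identity to the ancestor is exactly the
fraction of unchanged sites; each ortholog diverges at rate
`1 − sqrt(family_identity)` so that ortholog *pairs* hit the configured
expected identity up to the small probability that two sites mutate to the
same residue. `simulate_pair_dataset()` labels within-family pairs positive
when their true identity exceeds the 65% labeling threshold and draws
cross-family negatives at any requested ratio.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: no indels (so "identity" needs no alignment),
no realistic substitution matrices or rate heterogeneity, no paralogy or
gene fusion, no operon structure beyond order conservation, and no
composition biases between genomes. It validates the machinery — layout
arithmetic, profile/neighborhood logic, sampler behavior, recovery of a
planted similarity structure — not biological accuracy on real proteomes.

## Numerical and degenerate-input choices

- Region boundaries: `floor(n/3)` flanks, remainder to the middle;
  sequences of length < 3 get empty flanks.
- Feature additivity is exact up to floating-point addition; the invariant
  is tested at 1e-9.
- Ranking ties are broken by node id ascending, everywhere, so replicate
  comparisons are deterministic.
- Degree-0 nodes get bridging centrality 0 (their coefficient is
  undefined otherwise).
- Metrics with zero denominators (sensitivity with no positives, Jaccard
  of two empty sets, Fleiss with expected agreement 1, Kendall pairs with
  fewer than two shared nodes) return flagged values rather than NaNs, and
  error only when *nothing* is computable.
- All randomness (sampler, negative downsampling, simulation, forest
  training) flows through explicit seeds; per-stage seeds are derived from
  the master seed by a fixed integer recurrence recorded in the run
  manifest, so a manifest suffices to reproduce a run bit-identically.
  Parallel execution is not used: determinism is the contract, and the
  pipeline is a pure function of (inputs, configuration, seed).

## Problem sizes used in the tests

The suite validates at deliberately small scale chosen for seconds-level
runtimes: proteomes of 10–60 proteins across 2–4 genomes, sampler groups
of 100–250 members, 20 stochastic replicates for trend checks, 40–80 seeds
for degree-homogeneity checks, and forests trained on a few hundred pairs.
All full-scale settings (50 replicates, 180-configuration grid, arbitrary
genome counts) remain available through the same interfaces.

## Known limitations

- The neighborhood rule is a reconstruction from parameter semantics (see
  above); other block-conservation conventions exist and the operation is
  interface-isolated for that reason.
- The MGP functional form is likewise a reconstruction satisfying the
  metric's stated properties.
- Features-mode matching with ±1-unit tolerance is sensitive to the
  propensity table's units; tables with large dynamic ranges effectively
  shift discrimination onto the count features.
- Identity labeling for real data must be supplied externally (the package
  computes true identities only for its own simulations); no alignment
  engine is included.
- Edge confidence scores are not computed; evidence labels (profile,
  neighborhood) are the only per-edge annotation.
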