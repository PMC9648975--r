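---
title: "Methods: hierarchical k-mer species assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical k-mer species assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kmerassign)
```

This vignette documents the model behind `kmerassign`, its tunable
parameters, the synthetic data used to test it, and the numerical and
design choices made where the method leaves room for them.

## The problem

Multilocus amplicon panels sequence a few dozen short nuclear targets
(~160 bp) per specimen. Per target, a diploid specimen contributes one
haplotype (homozygous), two (heterozygous), or occasionally more
(contamination, PCR/sequencing artefacts, or genomic duplication). The task
is to assign each specimen to a species — or, when the data cannot support a
species-level call, to the most precise taxonomic group it does support —
against a labelled reference database, and to be explicit about uncertainty
throughout. Species complexes make this genuinely hierarchical: their
members share so much variation that no genus-wide rule separates them, so
species-level resolution inside a complex needs a second, specifically
trained stage.

## Stage 1: k-mer distances and nearest-neighbour assignment

**Distance.** A haplotype is summarised by its table of overlapping k-mer
counts over all 4^k possible k-mers (lexicographic order, A < C < G < T).
The distance between tables q1, q2 is `sum(|q1 - q2|) / sum(q1 + q2)`: the
proportion of non-matching k-mers, in [0, 1]. Using counts (not
presence/absence) and normalising by total count removes the length bias
that would otherwise favour short sequences. Substitutions, indels and
small structural variants all move this distance smoothly, which is the
point of avoiding alignment. Between samples, the distance is the mean over
shared targets of the mean distance over all haplotype pairs at that target
(denominator |Q1||Q2|), so zygosity is averaged rather than ignored.

**Choice of k.** k trades error tolerance against within-sequence k-mer
collisions. Treating the 153 8-mers of a 160 bp target as uniform draws
from the 65,536 possibilities, all are distinct with probability ~84%
(`prob_all_kmers_distinct(160, 8)`), while 4-mers in a 149 bp sequence are
all distinct with probability < 1e-22: k = 8 keeps individual targets
mostly collision-free while tolerating divergence. The default is k = 8
everywhere; the code accepts 2 ≤ k ≤ 12 (dense 4^k tables are stored
sparsely, so memory is not the constraint — discrimination is).

**Species-groups.** The reference database is partitioned at thresholds
0.1 (fine), 0.3 (intermediate) and 0.51 (coarse). The partition rule is
single-linkage: groups are connected components of the graph joining
samples at distance strictly below the threshold. This rule is the unique
one that (a) reproduces the ideal partition whenever the partitioning
condition holds — within-group distances below the threshold, between-group
distances above — and (b) degrades gracefully when it does not, with every
violation surfaced by `partition_condition_report()`. Strictness of the
comparison (`< t`, not `<=`) follows from reading the condition as
"smaller than the threshold". Nestedness of the three levels is automatic
(an edge at a smaller threshold is an edge at a larger one). Human-readable
group labels are derived by majority species label; curated suffixes for
complexes (`_c`) or unresolved members (`_sp1`, ...) are the responsibility
of the labels file, since deciding them is a curation act, not a
computation.

**Assignment.** Per amplified target and per query haplotype, the
nearest-neighbour set is every reference haplotype at the minimal distance
(ties within 1e-12 included — distances are ratios of small integers, so
exact ties are common and floating-point equality needs a tolerance). For
each species-group, the NN *allele frequency* is the weighted share of the
group's allele copies that are NN sequences: each reference sample carries
total weight 2 (homozygote: 2 copies of one haplotype; heterozygote: 1 + 1;
more than two haplotypes: 2/|Q| each — the generalisation we chose to keep
every sample's weight at 2). Frequencies are normalised to per-target
proportions summing to 1, haplotype proportions are averaged within a
target (heterozygous and multi-allelic queries contribute the average over
their unique sequences, each from its own NN search), and per-target
proportions are averaged unweighted over targets. Missing targets are
ignored. A level classifies the query when its top proportion is at least
0.8 (inclusive); tie handling needs no special rule because two groups at
≥ 0.8 would sum above 1. Queries need at least 10 amplified targets.

Frequencies rather than raw NN counts correct for group size: an allele in
2 of 10 homozygous samples of group A and 1 of 2 of group B yields
proportions 0.29 / 0.71, whereas counts would give 0.67 / 0.33 purely
because A is bigger. One subtlety found while testing: the top group's
proportion is monotone towards coarser levels for its own samples, but
strict monotonicity for *minor* groups can fail — pooling a small positive
frequency with a large empty sibling dilutes it. We therefore assert
monotonicity only for the dominant group and document the rest.

**Validation.** `dropout_validation()` removes each reference sample in
turn and re-assigns it. Samples that are singletons at a level have no
same-group neighbour and are excluded from that level's accuracy (reported
separately).

## Stage 2: VAE over summed diploid tables, convex-hull classification

**Input.** One 65,536-entry table per sample: per target, the sum of the
two haplotype tables (heterozygote), twice the single table (homozygote, so
zygosity does not distort totals), or the sum of two randomly chosen
haplotypes (more than two alleles — counts must stay integral for the
Poisson model, so averaging over alleles is not available). Missing targets
contribute zeros. A complete 62-target sample totals a little under 20,000
counts.

**Model.** A fully connected encoder maps each table to a diagonal Gaussian
in a 3-dimensional latent space (mean and log-variance per dimension —
log-variance for numerical stability); one reparameterised sample per
datapoint per step feeds the mirrored decoder, whose softplus output
activation guarantees strictly positive Poisson means. The loss is the
Kullback–Leibler divergence of the Poisson model from the observed counts
(`sum(x*log(x/lambda) + lambda - x)`, equal to the negative Poisson
log-likelihood up to the `log(x!)` constant) plus `w` times the Gaussian KL
of the encoder's distribution from N(0, I), summed over latent dimensions
and averaged over the batch. The regulariser anchors the latent scale and
prevents overfitting.

Defaults: encoder 65,536 → 128 → 32 → (3 + 3), `w = 1`, Adam with learning
rate 1e-3, 200 epochs, batch size 32, tanh hidden activations. All of this
is `vae_config()`; none of the downstream geometry depends on these exact
values, but the hull-stage distance threshold does depend on the trained
latent scale (below).

Two implementation notes. First, the optimiser and backpropagation are
written directly in R against BLAS matrix products; with at most a few
hundred samples and 8.4M parameters in the widest layer this trains in
seconds to minutes on one CPU. Second, raw count tables saturate the first
tanh layer — a single Adam step moves every first-layer weight by ±lr, and
with ~19,000 counts of input mass the pre-activations drift by ±19,
collapsing all samples to one latent point. The encoder therefore reads
deviations from the training-set mean profile, scaled to a mean per-sample
norm of 10; the reconstruction target remains the raw counts. Training is
deterministic given `config$seed` (weights, minibatch order and
reparameterisation draws all derive from it; the caller's RNG state is
preserved).

**Hulls.** Each species (or merged set of species too close to separate,
e.g. sister taxa distinguished only by geography) is represented by the
convex hull of its labelled latent points; at least 4 non-coplanar points
are required, and degeneracy is an error rather than a silently jittered
fix. Facets are enumerated exhaustively over point triples (supporting
planes), which is robust to many coplanar points and cheap at the tens of
points per species this stage sees. Point-to-hull distance is computed
exactly as the minimum-norm point of the translated vertex set (Wolfe's
algorithm); a point inside or on the hull has distance 0 — boundary
membership counts as inside, the conservative choice for classification.
Hull overlap is defined as sharing an *interior* point: it is tested as
zero distance between the hulls after shrinking each towards its centroid
by a relative 1e-6, so boundary contact (a shared vertex, edge or face)
does not count; the effective tolerance is 1e-6 of the hull diameter.
Overlapping hulls are trimmed by repeatedly removing the defining point
with maximal penetration depth (distance from inside to the boundary) into
the other hull, with deterministic tie-breaks (depth, then label, then
index). Each iteration removes one point, so trimming terminates; the
removal set is logged but not guaranteed minimal.

**Classification.** For a query latent position, rules apply in order:
(i) if the two closest hulls are the configured special pair and both
distances are below `special_dist`, the call is `uncertain_<closer>_<farther>`
— this precedes the inside rule, because the region between an inseparable
pair is uncertain even when the point falls inside one of the two hulls;
(ii) inside a hull → that label; (iii) all other hulls at least `ratio`
times farther than the closest → the closest label; (iv) otherwise
`uncertain_` plus every label within `ratio` times the closest distance, in
proximity order. The ratio rule (default 7) is scale-free;
`special_dist` (default 14) is tied to the latent scale of the particular
trained model and must be re-tuned per model — it is a config value, not a
constant of the method. Classification requires at least 50 amplified
targets; VAE training sets require 45 (validation-style sets 30), all
configurable.

## Synthetic data: what it emulates and what it does not

`simulate_reference_db()` generates a panel of 62 targets with lengths
N(160, 30²) (floored at 3k): ancestral sequences are mutated down a
series → complex → species tree, then individuals receive per-haplotype
mutations, per-target heterozygosity (0.3), dropout (0.05) and occasional
contamination (0.01, an allele from another species). Substitution rates
per branch (0.003 / 0.012 / 0.018 / 0.045, with geometric indels at 5e-4)
were chosen from the closed-form expectation that a pairwise per-site
divergence q yields an 8-mer distance of roughly 1 − (1 − q)^8, targeting
the middles of the bands delimited by the 0.1 / 0.3 / 0.51 thresholds;
because indels and finite targets make the closed form approximate,
calibration is empirical-first — realised tiers are measured after
generation and the database is redrawn (rates nudged once) on violation,
with an error after three failures. The default tree places five species in
two complexes, one complex per series, so every level of the hierarchy has
a real decision to make. `simulate_queries()` covers the deployment
scenarios: members, novel species within a represented complex, fully
diverged samples, F1 hybrids, contaminated samples.
`simulate_vae_clusters()` skips sequences entirely and draws Poisson
samples from sparse species-specific mean profiles scaled to ~19,000 counts
per sample, isolating the VAE and hull stages.

What the generator does *not* emulate: population structure within species,
chromosomal inversions, introgression, primer-binding-site evolution
(dropout is a flat per-target probability), read-level error processes, and
the uneven species representation of real reference databases. Passing
tests on this generator therefore demonstrates correctness of the
machinery and recoverability under the stated statistical structure — not
field accuracy on real specimens, which depends on the quality and
coverage of a real reference database.

## Numerical choices and degenerate inputs

- Sequences shorter than k and symbols outside A/C/G/T are errors by
  default (a zero table would silently distort distances; dirty consensus
  haplotypes signal upstream problems); a lenient mode drops affected
  k-mer windows only.
- Sample pairs sharing no target: the pairwise distance is undefined and
  errors as a point operation; inside a distance matrix the pair records
  the sentinel 1.0 with a warning so matrix-level operations stay total.
- NN distance ties: tolerance 1e-12; classification threshold and target
  gates are inclusive ("at least").
- The Wolfe minimum-norm solver regularises its corral system via a
  pseudo-inverse fallback when near-singular; hull facet deduplication
  works on plane coefficients rounded at the degeneracy tolerance
  (1e-9, scaled by the coordinate magnitude).
- VAE: non-finite loss aborts with the offending epoch and loss components;
  decoder output is floored at 1e-8 above zero; the decoder output bias is
  warm-started at the softplus-inverse of the training column means, which
  removes most of the early large-gradient phase.
- Reference databases enforce ≥ 10 amplified targets at build time with an
  explicit rejection report; haplotype frequency values are taken as
  authoritative from the upstream pipeline and never recomputed after
  filtering.

## Problem sizes used in the test-suite

The suite exercises the full pipeline at deliberately desk-sized scales:
reference panels of 20–30 samples (5 species × 4–6 samples, 62 targets),
query sets of 3–20 samples per scenario, VAE fixtures of 150 samples
(3 × 50) trained for 25 epochs with hidden layers 64 → 16 for the
clustering check and smaller configurations for smoke tests, and hull sets
of 8–30 points. These sizes keep every property measurable (exact species
recovery, ARI ≥ 0.9 latent clustering, 100% drop-one-out accuracy at the
fine level) while the whole suite runs in a few minutes on one CPU.

## Known limitations

- Single-linkage partitioning is our documented reading of the
  threshold-based species-groups; where the partitioning condition is
  violated, different clustering rules would disagree, and the report
  exists precisely to expose those cases.
- Trimming minimises nothing: it greedily removes maximal-penetration
  points and can remove more points than strictly necessary.
- The hull-overlap test's shrink tolerance means interpenetrations
  shallower than ~1e-6 of the hull diameter count as touching.
- `special_dist` is meaningful only relative to a trained latent scale;
  persisting a model and its hulls together is the supported workflow.
- The VAE stage needs enough labelled reference samples per fine group
  (≥ 4 non-coplanar latent points after the training gate); the pipeline
  degrades gracefully to the NN outcome for complexes where this fails.
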