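---
title: "Gene-order alignment distances for phage phylogenetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-order alignment distances for phage phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goat)
library(ape)
```

## The problem

Tailed bacteriophages evolve by mechanisms that erode sequence similarity
quickly: high mutation rates, rampant horizontal transfer, and genomic
mosaicism. Above the genus rank, nucleotide identity between phage genomes is
often undetectable while gene *order* — the synteny of the genome — still
carries a usable evolutionary signal, because rearrangements (inversions,
transpositions) and gene gain/loss accumulate more slowly than point
mutations. This package implements a gene-order alignment distance (GOAT,
Gene Order Alignment Tool) for such genomes, together with the supporting
machinery a synteny-based classification study needs: orthologous-group
profiles, family substitution matrices, BioNJ trees, Robinson–Foulds tree
comparison, similarity-threshold taxon demarcation, and a simulator of
gene-order evolution for validation.

## The model

Each genome is reduced to a **gene-order profile**: the sequence of
gene-family labels (e.g. pVOG identifiers assigned by HMM search at E-value
< 10⁻²) in chromosomal order. Genes without a family assignment get unique
`ORFAN:` labels, so they align only to themselves; a flag drops them
instead, since it is genuinely unclear whether unassigned genes should carry
synteny signal.

Two profiles are compared by **semiglobal dynamic-programming alignment**:
end gaps are free on both sequences, internal gap positions cost a linear
penalty, and a match of families *i* and *j* scores `M[i, j]`, a symmetric
substitution matrix built as the average of reciprocal profile–profile
(HHsearch-style) hit scores. Averaging reciprocal hits makes the matrix
symmetric by construction; a missing direction counts as zero, which is the
conservative reading of "average of reciprocal hits" for one-sided hits.

Phage genomes are circular or circularly permuted, and assemblies are cut at
arbitrary positions, so the optimal score `G_AB` is maximized over **all
circular rotations of both profiles and both orientations** (sense and
reversed). Scores convert to a normalized distance

$$D_{AB} = 1 - \frac{G_{AB} + G_{BA}}{G_{AA} + G_{BB}},$$

which is 0 for identical gene orders, 1 for genomes sharing no alignable
families, symmetric by the formula, and clamped to [0, 1] with a warning in
the pathological case where cross-scores exceed self-scores (impossible for
identity-like matrices). The distance matrix feeds BioNJ to produce a tree.

```{r toy}
m <- synth_similarity_matrix(LETTERS[1:6])
a <- genome_profile("A", c("A", "B", "C", "D"))
b <- genome_profile("B", c("C", "D", "A", "B"))   # rotated copy
goat_distance(a, b, m)                            # 0: rotation is invisible
```

## Why rotations of *both* genomes are searched

A natural shortcut is to rotate only the second genome, on the argument that
rotating both is redundant. For semiglobal alignment with internal gap
penalties this is false: aligned pairs must be monotone in the *linearized*
first sequence, so adjacencies that straddle its cut point can never be
used. A two-gene example shows it: with profiles `[A,B]` and `[A,X,B]`
(identity matrix, gap 0.5), the best score over rotations of the second
profile alone is 1.5, but after rotating the first profile to `[B,A]` the
rotation `[X,B,A]` aligns both genes adjacently for a score of 2. Searching
one side only would make the distance depend on the arbitrary assembly
origin of the first genome. The implementation therefore maximizes over
rotations of **both** circular profiles (and both orientations), which makes
the score exactly invariant to the linearization origin and the reading
direction of either input — properties the test suite checks directly. The
extra factor in run time (the DP runs *n·m* times instead of *m*) is
irrelevant at phage scale.

Determinism is pinned down everywhere a tie could arise: the search prefers
the smallest rotation offset of the first profile, then of the second, then
sense over antisense; the traceback prefers diagonal moves, then gaps
consuming the first sequence; equal-scoring end cells resolve to the largest
coordinates.

## Tunable parameters

* `gap_penalty` (per internal gap position): default **0.5 × median
  diagonal** of the substitution matrix. A matrix-relative default keeps
  distances invariant when hit scores are rescaled (HHsearch score columns
  differ between runs and versions); with an identity-like matrix it equals
  0.5, so one internal indel costs half a perfect match.
* `search_rotations`, `search_antisense`: on by default; rotations apply
  only to profiles flagged circular.
* `evalue_max` for family assignment: hits pass at E-value strictly below
  10⁻², the conventional cutoff for pVOG HMM assignment; among passing hits
  the smallest E-value wins, ties broken by larger score then lexicographic
  family id.
* Hit filters for Dice/symmetrical-identity aggregation: identity ≥ 30%,
  alignment length ≥ 30, E ≤ 0.01 — the standard reciprocal-tBLASTx filter
  triple, all configurable.
* Demarcation thresholds: percent similarity with strict `>` edges;
  conventional presets 95 (species, nucleotide identity), 50 (genus, SI),
  25 (subfamily, translated SI). Single linkage is the only linkage under
  which ">X%" edges compose transitively into clusters, and it makes
  partitions provably nested as the threshold rises.

## Genome similarity from hit tables

Dice and symmetrical identity are aggregated from standard 12-column
tabular alignment output. Both use **identity-weighted merged intervals**:
each query position covered by at least one filtered hit contributes its
maximum fractional identity, computed on atomic segments between interval
breakpoints (minus-strand coordinates are normalized first). Then

* Dice = `100·(C_AB + C_BA)/(len_A + len_B)`,
* SI = `100·(C_AB/len_A + C_BA/len_B)/2`,

where `C_XY` is the weighted covered length of X against Y. The exact
aggregation used by the original tools is not published; this definition is
documented, tested against a per-position brute-force oracle, and both
scores are bounded in [0, 100], symmetric, and equal 100 for complete
self-hits.

## Trees and their comparison

BioNJ (variance-weighted neighbor joining) turns the distance matrix into an
unrooted tree; on any additive matrix it recovers the generating topology
and branch lengths exactly, which the tests verify on random trees up to 12
leaves. Negative estimated branch lengths — possible on non-additive input —
are set to zero with the difference transferred to the sister edge,
preserving leaf-to-leaf path lengths. Trees are rooted by placing the root
at the midpoint of a designated outgroup's pendant edge.

Robinson–Foulds distances count non-trivial bipartitions present in exactly
one tree. The normalized form divides by the **total number of non-trivial
bipartitions in both trees** rather than `2(n−3)`: this handles
multifurcating trees gracefully (a pair of star trees compares as 0, not
0/0) and reads directly as "the fraction of data partitions present in only
one tree". Both conventions coincide for binary trees, where the raw count
is cross-checked against phangorn.

## The simulator: what it emulates, and what it does not

`evolve_along_tree()` draws a random ancestral profile (labels sampled
without replacement from a family pool) and evolves it along a given tree;
each branch receives Poisson(total rate × length) events drawn from five
types: arc inversion, arc transposition, single-gene loss, single-gene gain
(always a fresh `NOVEL:` label, so convergent gain never fakes homology),
and rotation of the linearization origin. Defaults — 30-gene profiles from a
pool of 500 families, rates (0.1, 0.1, 0.15, 0.15, 0.1) per branch unit,
arc spans 2–8 — model a large-phage scenario in which indels outnumber
rearrangements and the annotated gene complement is a few dozen families;
they were fixed once, before any validation was run. Every event is logged
with its sampled parameters, and replaying a log reproduces the mutated
profile exactly.

What the simulator does **not** emulate: sequence-level evolution (family
assignment noise, HMM sensitivity), unequal family sizes and paralogy,
biased rearrangement hotspots, and homologous recombination between
lineages. Passing tests on simulated data therefore validate the
*algorithms* — that the DP finds true optima, that distances respect their
axioms, that trees are recovered when the signal is present — not the
biological adequacy of gene order as a marker for any particular clade.

## What recovery simulations can and cannot show

With rearrangement signal on every branch, the pipeline recovers topologies
well: the test suite includes an 8-leaf run with three guaranteed events per
branch that recovers most of the tree, and the command-line `simulate` →
`distmat` → `tree` path at moderate rates routinely reaches RF = 0. But
under a *Poisson* event process at low rates the recovery probability is
bounded by elementary arithmetic, not by implementation quality: at 0.5
events per branch a given internal branch receives **no** event with
probability e⁻⁰·⁵ ≈ 0.61 (and rotation events carry no signal at all, so
the informative rate is lower still). An internal branch without events
leaves its bipartition unsupported in the distance matrix, and any
tree-building method resolves it arbitrarily. For the 8-leaf balanced tree
(5 internal branches) the chance that every internal branch is informative
is below 1%, so high RF = 0 rates are unattainable in that regime, and
median RF *rises* as rates fall towards zero (signal starvation) until the
opposite, saturation regime takes over at high rates. The acceptance suite
reports recovery under the low-rate regime as measured; simulation problem
sizes throughout (8 leaves, 30-gene profiles, 20 replicates per condition)
were chosen as the smallest designs in which these regimes are clearly
separated.

## Numerical and degenerate-input choices

* All alignment scores are nonnegative (mismatches score whatever the
  matrix says, never less than 0 via the empty alignment), so distances
  cannot exceed 1 with identity-like matrices.
* Self-scores of zero (possible only with a zero diagonal) are an error:
  the distance is undefined.
* A label with no self-hit in the hit table gets its diagonal set to its
  row maximum (or 1 for an empty row) with a warning — self-alignment must
  be positive.
* `ORFAN:` labels added to a matrix get the median diagonal of real
  families, off-diagonal 0, letting unassigned genes match only themselves
  without dominating.
* Traceback and agglomeration ties are all broken deterministically (see
  above; BioNJ ties follow ape's implementation order).
* Genes spanning a circular origin are placed by their start coordinate;
  coordinates are 1-based inclusive in both GFF3 and TSV dialects.

## Limitations

* The gap model is linear; affine gaps would require a three-matrix DP and
  are not implemented (nothing in the distance definition needs them).
* Strand labels are carried through profiles but not consulted by the
  aligner: the antisense search reverses label order only, consistent with
  aligning order alone.
* Exact numeric parity with the fragment-based similarity tools that
  inspired the SI aggregation is not claimed; only the documented
  interval-based definition is implemented.
* The exhaustive alignment reference (`best_alignment_exhaustive`) is
  combinatorial and only usable for profiles of ~10 genes; it exists to
  validate the DP, not to analyze data.
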