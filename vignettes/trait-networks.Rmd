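---
title: "Trait co-occurrence networks: model, nulls and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait co-occurrence networks: model, nulls and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitgraph)
```

## The model

`traitgraph` treats a characters × taxa matrix not as input to tree
inference but as a catalogue of trait co-occurrences. Each multistate
character is split into one binary trait per state; states whose label
indicates absence are dropped, because "lacks feature X" and "has feature X
shaped Y" are not symmetric observations — only realised features are
nodes. The *support* of a trait is the set of taxa bearing it; missing
cells support nothing.

For every pair of traits from *different* characters, the pair of supports
falls into exactly one of four relations — identical (I), strictly nested
(II, directed from nested to inclusive), overlapping-but-non-nested (III),
disjoint (IV) — which partition all cross-character pairs because the four
set predicates are exhaustive and mutually exclusive on non-empty sets.
Pairs of states from the same character are skipped entirely: their
disjointness is a coding artefact, not biology. The result is a multiplex
network that is a deterministic, exact picture of the matrix: no
thresholds, no weights, no heuristics.

Interpretation rests on a few assumptions worth keeping in mind:
taxon sampling is taken at face value (a "disjoint" pair may co-occur in
unsampled taxa); characters are scored consistently across taxa; and the
matrix is near-complete (the only implemented missing-data policy treats a
missing cell as the absence of all of that character's traits for that
taxon, a deliberate simplification appropriate for matrices with isolated
missing entries — the package logs how many cells it applied to).

## Statistics

* **Complexes** — connected components (≥ 2 nodes) of the type I layer.
  Identity of supports is transitive, so components must be cliques; the
  implementation verifies this rather than assuming it.
* **Stability** — type II in-degree counts how many traits live strictly
  inside a focal trait's distribution; in-degree 0 with positive out-degree
  marks precarious/unstable traits.
* **Fluidity** — on the type III layer with `k` edges and `N` total traits,
  density is `2k/(N(N−1))` and the proportion of triangles divides the
  triangle count by all `N(N−1)(N−2)/6` possible triplets. This is
  intentionally *not* transitivity: the denominator counts unconnected
  triples too, so the proportion is comparable across networks of equal
  `N` regardless of connectance. `N` is the full trait count of the
  recoded matrix, including nodes isolated on the type III layer — the
  one consistent choice under which the density and triangle-proportion
  identities pin down the same `N` (both closed forms solved over the
  integers give a single common solution; `scripts/acceptance.R`
  recomputes this). The diameter is the longest shortest path within any
  connected component (single-node components contribute 0; an empty layer
  has diameter 0).
* **Type D triplets** — `{s, t, u}` with `t–s`, `t–u` of type III and
  `s–u` of type IV; `t` is the central node. The definition used is the
  III + III + IV motif — the one under which the worked four-trait fixture
  (`pivotal_trait_fixture()`) reproduces its documented two central triplets; some
  summary tables label this row as a "type II+IV" pattern, which does not
  match that worked example and is not used here. Counting is exact:
  `diag(A₃A₄A₃)/2` per node, cross-checked in the test suite against full
  enumeration of all triples.

## Permutation nulls

Both nulls permute states *within columns*, preserving each column's state
multiset exactly. Consequences used throughout: trait supports keep their
sizes, traits remain identifiable by (character, state) across replicates
— which is what makes per-node null distributions well defined — and the
recoding of a permuted matrix never gains or loses traits.

* **Equiprobable**: each column is independently, uniformly permuted
  across taxa; the null of uncoordinated evolution.
* **Phylogenetic**: a restricted permutation accounting for phylogenetic
  autocorrelation. Patristic distances are normalised to a maximum of 1
  and turned into weights `w = k − d` with `k = 1.01` by default, so
  exchanges between the closest relatives are ~100× more likely than
  between the most distant ones; `k → ∞` recovers the equiprobable
  scheme. Each column draws a random bijection by visiting target taxa in
  random order and sampling an unused source taxon with probability
  proportional to `w(target, source)`.

One numerical choice needs stating. The weight matrix `W` carries `k` on
its diagonal (`d_ii = 0`), but using that value when *sampling* would make
self-assignment ~100× more likely than any exchange at `k = 1.01`,
collapsing the permutation toward the identity and breaking the
exchangeable limits that define the scheme's contract (a star tree, where
all taxa are equidistant, must give uniform permutations). The sampler
therefore treats self-assignment like assignment from the taxon's nearest
neighbour (`w_tt = k − min_s d_ts`): on a star tree all sampling weights
become equal (exactly uniform), `k → ∞` is uniform, and on a structured
tree a state still preferentially stays at or near its own tip. The
`phylo_weights` object exposes both matrices (`W`, and the sampling matrix
`S`).

Empirical one-sided p-values use `(b+1)/(M+1)` with `b` the number of
replicates at least as extreme as the observed value, so the smallest
attainable p is `1/(M+1)`; with the default `M = 5000` that floor is
`1/5001 ≈ 0.0002`. The same `M` is used for both models. Scalar statistics
report the smaller tail with a Higher/Lower/NS label, Bonferroni-corrected
over the family of scalar statistics. Per-node tests (stable traits via
type II in-degree, pivotal traits via type D centrality) use the upper
tail only, are Bonferroni-corrected over **all `N` nodes** — the
conservative choice, since no principled subset of "tested" nodes exists
— and must pass under *both* nulls. The code warns at run time when `M`
is too small for the corrected floor `N/(M+1)` to reach `alpha`, since
then no node can ever be flagged.

Calibration is part of the test suite: on data generated from the
equiprobable null itself, p-values are super-uniform (never
anti-conservative), checked by a one-sided Kolmogorov–Smirnov test over
hundreds of simulated data sets; the two nulls are statistically
indistinguishable on a star tree.

## Tree-based classification of nested pairs

Against a rooted reference tree, each directed type II edge
(inner → outer) is classified by whether each endpoint's support is
subtended by an edge of the tree: clade-in-clade (nested synapomorphies),
clade-in-paraphyletic, paraphyletic-in-clade,
paraphyletic-in-paraphyletic. "Paraphyletic" is operationalised simply as
"not monophyletic with respect to the sampled taxa" — the data cannot
distinguish para- from polyphyly, and a binary endpoint test is the only
reading under which the four categories partition the nested pairs.
Singletons and the full leaf set count as monophyletic. Monophyly is
assessed on the tree as rooted; no unrooted bipartition fallback is
attempted. Trees supplied without branch lengths get unit lengths with a
warning (topological distances), which matters only for the phylogenetic
null.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `absence` | labels matching `/absen/` (case-insensitive) | which states are absence-coded; also accepts explicit symbols/labels or a predicate. With unlabelled states and no option, nothing is treated as absence. |
| `min_taxa` | 1 | minimum support size for a trait to enter the network; single-host traits are kept by default (they are autapomorphy-like and generate trivial patterns, and users may prefer `min_taxa = 2`). |
| `permutations` (`M`) | 5000 | replicates per null model; p-value floor `1/(M+1)`. |
| `phylo_k` | 1.01 | restriction strength of the phylogenetic null; larger is closer to equiprobable. |
| `alpha` | 0.05 | family significance level after Bonferroni. |
| `seed` | — | one integer drives both permutation streams; identical settings + seed give byte-identical outputs. |

## The synthetic generators

`random_matrix()` draws cells i.i.d. uniformly over each character's
states (the equiprobable null's own generating process), with an optional
missing-cell rate. `simulate_mk_on_tree()` evolves each character
independently down a tree under the symmetric q-state Mk process from a
uniform root state, using the closed-form branch transition probabilities
(the matrix exponential of the symmetric rate matrix), which is exact and
cheap for small state counts. Together they bracket the two nulls: the
first generates data with no structure, the second data whose only
structure is phylogenetic.

What they deliberately do **not** emulate: correlated characters (beyond
what shared phylogeny induces), rate heterogeneity across sites or
branches, ascertainment bias of morphological matrices (characters are
included by systematists *because* they vary informatively), polymorphic
cells, or scorer error. Passing tests on these generators therefore
demonstrate the correctness of the combinatorics and the calibration of
the tests under their stated nulls — not that real matrices satisfy those
nulls.

`pivotal_trait_fixture()` is the worked four-trait configuration (supports
`{a,b}`, `{b,c,d}`, `{c,e}`, `{d,e}`) whose complete edge pattern, type D
count and diameter are known by hand enumeration; it anchors the end of
the test suite and the acceptance script.

## Numerical and degenerate-input choices

* Undirected edges are stored once with `from < to`; all edge tables are
  sorted by (from, to); iteration order is deterministic everywhere, so a
  given matrix yields one network and one output byte stream.
* Density requires `N ≥ 2`, the triangle proportion `N ≥ 3`; both raise
  errors rather than returning `NaN`.
* An all-states-filtered recoding ("empty trait set") is an error, not an
  empty network.
* A zero-length tree (all patristic distances 0) yields uniform weights
  with a warning.
* A statistic failing on a permuted replicate is recorded as a missing
  replicate with a warning, and `M` is effectively reduced for that
  statistic's p-values.
* The regionalization test builds the 2×2 table (unstable vs. not) ×
  (cranio-dental S/T/J vs. postcranial BP/FL/HL) and uses the two-sided
  Fisher exact test; an empty margin returns p = 1 with a warning. The
  two-group split follows the conventional contrast of cranio-dental
  against postcranial regions.

## Problem sizes in the shipped tests

The suite exercises: brute-force classifier equivalence on 200 random
matrices (≤ 8 taxa, ≤ 6 characters); exhaustive triangle/D-triplet
enumeration up to N = 30; p-value calibration over 500 simulated data sets
at `M = 199`; star-tree equivalence over 2 × 2000 replicates; an exact
p-value check against full enumeration of all 24³ per-column permutations
of a 4 × 3 matrix; and seed-stability of flagged trait sets at `M = 5000`
on a 15-taxon, 30-character nested-support generator. These sizes were
chosen so that every oracle is exact and the full suite runs in a few
minutes on a laptop.

## Known limitations

* No polymorphic cells ("0&1"), no gap-vs-missing distinction, no
  continuous characters.
* The only missing-data policy is absent-for-that-character; with
  missing-heavy matrices this deflates supports and should be revisited.
* The restricted permutation is one member of the family of
  distance-weighted permutation schemes; its exchangeable limits (star
  tree, large `k`) are exact, but intermediate-`k` behaviour is a
  modelling choice, not a canonical algorithm.
* Per-node significance inherits the conservatism of Bonferroni over all
  `N` nodes; with thousands of traits, genuinely stable nodes may fail to
  reach the corrected threshold unless `M` is raised accordingly.
* The package computes no communities, centralities or embeddings beyond
  the statistics described above; the network files (GraphML/TSV) are the
  interface to general-purpose graph tooling.
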