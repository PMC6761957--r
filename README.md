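# traitgraph

Trait co-occurrence networks from morphological character matrices.

Phylogenetic "characters × taxa" matrices are usually consumed by tree
inference. `traitgraph` enumerates a different signal in the same data: it
recodes every non-absence character state into a presence/absence **trait**,
then classifies every pair of traits from different characters by comparing
their taxon-support sets

- **type I** — identical supports (the traits always co-occur; connected
  components of this layer are *complexes*, candidate units of common
  developmental regulation),
- **type II** — one support strictly nested in the other (a directed edge
  from the nested to the inclusive trait; high in-degree marks *stable*
  backbone traits, in-degree zero marks *unstable* ones),
- **type III** — overlapping but non-nested supports (traits used in
  different combinations in different organisms — a signature of
  dissociability),
- **type IV** — disjoint supports (traits never found together).

The four relations partition all cross-character pairs, so the multiplex
network is an exact picture of the matrix, not an inference. On the type III
layer the package computes the density `2k / (N(N−1))`, the number of
triangles and their proportion among all `N(N−1)(N−2)/6` possible triplets
(deliberately **not** a clustering coefficient), and the diameter. Combining
layers, a **type D triplet** is a triple `{s, t, u}` with `t–s` and `t–u`
overlapping and `s–u` disjoint: the central trait `t` is a *pivotal*
candidate, used in alternative organisations that never co-occur.

Significance is assessed with two permutation nulls that both preserve each
column's state multiset (so traits stay identifiable across replicates):

- **equiprobable** — uniform within-column permutation of states across
  taxa;
- **phylogenetic** — restricted within-column permutation in which states
  preferentially move between close relatives, with weights `w = k − d`
  (`d` = patristic distance normalised to max 1, `k = 1.01` by default).

Empirical one-sided p-values follow `(b+1)/(M+1)`; per-node tests
(stable/pivotal traits) are Bonferroni-corrected over all `N` nodes and
require significance under *both* nulls. Against a reference tree, every
nested (type II) pair is classified by endpoint monophyly into
clade-in-clade, clade-in-paraphyletic, paraphyletic-in-clade and
paraphyletic-in-paraphyletic — separating nested synapomorphies from
associations that need other explanations.

## Worked example

Four traits over taxa `a`–`e` with supports `n43 = {a,b}`, `n38 = {b,c,d}`,
`n2 = {c,e}`, `n12 = {d,e}`:

```r
library(traitgraph)
net <- build_network(pivotal_trait_fixture())
summary(net)
#> trait network metrics (N = 4)
#>   complexes: 0 (covering 0 traits)
#>   edges: I=0 II=0 III=4 IV=2
#>   type III: density 0.666667, triangles 1 (proportion 0.250000), diameter 2
#>   type D triplets: 2
```

No two supports are identical or nested, so the I and II layers are empty.
`n38` overlaps `n43`, `n2` and `n12` (type III), while `n43` is disjoint
from `n2` and `n12` (type IV): `n38` is therefore central in two type D
triplets (`{n43, n38, n2}` and `{n43, n38, n12}`) — a pivotal trait
combined with partners that never co-occur. The triangle `{n38, n2, n12}`
gives 1 of the 4 possible triplets (proportion 0.25), and the longest
shortest path on the overlap layer (e.g. `n43–n38–n2`) has length 2.

A full analysis from a file, including both permutation nulls and
tree-based classification of nested pairs:

```r
run_trait_analysis("matrix.nex", "out/", tree_file = "tree.nwk",
                   permutations = 5000, seed = 1)
```

or from a shell via the bundled driver:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "traitgraph.R", package = "traitgraph"))') \
  run --matrix matrix.nex --tree tree.nwk --permutations 5000 --seed 1 --out out/
```

Outputs: `summary.json` (all scalar metrics), `traits.tsv`, `nodes.tsv`
(degrees, D-centrality, significance flags), `edges_type1..4.tsv`,
`complexes.tsv`, `multiplex.graphml`, `permutations.tsv`,
`nested_pairs.tsv`.

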