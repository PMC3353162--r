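# phylodist

Linear-time evolutionary distinctiveness indices on edge-weighted
phylogenetic trees.

## The problem

Conservation triage needs a defensible way to rank species by how much
unique evolutionary history each one carries. Three per-taxon indices
dominate this literature, all built on phylogenetic diversity
(PD — the total branch length of the smallest subtree connecting a set of
leaves):

- **Fair proportion (FP)** — on a rooted tree, each edge's length is split
  equally among the species descending from it, and a species' score is the
  sum of its shares along the root-to-tip path:
  `FP(x) = Σ_{e ∈ path(root,x)} λ(e) / |S_e(x)|`.
  Multiplied by an extinction probability it gives the EDGE score used for
  global prioritisation rankings.
- **Shapley value** — the game-theoretic value of the coalitional game whose
  payoff is PD on the *unrooted* tree: the expected marginal PD a taxon adds
  over all arrival orders of the taxa. It reduces to a per-edge linear
  combination `ψ(x) = Σ_e |S̄_e(x)| / (n·|S_e(x)|) · λ(e)`, where `S_e(x)`
  is the block of edge `e`'s split containing `x`.
- **HED (heightened evolutionary distinctiveness)** — the expected marginal
  PD a taxon adds to the surviving taxa when every other taxon independently
  goes extinct with probability `p(·)`:
  `ψ(x) = Σ_e (Π_{y∈S_e(x)−{x}} p(y)) · (1 − Π_{y∈S̄_e(x)} p(y)) · λ(e)`.

Evaluating the Shapley and HED edge sums naively costs O(n²) per tree, which
is prohibitive for posterior samples of thousands of trees with thousands of
tips. phylodist computes both in **linear time**: each edge is replaced by a
pair of directed arcs carrying precomputed coefficients, the first taxon of
a planar leaf ordering is evaluated directly, and every subsequent taxon's
score is obtained by updating only the arcs on the path from its
predecessor — each edge is touched at most twice over the whole sweep.
Zero-probability taxa (for which the HED arc form would divide by zero) go
through a dedicated coefficient set, and probability products are kept as
(zero-count, log-sum) pairs so they neither underflow nor require division.

The package also provides exhaustive definitional oracles (subset
enumeration and permutation averaging, for testing), IUCN Red List category
mapping with data-deficient imputation, a Yule tree simulator, streaming
batch scoring of multi-tree Newick files, and a command line.

## Worked example

```r
library(phylodist)

tr <- parse_newick(
  "((((platypus:60,echidna:60):120,(elephant:100,(dolphin:60,bat:60):40):80):5,opossum:185):15,kiwi:200);")
status <- c(platypus = "NT", echidna = "CR", elephant = "VU",
            dolphin = "LC", bat = "EN", opossum = "LC", kiwi = "DD")
p <- map_categories(status, builtin_value_set("isaac"))
score_tree(tr, scores = c("fp", "shapley", "hed", "edge"), p = p)
```

```
     taxon    fp edge_product shapley    hed pendant_length
1 platypus 123.5        6.175   121.6 108.12             60
2  echidna 123.5       49.400   121.6  66.02             60
3 elephant 130.2       13.017   125.6 100.41            100
4  dolphin 110.2        2.754   104.3  69.62             60
5      bat 110.2       22.033   104.3  61.20             60
6  opossum 187.5        4.688   191.3 185.91            185
7     kiwi 200.0       26.667   216.3 215.17            215
```

Reading the numbers: FP and Shapley are close everywhere and sum to the
total edge length (conservation); the deep, species-poor lineages (opossum,
kiwi) get the extra weight of the unrooted stem under Shapley. HED is
dominated by each species' pendant edge — the echidna's HED is *below* its
FP because its own high risk (CR, p = 0.4) cannot threaten the branches it
shares with the safer platypus, while the EDGE product (FP × p) still ranks
it first. The kiwi, data deficient, was imputed the weighted mean of the
other six probabilities.

Batch scoring from the shell:

```sh
Rscript exec/phylodist simulate-yule --n-tips 500 --n-trees 100 --seed 7 --out trees.nwk
Rscript exec/phylodist score --trees trees.nwk --scores fp,shapley --out scores.tsv
Rscript exec/phylodist compare --trees trees.nwk --scores fp,shapley
```

## Layout

- `R/` — tree model and Newick I/O (`parse_newick`, `unroot_tree`,
  `phylogenetic_diversity`), the scoring engine (`fair_proportion`,
  `shapley_linear`, `hed_linear`, `hed_zero_prob`, quadratic cross-checks),
  oracles (`shapley_exhaustive`, `shapley_permutation`, `hed_exhaustive`),
  IUCN mapping (`builtin_value_set`, `map_categories`, `combine_runs`),
  generators (`yule_tree`, `random_probabilities`, `basal_clade_fixture`),
  batch layer (`score_batch`, `compare_report`) and CLI.
- `vignettes/evolutionary-distinctiveness.Rmd` — methods notes: model,
  algorithm, numerical choices, limitations.
- `tests/testthat/` — unit, property and end-to-end suites.
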