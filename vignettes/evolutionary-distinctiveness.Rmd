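---
title: "Evolutionary distinctiveness indices in linear time: methods notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary distinctiveness indices in linear time: methods notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylodist)
```

## The indices

Let `T = (V, E, λ)` be an unrooted tree on `n` taxa with non-negative edge
lengths, and for a leaf set `Y` let `PD(Y)` be the total length of the
smallest subtree connecting `Y` (0 for `|Y| ≤ 1`). Deleting an edge `e`
bipartitions the taxa; `S_e(x)` denotes the block containing taxon `x`.

**Fair proportion** is a rooted index: each edge's length divided by the
number of descendant species, summed along the root-to-tip path. Its column
sums to the total edge length of the tree.

**The Shapley value** of taxon `x` is the average, over all `n!` arrival
orders, of the marginal PD that `x` contributes. It collapses to a linear
combination of edge lengths,

```
ψ_sh(x) = Σ_e  |S̄_e(x)| / (n · |S_e(x)|) · λ(e),
```

and inherits Shapley efficiency: the scores sum to `PD(X) = Σ λ(e)`.

**HED** assumes each taxon `y` independently goes extinct with probability
`p(y)` and asks for the expected marginal PD `x` would add to the
survivors. Its edge form is

```
ψ_hed(x) = Σ_e (Π_{y ∈ S_e(x)−{x}} p(y)) · (1 − Π_{y ∈ S̄_e(x)} p(y)) · λ(e):
```

an edge contributes only if everyone sharing it with `x` dies (first
product) while someone beyond it survives (second factor).

Both unrooted indices ignore the root: a degree-2 root is suppressed
internally and its two half-edges merged, so any rooting of the same tree
gives identical Shapley/HED vectors (tested to 1e-9). FP genuinely depends
on the root, so `fair_proportion()` refuses a tree whose root designation
was dropped rather than guessing a midpoint root. A root *branch*
(`$root.edge` in Newick) belongs to no split and is excluded from every sum.

## The linear-time traversal

Each edge is replaced by two directed arcs. For an arc pointing away from
taxon `z`, its coefficient depends only on which side of the split `z` lies,
so one pass computes two numbers per edge (clade side / complement side):
for Shapley, `|S̄|/(n|S|)`; for HED, `Π_near p · (1 − Π_far p)`. A taxon's
score is the sum of coefficient × length over the arcs directed away from
it.

The engine then walks a planar leaf ordering `x₁, …, xₙ` (the depth-first
circuit of the tree as written in Newick, so output order is reproducible):
`x₁` is evaluated directly, and each `x_{i+1}` differs from `x_i` only on
the arcs along the path between them, where the reference taxon switches
sides. In a depth-first circuit every edge lies on at most two
consecutive-leaf paths, so the incremental phase performs at most `2|E|`
coefficient updates. The implementation records this count and exposes it
as the `update_count` attribute; the test suite asserts the bound on every
tree it touches. Internally the updates are a single vectorised cumulative
sum over the Euler tour, so scoring 10⁵ tips (Shapley + HED) takes well
under a second; the acceptance script measures the per-edge cost ratio
between 10⁴ and 10⁵ tips, which sits near 1.4 (a quadratic implementation
would be near 10).

### Zero extinction probabilities

HED for `p(x) > 0` is recovered from the arc sums by dividing by `p(x)`.
For `p(x) = 0` the package evaluates a second coefficient set in which the
near-side product runs over the *positive*-probability taxa only and is
admissible only when the near side contains at most one zero-probability
taxon (then necessarily the reference taxon itself); the far-side factor
keeps the plain product, which is 1 whenever that side contains any
zero-probability taxon. This is the unique reading under which the route
reproduces the definitional edge form for every zero-probability taxon, and
the suite verifies exactly that — against exhaustive enumeration — on trees
carrying 0, 1 and `n` zeros, with exact 1s mixed in.

Probabilities that are positive but below 1e-300 would turn the division
into noise amplification; they are treated as zeros with a warning.

## Numerical choices

- Probability products are maintained as a pair (count of zero factors,
  log-sum of positive factors). Products over thousands of taxa then cannot
  underflow, zeros stay exact, and no division by a possibly-zero factor is
  ever needed. One code path is used at every tree size.
- Factorial weights in the exhaustive oracle are exact (12! fits a double
  with no rounding); the division by `n!` happens once at the end.
- Comparisons in tests use relative tolerance 1e-9 with an absolute floor
  of 1e-12 near zero; the pipeline is pure double-precision arithmetic and
  observed discrepancies are ~1e-14.
- Zero-length edges are legal and contribute nothing; negative lengths are
  rejected at parse time. Ties in the leaf ordering follow the input Newick
  order, making all outputs deterministic.
- A two-leaf unrooted tree is represented by its degree-2-root cherry
  (ape's `phylo` cannot encode a single free edge); every split-based
  quantity merges the two half-edges, so totals, scores and pendant lengths
  equal those of the one-edge tree.

## Oracles and what the tests show

Two brute-force implementations evaluate the definitions literally:
subset-sum Shapley with factorial weights and survival-weighted HED
enumeration, both over all subsets (hard cap 12 leaves), using their own
phylogenetic diversity routine (union of leaf-to-leaf edge paths) so no
code is shared with the production engine. A third, permutation-average
Shapley (≤ 7 leaves) checks the subset form independently. The acceptance
suite crosses linear, quadratic and exhaustive routes on 200 random Yule
trees of 2–9 tips and requires agreement to 1e-9; conservation, re-rooting
invariance, scale equivariance and the HED limit identities
(`p ≡ 0` → pendant edge exactly; `p ≡ 1` → 0; uniform `p = 1e-6` →
correlation with the pendant above `1 − 1e-6`) are asserted on larger
simulated trees.

## The generators, and what they do not emulate

`yule_tree()` draws pure-birth trees conditioned on the tip count: two
crown lineages, exponential waiting times at total rate (birth rate ×
lineage count), a uniformly chosen lineage splitting at each event, and a
final exponential epoch so all pendant edges are positive. Trees are
binary, ultrametric, and a deterministic function of the seed. The birth
rate defaults to 1 since every index is scale-equivariant. Test sizes
follow the study conditions of the suite: 200 small trees (2–9 tips) for
oracle equivalence, 50 trees at 10/100/1000 tips for conservation, single
trees at 10⁴–10⁵ tips for the scaling measurements.

`basal_clade_fixture()` builds the configuration in which Shapley and FP
visibly part ways: a small clade joined to a large balanced clade by two
long stems. For its members the unrooted Shapley sum keeps a sizeable
contribution from the stem that the rooted FP path shares away, so
Shapley > FP for every basal tip — the suite asserts the sign, not a
magnitude.

Real phylogenies are not Yule trees: empirical trees carry polytomies
(supported throughout — every formula is split-based and degree-agnostic),
non-ultrametric branch lengths (also supported), correlated extinction
risks and imperfect taxonomies. Passing tests therefore certify the
*algorithms* — agreement with definitions, invariances, scaling — not any
biological claim about a particular dataset. Taxon matching between trees
and probability tables is deliberately exact (trimmed, unquoted,
case-sensitive) and mismatches are hard errors; experience with large
supertrees says silent reconciliation is where analyses go wrong. The batch
layer's `--intersect` flag is the one sanctioned relaxation: it prunes all
trees to their common taxa, merging the adjacent edges.

## IUCN probabilities

`builtin_value_set()` ships the two published category-to-probability
assignments: `isaac` (CR 0.4, EN 0.2, VU 0.1, NT 0.05, LC 0.025 — risk
doubling per rank) and `iucn100` (0.999, 0.667, 0.1, 0.01, 0.0001).
Data-deficient taxa take, by policy, the weighted mean of the mapped
non-DD values, a fixed category's value (`as_category:NT`), or a fixed
number. `combine_runs()` averages score tables from alternative DD
treatments; the mean is unweighted — the natural symmetric choice when two
equally defensible runs are combined — and the component tables are kept so
any other combination can be applied downstream. Extinct codes (EX/EW) are
rejected with instructions to prune those tips: scoring an extinct species
against a tree that still contains it answers no meaningful question.

## Known limitations

- The exhaustive oracles refuse more than 12 leaves by design.
- `compare_report()` returns `NA` correlations for constant columns (e.g.
  all-equal pendants on a perfectly balanced synthetic tree).
- Newick is the only tree format (one tree per line for batches); NEXUS
  users should convert upstream.
- Single-tree scores carry no uncertainty; across-tree spread (sample SD)
  is only available from `score_batch()` over a tree sample.
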