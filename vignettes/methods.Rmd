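---
title: "Methods: models, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supertreeq)
```

This vignette documents what `supertreeq` computes, the parameter defaults
and why they were chosen, and where the implementation deliberately departs
from textbook formulations. It is the reference companion to the README's
worked example.

## 1. Problem setting

A *profile* is a collection of unrooted source trees on overlapping taxon
subsets. A supertree method maps a profile to a single tree on the union of
the source-tree leaf sets. We benchmark methods in a simulation study where
the true (model) tree is known, so both the *optimization criterion* a
method targets (similarity to its input trees) and its *true error*
(distance to the model tree) can be measured — and the rank correlation
between the two can be studied.

## 2. The simulator (`model_condition`, `build_profile`)

Each replicate of a condition is generated as follows.

1. **Model tree.** A pure-birth (Yule) tree on `n` taxa
   (`simulate_model_tree`). Branch lengths are deviated from ultrametricity
   by multiplying each edge by an independent log-normal factor
   (`deviation_sd = 0.5` by default), so the tree violates a molecular
   clock the way empirical trees do.
2. **Gene presence.** Each gene's taxon set is produced by a birth/death
   walk over the model tree (`assign_gene_leafsets`): a gene is gained on a
   random edge and subsequently lost on descendant edges with a fixed
   per-edge probability. This yields the clustered, phylogenetically
   autocorrelated missing-data patterns real multi-gene datasets show,
   rather than uniformly random deletion. A consequence worth knowing:
   a taxon can be lost from *every* gene, so a profile may cover fewer
   than `n` taxa. All downstream construction and evaluation operates on
   `profile_taxa(profile)`, and supertrees are scored against the model
   tree *restricted* to the supertree's leaf set.
3. **Datasets.** `assemble_datasets` builds *clade-based* datasets (a gene
   restricted to a rooted subtree's taxa, mimicking densely sampled studies
   of one clade) and *scaffold* datasets (a sparse sample across the whole
   tree whose size is `scaffold_density` × the covered taxa). The
   `profile_type` is `"mixed"` (several clade datasets plus one scaffold)
   or `"all-scaffold"` (every dataset a sparse scaffold). Scaffold density
   is the experiment's main control variable.
4. **Sequences and estimation.** Sequences evolve under GTR+Γ+I
   (`evolve_sequences`; preset exchangeabilities/frequencies via
   `gtr_preset()`, gamma rate heterogeneity with `alpha = 1`, invariant
   proportion 0.2, default 500 sites). Source trees are estimated from the
   simulated alignments by neighbor joining on maximum-likelihood-style
   corrected distances (`estimate_source_tree`; negative NJ branch lengths
   are clamped to zero since only topologies are used downstream). Setting
   `estimator = "true"` skips sequences and returns the true restricted
   subtrees — useful for clean-recovery checks.

Defaults (`replicates = 1`, `sites = 500`, `n_genes` scaled to `n`) are the
package's own study conditions; experiments scale them up via
`model_condition(..., replicates = )` or the YAML config.

## 3. Quartet encodings (`encode_profile`, `sampled_encoding`)

Every source tree with ≥ 4 taxa induces a quartet topology `a,b|c,d` for
each 4-subset of its leaves. Encodings differ in which quartets they keep:

- **All** (`all_quartets`): every induced quartet of every source tree,
  weights accumulated across trees. Complete but quartic in the tree size.
- **Geo+TSQ / Exp+TSQ** (`sampled_encoding`): every *topologically short
  quartet* (TSQ) is always kept — a TSQ has both its cherries adjacent to
  the two endpoints of a single internal edge, so the TSQ set pins down
  each internal edge with locally reliable, short-distance signal. Each
  remaining quartet with topological diameter `d` (the maximum
  leaf-to-leaf path length in edges among its four taxa) is kept
  independently with probability `d^-3` (Geo) or `1.5^-d` (Exp). Both
  laws downweight long-diameter quartets, which are the ones most likely
  to be wrong in estimated trees; Exp prunes more aggressively.

Note that `d = 3` quartets are always TSQs, so the sampling law only ever
applies at `d ≥ 4`.

## 4. Quartet amalgamation (`maxcut_amalgamate`)

The amalgamation heuristic follows the divide-and-conquer max-cut scheme:
at each level it bipartitions the current taxon set by a randomized,
locally improved max-cut of a quartet-derived objective and recurses on the
two sides, each side carrying an *attachment dummy* taxon standing in for
the rest of the tree. Design choices that matter:

- **Cut objective.** A cut is scored directly by the quartets it resolves:
  `+w` for each quartet whose topology the cut satisfies (both cherries
  separated 2|2 the right way), `−λ·w` for each it violates 2|2 the wrong
  way, `0` for deferred quartets (split 3|1 or 4|0, decided deeper in the
  recursion). The default `λ = 1000` is *near-lexicographic*: any cut that
  violates even one unit of quartet weight scores worse than any
  violation-free cut, so on compatible (noise-free) inputs a violation-free
  cut exists at every level and exact recovery is preserved; on noisy
  inputs the scheme weakly dominated small-λ variants in our experiments.
  Both sides of a cut are required to hold ≥ 2 taxa.
- **Exact small cases.** Subproblems with at most `exact_limit` labels
  (default 7, capped at 9) are solved *exactly* by enumerating all
  unrooted topologies (`phangorn::allTrees`) against cached per-size
  tables of displayed quartets, with ties broken by enumeration order.
  This applies both at the top level and to recursion fragments (the
  attachment dummy is treated as an ordinary label and projected out of
  the winning tree afterwards). The heuristic alone was measurably
  suboptimal on small systems (~6% of random 5-taxon systems); with the
  exact base case the optimizer provably attains the maximum-quartet-
  compatibility optimum whenever the whole instance fits, and small
  fragments never degrade larger runs.
- **Determinism.** `restarts` (default 10) randomized cuts are tried per
  level under a seed-derived substream; the same `seed` always yields the
  same tree. Uncovered taxa (present in `taxa` but in no quartet) are
  attached as a star at the root rather than dropped.

## 5. The MRP pathway (`gmrp`)

`mrp_encode` builds the standard partial binary matrix (one column per
internal edge per source tree; taxa absent from a source tree get `?`).
`fitch_length` scores a topology by Fitch parsimony with missing data.
`ratchet_search` is a parsimony ratchet: alternating rounds of NNI hill
climbing on the original matrix and on a bootstrap-upweighted matrix,
collecting all distinct optimal topologies found. `gmrp` is the greedy
consensus (`greedy_consensus`) of those optima: majority splits first, then
remaining splits by frequency as long as they stay compatible — matching
the usual "greedy MRP" construction.

## 6. Evaluation (`error_rates`, `sum_distance`, `correlation_study`)

For an estimated supertree `T` and true tree `T₀` on the same leaves:
`FN = |Σ(T₀) \ Σ(T)|/|Σ(T₀)|` (missed true edges), `FP` symmetric
(wrong edges in `T`, normalized by `T`'s own internal-edge count, 0 if `T`
is a star), `RF` their mean. `sum_distance(T, profile, kind)` aggregates
the same rates of `T` restricted to each source tree's leaves (default
ratio-of-sums). `run_experiment` runs conditions × methods × replicates
under per-replicate derived seeds; failed replicates stay in the results
table flagged `failed = TRUE` but are excluded whole-replicate from
summaries. `correlation_study` computes, per replicate, the Spearman rank
correlation across methods between each sum-criterion and each true-error
metric, and reports mean/min/max per density; zero-variance replicates are
flagged degenerate and excluded from the aggregates (counted in
`n_degenerate`).

## 7. Problem sizes and limitations

The shipped experiment scale (32 taxa, 10 replicates, NJ estimation,
scaffold densities 20–100%) is chosen so the full benchmark runs in
minutes on one CPU; it is the package's own choice of study size, and all
knobs scale up through `model_condition` and the CLI config. Known
limitations: the ratchet is a heuristic (no optimality guarantee beyond
`exact_limit`-sized instances for the quartet side); the simulator models
nucleotide data only; `correlation_study` needs ≥ 2 methods and tie-free
values for informative ρ; and very low scaffold densities can leave taxa
uncovered, shrinking the evaluable leaf set as described in §2.
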