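# lintree

Maximum-parsimony phylogeny inference for CRISPR/Cas9 single-cell lineage
tracing.

Lineage recorders accumulate heritable Cas9-induced indels at engineered
target sites; sequencing reads them out per cell, giving a character matrix
`M ∈ {0, 1, 2, …, missing}^{n×m}` in which rows are cells, columns are
target-site *characters*, values are indel *states* (0 = uncut) and dropout
leaves missing entries. Because the founder cell is unedited and edited
sites are never re-cut (irreversibility: each character changes at most once
along any lineage, from 0 to a nonzero state), maximum parsimony is a
natural objective and the multi-state problem reduces cleanly to a
perfect-phylogeny-style analysis. `lintree` provides:

* **Reconstruction** — a greedy heuristic that recursively splits cells on
  the most frequent (or, with indel priors `q_ij`, the least likely:
  `argmin_{i,j} q_ij^{n_ij}`) mutation and provably recovers a perfect
  phylogeny when one exists (`build_greedy`); a Steiner-tree integer linear
  program over an inferred "potential graph" of candidate ancestral states
  (`build_potential_graph`, `optimize_neighborhood`, `solve_steiner`,
  exactness-checked against a Dreyfus–Wagner oracle); a hybrid that runs
  greedy to a cell-count cutoff and solves each clade exactly
  (`build_hybrid`); and a neighbor-joining baseline on one-hot binarized
  characters (`build_nj`).
* **Simulation** — a forward lineage simulator with configurable characters,
  states, state distributions, mutation rates, tree depth, subsampling and
  dropout (`simulate_lineage`), perfect-phylogeny and parallel-evolution
  generators (`inject_parallel_evolution`), and base-editor / phased-recorder
  presets.
* **Evaluation** — minimal irreversible ancestral annotation and parsimony
  (`annotate_ancestral_states`, `parsimony_score`), the depth-stratified
  triplets-correct statistic (`triplets_correct`), meta purity and mean
  majority vote for external labels, allelic and phylogenetic distances, and
  character bootstrapping.
* **Theory** — closed-form moments of a mutation's occurrence count X and
  leaf frequency Y under the binary-tree model (`closed_form_moments`), the
  least-squares linear estimate L(X|Y), a Markov-chain simulator
  (`simulate_markov`), and the numerical scan locating the critical mutation
  probability `1 − 1/√2 ≈ 0.29` below which Cov(X, Y) diverges negatively
  with depth (`critical_p_scan`) — the result that justifies splitting on
  frequent mutations.
* **Allele-table utilities** — indel-prior and mutation-rate estimation,
  clone calling from integration-barcode sets, intra-/inter-clone doublet
  detection with simulation-based threshold tuning, and a synthetic
  allele-table generator.

## Worked example

```r
library(lintree)
set.seed(7)

# simulate a lineage-tracing experiment: 20 characters, 20 states,
# 5% cutting rate, 8 generations, 100 sampled cells, 15% dropout
params <- sim_params(num_characters = 20, num_states = 20, p = 0.05,
                     depth = 8, subsample = 100 / 2^8, dropout = 0.15)
exp <- simulate_lineage(params)

# reconstruct with the greedy solver and score against the truth
tree <- build_greedy(exp$observed)
tree <- annotate_ancestral_states(tree, exp$observed)
tc <- triplets_correct(exp$tree, tree, n_triplets = 5000)
cat("parsimony:", parsimony_score(tree), "\n")
cat("triplets correct:", round(tc$thresholded, 3), "\n")
cat("NJ triplets correct:",
    round(triplets_correct(exp$tree, build_nj(exp$observed), 5000)$thresholded, 3), "\n")
cat("estimated mutation rate:",
    round(estimate_mutation_rate(exp$truth, d = 8), 4), "\n")
```

```
parsimony: 214
triplets correct: 0.849
NJ triplets correct: 0.733
estimated mutation rate: 0.0548
```

The greedy tree implies 214 mutation events and orders 84.9% of leaf
triplets as in the true tree (averaged over root-to-LCA depths), against
73.3% for neighbor joining on the same data; the mutation rate recovered
from the saturation curve (0.0548) is close to the generating 0.05. Writing
the tree is `write_newick(tree, "tree.nwk")`; branch lengths are per-edge
mutation counts.

The closed-form theory behind the greedy criterion, at the same cutting
rate:

```r
closed_form_moments(theory_params(p = 0.05, q = 0.5, h = 8))[c("E_X", "E_Y", "Cov_XY")]
#> E_X 9.38   E_Y 0.168   Cov_XY -0.015
```

A mutation of this probability is expected to arise 9.4 times in the tree,
and its count is negatively correlated with its observed frequency — the
more cells carry it, the fewer independent origins it likely had.

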