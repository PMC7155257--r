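---
title: "Maximum-parsimony lineage reconstruction from CRISPR/Cas9 recorders: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-parsimony lineage reconstruction from CRISPR/Cas9 recorders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The data and its constraints

CRISPR/Cas9 lineage recorders accumulate heritable indels at engineered
target sites. Each target site is a phylogenetic *character*; the indel
observed there is its *state*, with 0 the uncut state and a missing marker
for dropout (either heritable — Cas9 resections or silencing — or stochastic
capture failure). The data for $n$ cells and $m$ characters is a character
matrix of integer states. Two design constraints separate this setting from
classical phylogenetics and drive everything in this package:

* the founder cell is unedited (the root state is all zeros), and
* mutations are irreversible — an edited site is never re-cut, so along any
  root-to-leaf path a character changes at most once, from 0 to a nonzero
  state, never back and never sideways.

State labels are namespaced per character: state 3 at character 1 has no
relation to state 3 at character 2.

# Reconstruction

## Greedy perfect-phylogeny heuristic

`build_greedy()` recursively partitions the cells on the (character, state)
mutation carried by the most cells, on the rationale that under realistic
per-generation mutation probabilities a high-frequency mutation most likely
arose once, early. If the matrix admits a perfect phylogeny — every
(character, state) pair arising exactly once — this split is provably safe
and the recursion reconstructs the phylogeny exactly; the package asserts
this property in its test suite on simulated perfect phylogenies.

Cells missing the split character are assigned to the side with which they
share the larger mean fraction of mutated states, computed over characters
observed in both cells. Ties (and cells with no comparable characters) go to
the larger side; split-criterion ties go to the lowest (character, state)
index. Both tie-breaks are arbitrary but deterministic, chosen for
reproducibility.

With per-character priors $q_{ij}$ (the probability of state $j$ given a cut
at character $i$), the split criterion becomes
$\arg\min_{i,j} q_{ij}^{\,n_{ij}}$, evaluated in log space
($n_{ij}\log q_{ij}$) to avoid underflow: a *low-probability* indel at
*high frequency* is the strongest evidence of a single early origin. With
equal priors this reduces exactly to the frequency criterion.

## Steiner-tree integer linear program

`build_potential_graph()` approximates the space of plausible evolutionary
histories: starting from the deduplicated observed cells, every pair of
current source nodes whose edit distance is strictly below a threshold $d$
receives its latest common ancestor (agreement kept, disagreement set to 0,
missing entries acting as wildcards) with edges weighted by the number of
mutations gained; the process repeats until a single source — the root —
remains. `optimize_neighborhood()` raises $d$ from 1 and keeps the largest
graph within a node-count cap (default 10,000), the scalability control.

`solve_steiner()` then finds the minimum-weight subgraph connecting the root
to every observed cell as a network-flow integer linear program: integer
flows $d_{uv} \in \{0..|S|\}$ and binary selections $b_{uv} \ge d_{uv}/|S|$,
minimizing $\sum b_{uv}\,w(u,v)$ subject to flow conservation at
intermediate nodes, $|S|$ units leaving the root and one unit absorbed per
target. Because a flow formulation requires targets to be pure sinks — an
observed cell that is the ancestor of another would otherwise have to relay
flow while absorbing exactly one unit, which the balance equations forbid —
each target is split into a routing node plus a zero-weight sink copy; the
objective is unchanged. Solutions are verified in the test suite against an
independent Dreyfus–Wagner dynamic program (`exact_steiner_oracle()`),
which is exponential in the number of terminals and therefore reserved for
small instances.

The mixed-integer program is solved by HiGHS through a small bundled Python
helper (`scipy.optimize.milp`) behind a thin subprocess interface; time
limit (default 12,600 s) and relative gap are configurable, and a time-limit
hit returns the incumbent flagged as such. Degenerate in-degree ties in the
selected subgraph are broken by smallest incoming weight, then
lexicographically smallest parent string.

Missing data: full exhaustive imputation over all possible indels is
exponential, so missing entries are treated as wildcards in LCA construction
and edit distances (they match any state and contribute zero distance),
while observed leaves keep their missing entries. This is an approximation,
not an inference of the missing states.

## Hybrid

`build_hybrid()` runs the greedy recursion until subsets reach a cell-count
cutoff (default 200, configurable; the benchmark runs here use 50), solves
each stopped subset as an independent Steiner subproblem, and grafts the
subtrees back. Subproblems receive the recursion-time submatrix — split
characters consumed on the greedy path are already zeroed, which fixes the
clade's ancestral string — and results are merged in a manner independent of
execution order. A subproblem's ILP solution is grafted only when it is at
least as parsimonious as the greedy subtree over the same cells, compared on
the *original* submatrix (characters consumed on the path can still vary
within the subset, as a state in some cells and missing in others, and this
affects parsimony); this guards against time-limited incumbents and
guarantees the merged tree is never less parsimonious than pure greedy.

## Neighbor-joining baseline

`build_nj()` one-hot binarizes the matrix, computes identity-mismatch
dissimilarities over pairwise-complete binary columns, appends an all-zero
pseudo-root cell before joining (so the result can be rooted and cut by
depth), and removes it afterwards. This is the distance-based reference
method, not a recommended reconstruction.

# Scoring trees

`annotate_ancestral_states()` labels internal nodes per character with state
$s$ when every non-missing leaf below carries $s$ (all-missing subtrees keep
a wildcard), else 0; a mutation shared by every leaf is charged to the
implicit edge from the unedited founder to the root. Under irreversibility
this yields the minimal number of $0 \to s$ origins — one per maximal
monochromatic subtree — which the tests confirm against exhaustive labeling
on small trees. `parsimony_score()` totals the per-edge mutation counts.

`triplets_correct()` samples leaf triplets (with replacement, 10,000 by
default) and scores one correct when the outgroup leaf agrees between the
true and reconstructed trees. Fractions are stratified by the depth of the
triplet's LCA in the *true* tree — depth measured in unit edges from the
root — and averaged across depths, by default only over depths whose cell
count reaches 20 (the unthresholded average is also reported, and is the
fallback when no depth qualifies). Stratification prevents the abundant
shallow triplets from swamping the deep ones.

`meta_purity()` (a chi-squared statistic on the clade-by-label contingency
table at a horizontal cut yielding a requested number of clades) and
`mean_majority_vote()` (mean majority-label fraction per clade, ranging from
$1/|M|$ to 1) quantify label homogeneity below internal nodes when an
external grouping (e.g., a culture-plate split) is available.
`allelic_distance()` (0/1/2 per character, normalized by $2m$) and
`phylogenetic_distance()` (mutation-weighted path length normalized by the
tree diameter) relate character-space to tree-space similarity.
`bootstrap_characters()` resamples characters with replacement for branch
support; downstream replicate trees should be passed through
`collapse_singles()`.

# The simulator

`simulate_lineage()` grows a full binary tree of $D$ divisions; after each
division every still-uncut character of each daughter mutates independently
with probability $p$, drawing its state from a per-character distribution;
$\mathrm{round}(2^D M)$ leaves are sampled uniformly without replacement and
dropout masks each character of each sampled cell independently at
per-character rates. The defaults are the package's reference regime: 40
characters, 40 states, $D = 11$, $p = 0.025$, mean dropout 17% and 400
sampled cells. Per-character dropout rates are drawn from a Beta
distribution with mean 0.17 (concentration 10), since only the mean rate is
specified by the regime. The expected mutated fraction per cell is
$1-(1-p)^D \approx 0.24$, which the tests verify by Monte Carlo.

Per-state probabilities come from a mixture
$\theta\,\mathrm{Unif}(0,1) + (1-\theta)\,F$, normalized to sum to $p$.
The skewed component $F$ is a negative-binomial-shaped discrete family
(NB(5, 0.5) mass over the states, shuffled and jittered); empirical indel
spectra are strongly skewed, with a few indels dominating, and the
base-editor preset uses exactly this NB model. The default is $\theta = 0$
(fully skewed). A spline fit to a particular experiment's indel frequencies
would require that dataset; the NB surrogate reproduces the qualitative
skew, and $\theta$ exposes the skew-to-uniform axis that matters for
information-capacity questions.

Perfect-phylogeny mode (`unique_states = TRUE`) replaces the Bernoulli
process: each daughter edge at each division receives exactly one mutation,
in a uniformly chosen character not yet mutated along that lineage, with a
globally novel state. Two properties follow: the matrix always admits a
perfect phylogeny, and every division is identifiable from the data. The
second property is deliberate. Under Bernoulli mutation some internal edges
of the true tree carry no mutation, the truth is then not identifiable from
the matrix, and no algorithm could score perfectly against it — exactness
tests of the greedy solver would be meaningless. `inject_parallel_evolution()`
starts from such a base and plants $k$ identical fresh-character mutations
on two grandchild branches of a depth-$d$ node each, producing "near
perfect phylogenies" with controlled homoplasy.

`preset_base_editor()` (characters × states held at 400, $p = 1.04\%$, 10%
dropout, depth 10) and `preset_phased_recorder()` (50 characters in blocks
of five with rates $p_0(1 + e_j \lfloor i/5 \rfloor)$, $i = 1..50$, so the
max/min rate ratio is $1 + 10 e_j$) encode the two alternative-technology
regimes.

What the simulator does *not* emulate: cell death and asynchronous division,
heritable (clade-correlated) dropout — masking is i.i.d. per entry —
sequence-level artifacts upstream of allele calling, and doublets (those are
injected separately at the allele-table level). Passing tests on simulated
data therefore demonstrate correctness of the algorithms under the stated
generative model, not performance on any particular real dataset.

# Parallel-evolution theory

For one character and one state, let $p$ be the per-generation mutation
probability, $q$ the conditional state probability, $h$ the tree height,
$X$ the number of times the mutation occurs in the tree and $Y$ the fraction
of leaves carrying it. Mutation happens after division, so an edge into a
depth-$t$ node mutates with probability $pq(1-p)^{t-1}$ and fixes
$2^{h-t}$ of the $2^h$ leaves. In chain form ($N_1 = 1$ unmutated cell,
$A_t \sim \mathrm{Bin}(2N_t, p)$, $B_t \sim \mathrm{Bin}(A_t, q)$,
$N_{t+1} = 2N_t - A_t$): $X = \sum_t B_t$ and $Y = \sum_t 2^{-t} B_t$.
The $2^{-t}$ weight is fixed by exhaustive enumeration at small $h$ against
$E(Y) = q(1-(1-p)^h)$ — a generation-$t$ event covers $2^{h-t}$ leaves.

`closed_form_moments()` returns $E(X) = 2pq((2-2p)^h-1)/(1-2p)$ (limit
$2pqh$ at $p = 0.5$, branch taken within $10^{-9}$ of the singular point),
$E(Y)$, a closed-form variance bound for $X$, and $E(XY)$, $\mathrm{Cov}(X,Y)$,
$\mathrm{Var}(Y)$, $\mathrm{Var}(X)$ from exact moment recursions on the
chain ($E N_t$, $\mathrm{Var}\,N_t$, and the covariances of the $B_t$).
Two numerical points deserve note. First, covariances of the $B_t$ are
computed directly rather than as differences of product moments, whose
common $(2-2p)^{s+t}$ leading terms would swamp the result. Second,
$\mathrm{Cov}(X,Y)$ contains a $(2-2p)^h$ component whose coefficient
vanishes exactly in the infinite sum; the implementation evaluates that
block through the closed-form tail of the vanishing series, leaving the true
$(2(1-p)^2)^h$ behavior. Everything is validated against exhaustive
enumeration at $h \le 4$ and Monte Carlo at larger $h$.

The punchline is the sign and growth of $\mathrm{Cov}(X,Y)$: for
$p < 1 - 1/\sqrt{2} \approx 0.29$ the covariance diverges to $-\infty$
with $h$ — frequent mutations occurred *fewer* times — which is the
theoretical justification of the greedy split. `critical_p_scan()` finds
this boundary numerically, distinguishing divergence from saturation by a
geometric-growth test (consecutive-height magnitude ratios above 1.05,
negative covariance) at heights 40–200; plain monotonicity cannot separate
the two, because above the boundary the covariance also grows while
approaching its constant limit. `llse_x_given_y()` gives the least-squares
linear estimate $L(X\mid Y)$.

# Allele-table utilities

Upstream of the character matrix, an allele table records per (cell,
integration barcode) the called allele and its UMI count. The package takes
this table as its contract boundary (UMI collapsing and read filtering are
upstream concerns) and implements:

* `estimate_indel_priors()`: $q_s = f(s)/|I|$, the fraction of integration
  barcodes in which indel $s$ was seen in at least one cell.
* `estimate_mutation_rate()`: inverts the saturation curve
  $K/n = 1-(1-p)^{\,d}$ to $p = 1-(1-K/n)^{1/d}$, where $K$ is the mean
  number of mutated characters per cell over $d$ generations. (Note the
  $1/d$ exponent: it is the algebraic inverse of the saturation curve and is
  confirmed by parameter recovery in simulation.) A single 400-cell
  replicate carries roughly 10% relative spread because cells share
  ancestry, so accuracy checks average over replicates.
* `call_clones()`: iteratively assigns all cells carrying the currently
  most-shared integration barcode to a new clone until at most 0.5% of cells
  remain (the "junk" clone), then drops intBCs below 10% prevalence within
  each clone.
* `detect_doublets()`: intra-clone score = fraction of a cell's UMIs on
  non-plurality alleles of their intBC; inter-clone score = prevalence-
  weighted clone membership $m'_{i,k}$, normalized to sum to one per cell.
* `simulate_doublets()` and `tune_doublet_threshold()`: inject labeled
  synthetic doublets (union of two cells' rows; same-clone or cross-clone
  parents) and grid-search the decision rule over 0, 0.05, …, 1.0 by
  F-measure.
* `simulate_allele_table()`: a generator with known clone structure,
  configurable intBC leakage, detection dropout and log-normal-ish UMI
  counts, so every operation above is testable against generating truth.

# Problem sizes, determinism, degenerate inputs

All randomness flows through R's RNG — set one seed and every stage
(simulation, triplet sampling, bootstrapping) is reproducible; the only
caveat is the MILP backend, whose incumbent at a time limit is recorded with
its status and gap. The packaged benchmarks run at the reference regime with
5 replicates for the neighborhood-threshold stability check, 10 replicates
for the method-ordering comparison (hybrid cutoff 50, 3 s per subproblem,
5% gap), 50 replicates for perfect-phylogeny recovery, 20 random instances
for ILP-versus-oracle exactness, and $10^5$ Monte-Carlo replicates for the
theory checks; these sizes keep the full suite to roughly ten minutes while
leaving Monte-Carlo error well inside the asserted tolerances.

Degenerate inputs are defined behavior: a single cell yields a single-leaf
tree; a subset with no informative mutation becomes a polytomy; a character
matrix with no nonzero state binarizes to zero columns; an all-zero cell
coinciding with the root is attached directly beneath it; saturated
mutation-rate estimation ($K = n$) returns 1 with a warning; and the
neighborhood optimizer falls back to the star graph (d = 0) with a warning
when even $d = 1$ exceeds the cap.

# Known limitations

The potential graph is an approximation whose quality degrades under tight
node caps; with small caps and short time limits the ILP rarely improves on
greedy subtrees (the hybrid then simply equals greedy, by the fallback
rule). Missing data is wildcarded, not modeled; heritable and stochastic
dropout are not distinguished. The greedy tie-breaks are conventions, and
alternative prior link functions beyond $f(n) = n$ are not implemented.
Branch lengths are mutation counts, not time.
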