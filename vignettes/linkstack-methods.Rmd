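---
title: "Topological link prediction with feature elimination and stacking: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological link prediction with feature elimination and stacking: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkstack)
```

## The problem

Link prediction asks which node pairs of an observed, undirected,
unweighted network are most likely to be (or become) connected. linkstack
treats this as supervised binary classification: every candidate pair gets
a vector of topological similarity scores as features and a 0/1 label for
edge existence. The package implements the full protocol — feature
construction, balanced dataset assembly, random-forest-driven recursive
feature elimination (RF-RFE), and a two-level stacking ensemble (SELLP:
stacking ensemble learning for link prediction) — together with
similarity-only baselines and a statistical comparison layer.

## The twelve similarity indices

For nodes $v_i$ with neighbour set $\Gamma(i)$ and degree $k_i$, with $A$
the adjacency matrix, $L = D - A$ the Laplacian, $L^+$ its Moore–Penrose
pseudoinverse, and $P$ the row-stochastic transition matrix
$P_{ij} = A_{ij}/k_i$:

| # | Index | Definition | Range of information |
|---|-------|------------|----------------------|
| 1 | CN  | $|\Gamma(i)\cap\Gamma(j)|$ | local |
| 2 | PA  | $k_i k_j$ | local |
| 3 | AA  | $\sum_{l\in\Gamma(i)\cap\Gamma(j)} 1/\log k_l$ | local |
| 4 | LHN | $|\Gamma(i)\cap\Gamma(j)|/(k_i k_j)$ | local |
| 5 | RA  | $\sum_{l\in\Gamma(i)\cap\Gamma(j)} 1/k_l$ | local |
| 6 | ACT | $1/(l^+_{ii}+l^+_{jj}-2l^+_{ij})$ | global |
| 7 | MFI | $[(I+\alpha L)^{-1}]_{ij}$ | global |
| 8 | RWR | $\pi_i(j)+\pi_j(i)$, $\pi_i = c P^\top \pi_i + (1-c)e_i$ | global |
| 9 | SimRank | fixed point of $s_{ij} = \frac{C}{k_i k_j}\sum_{a\in\Gamma(i)}\sum_{b\in\Gamma(j)} s_{ab}$, $s_{vv}=1$ | global |
| 10 | LP  | $[A^2 + \alpha_{LP} A^3]_{ij}$ | quasi-local |
| 11 | LRW | $q_i \pi_i(j)(t) + q_j \pi_j(i)(t)$, $\pi_i(t{+}1)=P^\top\pi_i(t)$ | quasi-local |
| 12 | SRW | $\sum_{\tau=1}^{t} S_{LRW}(\tau)$ | quasi-local |

This ordering is canonical throughout the package: feature columns,
elimination orders and selected subsets all refer to it
(`index_names()`).

### Tunable parameters

All index parameters live in `index_params()`:

* `aa_log_base` (default natural log). The AA weight is sometimes written
  with $\lg$; any fixed base rescales all scores by a constant and leaves
  every ranking unchanged, so we default to the canonical natural-log form
  and expose the base.
* `mfi_alpha` (default 1): the classical matrix-forest index; any
  positive value is valid.
* `rwr_restart_c` (default 0.85): continuation probability of the
  restarting walk — the PageRank-family convention. The stationary
  distribution is obtained by an exact linear solve rather than truncated
  iteration; at desk scale the dense solve is both faster and more
  accurate.
* `simrank_decay_C` (default 0.8), `simrank_tol` ($10^{-4}$),
  `simrank_max_iter` (100): the decay and stopping rule of the SimRank
  fixed-point iteration, started from the identity. The iterate is
  entrywise non-decreasing and bounded by 1, so the stopping rule is safe;
  non-convergence (never observed on test graphs) returns the last iterate
  with a warning.
* `lp_alpha` (default 0.001): the standard weight of length-3 paths.
* `walk_steps_t` (default 3): LRW/SRW horizon. The initial resource
  $q_v = k_v/(2M)$ follows the original formulation of the index.

Isolated nodes are retained; every index scores a pair involving an
isolated node as 0 (no neighbours, no walks), and for the commute-time
index the zero is imposed explicitly since the pseudoinverse alone would
still produce a finite value. Cross-component pairs keep their
pseudoinverse-based ACT value; walk-based scores across components are
exactly 0.

## Dataset protocol

Positives are *all* $M$ edges; negatives are a uniform sample of $M$
non-edges (balanced 1:1, as appropriate for sparse networks). Both classes
are split by `train_fraction` (default 0.9; 0.8 probes robustness) into
train and test roles, so balance holds within each role. All similarity
matrices are computed on the **training graph** — the network with the
test positives removed — for train and test rows alike; otherwise global
indices would walk across the very links being predicted.

### Why features are leave-one-out

One asymmetry remains after removing test positives: a training positive
is still an edge of the training graph, so walk-based indices evaluated at
that pair would see the pair's own edge. The effect is drastic, not
subtle: the first-order term of RWR/LRW/SRW essentially encodes "already
connected", tree learners separate the training rows perfectly on it, and
the learned rule transfers to held-out pairs (whose edges are absent by
construction) as a constant prediction. We therefore evaluate every pair's
features on the training graph *minus that pair's own edge* when present.
Only training positives are affected; train and test rows become
exchangeable.

The corrections are exact closed forms or low-rank updates, not
recomputations: degrees drop by one for PA/LHN; CN, AA and RA are
unchanged (removing an edge neither changes the common-neighbour set nor
those neighbours' degrees); the length-3 path count obeys
$[A'^3]_{ij} = [A^3]_{ij} - k_i - k_j + 1$; MFI uses a Sherman–Morrison
update of $(I+\alpha L)^{-1}$; ACT reduces to the effective-resistance
identity — with $r = l^+_{ii}+l^+_{jj}-2l^+_{ij}$, the commute denominator
on the reduced graph equals $r/(1-r)$ — falling back to a direct
pseudoinverse when the edge is a bridge ($r \to 1$); RWR uses a rank-2
Woodbury update (two transition rows change); LRW/SRW re-propagate the two
affected sources under the corrected rows. SimRank has no exact low-rank
update (its fixed point depends globally on the edge), so we apply one
step of the SimRank operator of the reduced graph to the converged
unreduced solution; the residual error is second-order (observed below
$10^{-2}$ on random graphs) and this is the one approximate entry in the
feature table.

Each of the `n_runs` (default 10) independent runs re-samples the split
and negatives with seed `master_seed + r` and recomputes the similarity
matrices on its own training graph — self-contained, fully reproducible
runs. A `freeze_selection` switch reuses run 1's feature subset when a
single shared subset is preferred.

## Feature selection: RF-RFE

A random forest scores each feature by Gini variable importance: the total
sample-weighted impurity decrease, $GI(t) = 1 - \sum_c p_{tc}^2$, summed
over a feature's split nodes and all trees, then normalised to sum to 1.
(The textbook formula omits the sample weights; we use the sample-weighted
form that forest implementations actually compute — only the elimination
*order* matters downstream.) The forest engine is ranger with 100 trees by
default, single-threaded for determinism.

Elimination removes the single lowest-importance feature per round until
one remains. Every nested subset size $s$ is then scored by
cross-validated accuracy,
$CVS = \frac{1}{K}\sum_k p_k$ with $K = 5$ stratified folds, repeated
`n_repeats` times with re-randomised folds and forest seeds (both
re-randomised, since only re-randomising folds would understate forest
variance). The selected subset is the argmax of the CVS curve, ties broken
toward the *smaller* size — the goal is as few features as possible. The
scoring classifier is the same random forest as the importance engine, for
coherence. RFE sees training rows only; test rows never influence
selection.

## The stacking ensemble (SELLP)

Level one holds three deliberately heterogeneous base learners:

* **LR** — ridge-regularised logistic regression (glmnet, $\alpha = 0$),
  regularisation strength grid $\{0.01, 0.1, 1, 10\}$;
* **GBDT** — classical gradient-boosted trees: the boosting engine run
  without leaf-weight regularisation ($\lambda = \alpha = 0$, full
  row/column sampling);
* **XGBoost** — the same engine with its default second-order
  regularisation. Tree grids default to
  $\{50,100,200\}\times\{2,3,5\}\times\{0.05,0.1,0.3\}$
  (rounds × depth × learning rate).

The training table is split into $K = 5$ stratified folds. Each learner is
fitted once per fold on the complement ($3 \times 5 = 15$ base models);
hyperparameters are resolved per fold-model by grid search with an
internal 3-fold CV on that fold-model's own training partition, so tuning
never touches the held-out fold. Each model predicts positive-class
*probabilities* on its held-out fold; every training row is predicted
exactly once per learner, and the collected out-of-fold triples
$(\hat y_1, \hat y_2, \hat y_3, y)$ train the level-two fuse model (an
XGBoost classifier on the three meta-features only — no passthrough of the
original features). At test time each learner's five fold-models predict
and are averaged before fusing. Stratified folds are the default because
balanced data with small folds risks single-class partitions under plain
random assignment; a config switch restores plain random. `tune = FALSE`
replaces grid search with fixed mid-grid parameters — the fast path used
for small simulation studies.

## Evaluation

Accuracy, precision, recall and F1 come from the confusion counts at a
0.5 threshold on the fused probability (zero denominators report 0 with a
warning). AUC uses the rank form
$(S_0 - n_0(n_0+1)/2)/(n_0 n_1)$, where $S_0$ sums the positives' ranks in
the ascending-score list; midranks for ties make it the standard
concordance probability. Similarity-only baselines are threshold-free for
AUC; their classification metrics threshold at the median score of the
evaluated pool (balanced data then yields balanced predictions) — a
package convention, documented because no standard exists.

The matching score $\sigma$ ranks a candidate pool by an index and reports
the fraction of observed edges recovered in the top $|E|$ candidates;
ties break by a fixed pair ordering, so $\sigma$ is deterministic and
invariant under strictly monotone transforms of the scores. Multi-run
comparison follows a two-stage recipe at $\alpha = 0.05$: an F-test of
variance equality decides between the equal-variance and Welch t-tests,
and the 95% confidence interval of the mean difference comes from the
chosen test.

## Synthetic networks and what passing tests show

`generate_synthetic()` provides Erdős–Rényi, Barabási–Albert,
Watts–Strogatz and stochastic-block graphs (igraph generators, seeded,
bitwise reproducible). The benchmark fixture used by the package's
acceptance checks and by `scripts/acceptance.R` is a two-block planted
partition (2 × 100 nodes, within-block probability 0.15, between-block
0.01, ten runs at a 90% training fraction) — small enough to run minutes
on one core, structured enough that neighbourhood-based indices carry real
signal. Simulation studies in the test suite use reduced settings (one
CVS repetition, 50-tree forests, single-point hyperparameter grids);
these are runtime choices, stated here so results are interpreted at the
right scale.

Planted-partition graphs emulate community structure with homogeneous
degrees. They do not emulate heavy-tailed degree distributions, local
clustering beyond what blocks induce, degree assortativity, or the
hierarchical sparsity of infrastructure networks — so passing these checks
demonstrates the machinery is correct and the protocol leakage-free, not
that the method's ranking of real networks is reproduced. Real networks
are supplied as edge lists and run through the identical pipeline.

## Numerical choices and degenerate inputs

* Commute-time denominators at or below `linear_solve_tol` ($10^{-10}$)
  return score 0 with a warning.
* $(I+\alpha L)$ is positive definite for $\alpha > 0$; the MFI solve
  cannot fail.
* RWR solutions are validated as probability vectors (non-negative, sum
  1 within $10^{-8}$); isolated sources return the zero vector.
* Ties: lowest-VIM elimination takes the first-listed feature; CVS
  argmax takes the smallest size; matching-score ranking uses pair order.
* Empty pair rosters, empty-edge networks and constant features are legal
  inputs with defined outputs (empty tables with full column contracts,
  roster-only edge-list files, zero importance).
* All randomness flows from explicit seeds through a single derivation
  helper; nothing reads global RNG state implicitly. Learner engines run
  single-threaded, making reports bitwise reproducible.

## Known limitations

* Dense matrix algebra throughout: fine to a few thousand nodes,
  not intended for large graphs (no sparse/approximate solvers).
* The SimRank leave-one-out entry is a one-step approximation (above).
* The similarity-baseline threshold convention (median score) affects
  accuracy/precision/F1 of baselines, not AUC; comparisons against
  baselines should lean on AUC.
* No calibration of fused probabilities, no degree-matched negative
  sampling, no temporal splits, no multigraph/bipartite support.
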