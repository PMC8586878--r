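---
title: "Methods: sparse k-means clustering of count data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse k-means clustering of count data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(sparsekm)
```

# The problem

Single-cell RNA-seq experiments produce a cells-by-genes matrix of
nonnegative integer counts that is extremely sparse: most genes are not
observed in most cells.  k-means clustering of such data faces two
obstacles.  First, the natural dissimilarities for count data are
probability-distribution divergences (Kullback–Leibler, Jensen–Shannon,
Bhattacharyya), which are infinite or undefined when either cell has a zero
where the other does not.  Second, repairing those zeros with a pseudo-count
makes the matrix dense, which destroys the memory and time advantage of the
sparse representation.  `sparsekm` resolves both: a Gamma(β, β) pseudo-count
prior gives every gene positive mass, and it is applied *lazily*, so that
each distance is still computed in time proportional to the number of
stored entries (`nnz`) rather than the number of genes (`d`).

# Dissimilarity measures and the lazy prior

Rows are observations.  With `S = Σ_i X_i` the row total, the
prior-adjusted probability vector of a row is

$$\hat X_i = \frac{X_i + \beta}{S + d\beta},$$

so every zero gene takes the shared *background* value `β / (S + dβ)`.  The
five supported measures are

| measure  | formula | operates on |
|----------|---------|-------------|
| `SQE`    | $\sum_i (X_i - Y_i)^2$ | raw counts |
| `KLD`    | $\sum_i \hat X_i \log(\hat X_i / \hat Y_i)$ | prior-adjusted |
| `JSD`    | $\tfrac12 [\mathrm{KLD}(\hat X, M) + \mathrm{KLD}(\hat Y, M)]$, $M = (\hat X + \hat Y)/2$ | prior-adjusted |
| `BATMET` | $\sqrt{1 - \sum_i \sqrt{\hat X_i \hat Y_i}}$ | prior-adjusted |
| `COS`    | $1 - x \cdot y / (\lVert x\rVert\,\lVert y\rVert)$ | raw counts |

All logarithms are natural, so `JSD` is bounded by `log 2 ≈ 0.693`; this is
the standard convention in the Bregman-divergence literature that motivates
extending k-means++ beyond squared Euclidean distance.  `BATMET` is the
Bhattacharyya *metric* `sqrt(1 - BC)` built from the Bhattacharyya
coefficient `BC = Σ sqrt(p q)`; it satisfies the triangle inequality (as
does `sqrt(JSD)`), which the test suite spot-checks on thousands of random
triples.  `SQE` and `COS` ignore the prior: the prior exists to repair
zeros for probability measures, and cosine distance is well defined without
it.

The key computational identity is that for two rows the `d − |supp(x) ∪
supp(y)|` genes where *both* are zero all contribute the same term, a
function of the two scalar backgrounds only.  Their total contribution is a
single closed-form aggregate, so a pairwise distance needs the union
support plus O(1) extra work.  `count_touches()` exposes an entry-touch
counter that the tests use to verify the O(nnz) contract at `d = 100000`.

Point-to-center evaluation stores the `k` centers densely in the measure's
working representation (raw counts for `SQE`, probability vectors for
`KLD`/`JSD`/`BATMET`, unit vectors for `COS`).  For `SQE`, `COS`, `KLD` and
`BATMET` the full `n × k` cost matrix reduces to one sparse–dense matrix
product plus per-center aggregates (sum, log-sum or sqrt-sum of the center
entries), keeping the per-row work proportional to that row's support.  The
`JSD` mixture term `Σ_j (\hat x_j + c_j)\log(\hat x_j + c_j)` does not
factor this way: its off-support part depends jointly on the row's
background and the whole center.  We evaluate it exactly by grouping rows
that share a background value (rows with equal totals), computing one O(d)
aggregate per (group, center) pair, and adding an O(nnz) support
correction.  With the common case of equal-depth or few distinct row
totals this stays near O(nnz); in the worst case JSD center evaluation is
O(n·k·d) while remaining exact.

Degenerate inputs are never silently absorbed: a zero-sum row under
`prior = NULL` is an error for probability measures (its distribution is
undefined), an all-zero row is an error for `COS`, and `β ≤ 0` is a
configuration error.  Under an active prior an all-zero row is the uniform
distribution, which is well defined.

# The sampling kernel

k-means++ and localsearch++ both need weighted sampling without
replacement from the per-row cost array.  `sparsekm` uses exponential
random keys: item `i` gets `key_i = -log(u_i)/w_i`, and the `m` smallest
keys are exactly a sequential weighted draw without replacement.  The log
form is preferred over the equivalent `u^(1/w)` ordering for numerical
stability with small weights.  Zero-weight items (points that coincide
with a center) receive `+Inf` keys rather than being filtered, preserving
index alignment.  Partial samples built over disjoint index ranges merge
exactly (`merge_weighted_samples()`), because the top-`m` by independent
keys commutes with concatenation; `substream_seed()` derives reproducible
per-range streams so a partitioned run gives identical output regardless
of how many workers execute the ranges.  The selection of the `m` smallest
keys is done with a partial sort; a bounded heap would be equivalent
observable behaviour.

The test suite validates the kernel *exactly*: for small weight vectors it
enumerates every ordered sequence of draws to get the true subset law and
compares empirical frequencies over 2·10⁵ replicates by chi-square at
α = 0.01.

# Seeding and refinement

`kmeanspp()` picks the first center uniformly and each later center with
probability proportional to the current cost (distance to the nearest
chosen center), which carries the classical O(log k) expected
approximation guarantee — for squared Euclidean and, more generally, for
Bregman divergences.  With `n_candidates > 1` each step draws several
candidates and keeps the one minimizing the resulting total cost (greedy
k-means++).  The default is `1 + floor(log2 k)`, a common greedy choice;
set `n_candidates = 1` for the textbook algorithm.  The per-point cost
array is updated by elementwise minimum, so it is monotone nonincreasing
by construction.

`localsearchpp()` refines the seeds: each round samples one candidate row
`z` proportional to cost, evaluates for every center `c` the exact
objective of swapping `c` for `z` (using each point's best and second-best
center costs, so a round is O(n·k) with no approximation), and applies the
best swap only if it *strictly* lowers the objective.  Strict-improvement
acceptance guarantees the nonincreasing-cost invariant and termination;
ties are rejected.  One candidate is sampled per round.

# Optimization

`lloyd()` alternates nearest-center assignment (ties to the lowest center
index) with recomputing each center as the arithmetic mean of its members'
working representations.  For Bregman divergences (SQE, KLD) the mean is
the exact minimizer of the within-cluster sum, so the objective trace is
provably nonincreasing and is asserted in tests; for JSD/BATMET the mean
is the standard practical surrogate and the trace is recorded but not
guaranteed monotone.  COS centers are re-normalized after averaging.
Empty clusters are reseeded deterministically to the row with the largest
current cost.  Convergence: relative cost change below `tol` (default
`1e-4`), an assignment fixed point, or `max_iter` (default 100).

`minibatch_kmeans()` draws uniform batches (without replacement within a
batch), assigns the batch, and moves each touched center with the
streaming-mean rule `η_c = 1/N_c`, `N_c` the cumulative count of batch
points ever assigned to `c`.  Uniform (not importance-weighted) batch
sampling is used.  With `batch_size = n` one epoch telescopes to exactly
one Lloyd update, which the tests assert to machine precision.  The
full-data objective is evaluated at each epoch end; mini-batch cost is not
monotone step-by-step, so only the median trend over seeds is asserted.

# Defaults

| parameter | default | units / meaning |
|---|---|---|
| `prior` (β) | 0.01 | pseudo-counts per gene; `1` = Dirichlet/Laplace |
| `hvg` | 0 (function), 500 (CLI) | most-variable genes kept |
| `n_candidates` | `1 + floor(log2 k)` | k-means++ candidates per step |
| `ls_rounds` | 25 | localsearch++ rounds |
| `batch_size` | 1024 (function), 10000 (CLI) | rows per mini-batch |
| `max_iter` / `tol` | 100 / 1e-4 | Lloyd cap / relative cost change |
| `max_epochs` | 10 | mini-batch passes |

The CLI defaults (`k = 25`, batch 10000, prior 0.01, 25 rounds, HVG 500)
are tuned for atlas-scale inputs so the documented pipeline is one
flag-free command; the function defaults are sized for interactive use.
Highly-variable genes are ranked by the per-gene population variance of
raw counts, computed sparse-aware as `E[X²] − E[X]²`, ties to the lower
column index.  Variance is a deliberately simple, oracle-checkable choice;
more elaborate dispersion scores can be slotted in at the same interface.

# The synthetic generator

`generate_mixture()` plants `k` clusters with Dirichlet(α)-drawn
gene-probability profiles and draws each cell multinomially at a fixed or
log-normal depth.  Defaults — α = 0.05, 500 counts per cell, fixed depth —
give peaked, well-separated profiles typical of distinct cell types at a
realistic post-HVG depth, and make recovery difficulty monotone in α
(asserted in tests).  `disjoint = TRUE` assigns disjoint gene blocks, the
maximally separated case where exact recovery is forced; an optional
Dirichlet-multinomial mode adds per-cell overdispersion.  The generator
deliberately does *not* simulate doublets, ambient RNA, batch effects or
gene–gene correlation: passing recovery tests on these fixtures
demonstrates the correctness of the optimization stack, not robustness to
real scRNA-seq artefacts.

```{r example}
sim <- generate_mixture(mixture_spec(n_per_cluster = 40, n_genes = 120,
                                     k = 4, seed = 7))
fit <- sparse_kmeans(sim$matrix, k = 4, measure = "KLD", hvg = 60, seed = 1)
fit
adjusted_rand_index(fit$cluster, sim$labels)
```

# Numerical choices

* 0·log 0 is evaluated as 0 everywhere; `KLD` with no prior and a zero in
  the second argument's support is `+Inf` by the mathematics, not an error.
* `BATMET` clamps `1 − BC` at zero before the square root: for identical
  rows floating summation can leave `BC = 1 ± 1e-16`, and the square root
  amplifies that to ~1e-8, which is why zero-distance assertions on BATMET
  use 1e-6 tolerances.
* Assignment ties always break toward the lowest center index; swap ties in
  localsearch++ are rejected.  Both rules make runs bit-reproducible for a
  fixed seed.
* Internal indices are 0-based half-open (CSR convention); Matrix Market's
  1-based indices are converted only at the I/O boundary.
* Counts are stored as given (integer or real flag retained); all
  divergence arithmetic is double precision.

# Validation scales

The suite validates at sizes chosen to make exhaustive oracles feasible:
dense-oracle distance sweeps up to `d = 10⁵`; sampling exactness on ≤6-atom
weight vectors with 2·10⁵ replicates; the k-means++ bound on 40
one-dimensional points, where the optimal 3-means cost is exhaustively
enumerable over contiguous splits of the sorted values; localsearch++
against brute-force best-swap evaluation on 18-point instances; mini-batch
versus Lloyd on a 2000×200 five-cluster mixture over 20 seeds; and the full
pipeline on 600×400 mixtures.

# Limitations

* JSD center evaluation is exact but only near-O(nnz) when row totals
  repeat (see above).
* Lloyd monotonicity is asserted only for Bregman measures; JSD/BATMET
  traces can in principle tick upward after a center update.
* The Itakura–Saito divergence and importance-sampled (gradient-descent)
  mini-batch variants are not implemented.
* Memory-mapped backing for out-of-core matrices is not provided; matrices
  must fit in RAM in CSR form.
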