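---
title: "Methods: penalized-likelihood screening of fossil calibrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: penalized-likelihood screening of fossil calibrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the numerical choices, and the
known limitations of `fossilsieve`. The package README covers the workflow;
this document covers *why* each stage is built the way it is.

## 1. The problem

Bayesian divergence dating is only as good as its fossil calibrations. A
single misidentified or misassigned fossil that implies a much older minimum
age than the true node age can drag an entire chronogram toward the past.
`fossilsieve` implements a screening protocol: every candidate fossil is used
*alone* to date the tree, the resulting single-fossil chronograms are compared
at a small set of reference nodes, and fossils whose implied ages are
interquartile outliers are culled before any joint analysis.

## 2. Penalized-likelihood dating

### 2.1 Model

The input is a rooted maximum-likelihood phylogram with branch lengths in
expected substitutions per site, plus the alignment length `L`. For branch
`j`, the expected number of substitutions is `x_j = b_j * L`, modelled as
Poisson with mean `r_j * t_j`, where `r_j` is the branch's substitution rate
and `t_j` its duration in millions of years. Up to constants in the data the
log-likelihood is

```
sum_j [ x_j * log(r_j * t_j) - r_j * t_j ]
```

Rates and times are not separately identifiable from a single branch, so the
likelihood is penalized for rate heterogeneity (Sanderson's
penalized-likelihood idea): the objective maximized by `pl_chronogram_fit()`
is

```
Phi(t, r) = loglik(t, r) - lambda * [ sum_{j: non-root} (r_j - r_parent(j))^2
                                      + Var(r over root-adjacent branches) ]
```

The penalty is quadratic in the rates. Large `lambda` forces a strict clock;
small `lambda` lets every branch float. `cross_validate_lambda()` scores a
grid of `lambda` values by branch-wise cross-validation (refit with one
terminal branch removed, score the held-out branch's Poisson deviance) and is
the recommended way to choose `lambda` when the data are informative enough.

### 2.2 Parameterization and feasibility

Node ages must satisfy two kinds of constraints: every parent is older than
its children, and calibrated nodes must lie inside their `[min_age, max_age]`
windows. `pl_problem()` intersects these constraints by propagating bounds up
(a node is at least as old as the oldest minimum below it) and down (at most
as old as the smallest maximum above it), and fails loudly if the set is
empty (`infeasible`) or unbounded above (`unidentifiable`: at least one
calibration must have a finite maximum, otherwise only rate*time is
identified).

Internally the optimizer works in an unconstrained parameterization: nodes
are visited in preorder and each free node age is written as

```
age = lower + plogis(u) * (upper - lower)
```

where `lower`/`upper` are the node's *current* feasible interval given the
ages already assigned to its ancestors. Point calibrations (`min == max`)
are fixed and carry no parameter. Rates are parameterized on the log scale.
The gradient of the objective is computed analytically, including the
backpropagation through the sequential transform, and is verified against
central finite differences in the test suite. Optimization uses `optim`
BFGS with multiple restarts (`restarts`) from perturbed clock-heuristic
starting points; the clock heuristic initializes ages from a strict-clock
scaling of the phylogram's root-to-tip depths, which is exact for noiseless
clock-like data and a good basin for relaxed data.

### 2.3 Numerical choices

* Zero-duration branches with positive counts give `-Inf` objective; the
  transform keeps durations strictly positive during optimization.
* The profile of the objective over rates at fixed ages is strictly concave
  (Poisson likelihood plus a quadratic penalty), which is what makes the
  exhaustive grid-search oracle used in the acceptance tests feasible.
* With noiseless input (`alignment_length = Inf` in the simulator) the
  phylogram branch lengths are treated as exact expectations; recovery of
  the generating ages is then limited only by optimizer convergence
  tolerances, and is verified to be within 1% in the tests.

## 3. The screening protocol

`screen_fossils()` implements the protocol end to end:

1. **Per-fossil dating.** Every `ASSIGNED` registry record is converted to a
   single calibration (its `min_age`/`max_age` at its assigned node, plus a
   root maximum to keep the problem identifiable) and the tree is dated with
   `pl_chronogram_fit()`. Failures are recorded as `RUN_FAILED`, never
   silently dropped.
2. **IQR culling.** At each of (typically three) *reference nodes* the
   implied ages are collected across all successful runs, and `iqr_bounds()`
   computes the first and third quartiles. A fossil is excluded if its
   implied age falls strictly outside `[Q1, Q3]` at *any* reference node;
   values exactly on a quartile are kept (inclusive bounds). Two quantile
   rules are provided: `"linear"` (R's default type-7 interpolation) and
   `"hinges"` (Tukey's hinges); the rule used is recorded in the report.
   Optional `expected_min`/`expected_max` columns on the reference table are
   echoed into the report for human inspection but never influence the
   decision.
3. **Node-support filter.** After IQR culling, any node retaining three or
   fewer surviving fossils is considered too weakly supported to calibrate,
   and its fossils are removed with reason `LOW_NODE_SUPPORT`. The order
   matters: support is counted among IQR *survivors*, not raw candidates.
4. **Calibration selection.** For each surviving node,
   `select_calibrations()` picks the record with the **oldest minimum age**
   — the hardest minimum the surviving evidence supports — as the node's
   calibration, with no maximum (maxima come from the root constraint in the
   downstream analysis).

Every exclusion carries a machine-readable reason
(`OUTLIER_AT_<node>`, `LOW_NODE_SUPPORT`, `RUN_FAILED`), and the full
per-fossil table is written by `write_screening_report()` so decisions can be
audited.

## 4. Bayesian node dating

`mcmc_date()` is a deliberately minimal Metropolis-Hastings sampler for node
ages under an independent-rates relaxed clock: each branch rate is iid
lognormal with location `log(mean_rate)` and scale `rate_log_sd`, and the
Poisson branch-length likelihood is the same as in the PL stage.

**Prior on ages.** The prior is flat over the feasible polytope: uniform
subject to parent-older-than-child, the calibration minima/maxima, and a
hard root maximum `root_max`. This is a simplification relative to the
birth-death priors of full dating packages, chosen so that the prior can be
sampled *directly* by rejection, giving an exact oracle for the prior-only
MCMC check in the test suite.

**Moves.** Each generation applies, in fixed order with pre-drawn uniforms
for bit-reproducibility:

* single node-age slides within the node's current feasible interval;
* *compensated* node slides that rescale the adjacent branch rates so the
  expected substitutions are unchanged (likelihood-invariant; Hastings ratio
  from the rate Jacobian);
* per-branch rate multipliers;
* a whole-tree age scaling and a "ridge" move (ages multiplied by `c`, rates
  divided by `c`) that travel along the rate–time ridge.

Proposal scales adapt during burn-in only, so the post-burn-in chain is a
valid fixed-kernel Markov chain. Effective sample sizes are computed with
Geyer's initial-positive-sequence estimator (`ess()`); replicate chains
(`replicates`) are summarized jointly and their per-node posterior-median
discrepancies are reported as `replicate_delta`.

## 5. The synthetic generator

`sim_config()` / `simulate_tree()` / `simulate_fossils()` generate complete
study datasets: a birth-death chronogram with known node ages, branch rates
(strict or lognormal-relaxed), a phylogram whose branch lengths are either
exact expectations (`alignment_length = Inf`) or Poisson-noised counts
divided by the alignment length, and a fossil registry in which a configured
fraction of records is *misleading*: their minimum ages are planted at a
multiplier (default 2x) of the true node age, while informative records get
minima drawn below the true age. The generator records ground truth
(`.misleading`, true ages/rates) in attributes and hidden columns that the
screening code never reads; tests verify the screening stage recovers the
plant. Fossils are only attached to nodes old enough to carry them
(`fossil_min_node_age`), since a minimum planted on a very young node is
trivially detectable and would inflate measured screening power.

## 6. Problem sizes and runtime

The defaults are sized for interactive use: trees of 5–20 tips, registries
of tens to ~100 fossils, MCMC runs of 10^4–10^5 generations. Per-fossil PL
dating dominates screening cost (one optimization per fossil per restart);
100 fossils on a 14-tip tree with one restart takes on the order of half a
minute. The MCMC stage runs ~50,000 generations on a 6-tip tree in a few
seconds per chain.

## 7. Limitations

* The Poisson branch-length model ignores phylogenetic uncertainty in the
  input phylogram; branch lengths are treated as sufficient statistics.
* The flat polytope age prior is not a birth-death prior; posterior ages on
  deep, uncalibrated nodes lean on the root maximum.
* The IQR cull assumes most candidate fossils are informative; if more than
  ~25% of candidates at a reference node are misleading in the same
  direction, the quartiles themselves shift and power degrades.
* The node-support threshold (more than three fossils) is a fixed protocol
  constant, not an estimated quantity.
* `ape::chronos()` is available in the test suite as an independent
  cross-check of chronogram shapes, but the PL implementation here is
  self-contained and differs in penalty details, so numerical agreement is
  approximate by design.
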