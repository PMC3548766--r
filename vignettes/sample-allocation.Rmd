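---
title: "Optimal sample-to-batch allocation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal sample-to-batch allocation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batchalloc)
```

## The problem

Sizable genomics experiments are processed in batches — plates, or the
chips within plates — and systematic non-biological differences between
batches (batch effects) can rival the biological signal of interest. A
study designed up front as a randomized complete block design (RCBD) would
place an equal, complete replicate of every group in every batch. In
practice the collection that finally reaches the profiling instrument is
unbalanced and incomplete: samples fail QC, are rare, or arrive late. With
complete randomization there is then a substantial chance that biological
groups or clinical confounders end up statistically dependent on batch.

`batchalloc` takes the collection as given and optimizes the *assignment*:
which sample goes into which well, so that every categorical covariate the
analyst cares about is distributed as evenly across batches as the
collection permits.

## Model

Crossing the covariates under consideration gives a single unified variable
whose observed level combinations are the *optimization strata*,
$j = 1, \dots, s$, with sizes $S_j$. The container provides $m$ batches with
$B_i$ usable wells each. The expected allocation is

$$E_{ij} = \frac{B_i\, S_j}{\sum_i B_i},$$

which reduces to $S_j/m$ for equal batches. Writing
$E_{ij} = \lfloor E_{ij}\rfloor + \delta_{ij}$, an ideal RCBD is exactly the
case where every fractional part $\delta_{ij}$ is zero. An assignment with
realized counts $n_{ij}$ is scored by the least-squares objective

$$V = \sum_{ij} \left(n_{ij} - E_{ij}\right)^2,$$

zero precisely when the assignment matches expectation cell by cell.

## Block randomization

`block_randomize()` first places $\lfloor E_{ij}\rfloor$ randomly chosen
samples of every stratum into every batch. That leaves $r_j = S_j -
\sum_i \lfloor E_{ij}\rfloor$ samples per stratum and $w_i = B_i - \sum_j
\lfloor E_{ij}\rfloor$ free wells per batch. Each leftover sample of
stratum $j$ is assigned to a batch with probability proportional to
$\delta_{ij}$.

The probability law is stated per sample–batch pair; it does not by itself
say whether leftovers are drawn sequentially or simultaneously. We draw
them sequentially, visiting strata in random order and restricting each
draw to batches with remaining free wells (falling back to a uniform draw
over those batches in the rare case where all their $\delta_{ij}$ are
zero). This respects the stated law marginally while guaranteeing that the
allocation always completes; the Monte-Carlo tests in the suite confirm the
marginal frequencies (e.g. a 50/50 split of the odd sample for two equal
batches, and a 25/75 split when $\delta = (0.25, 0.75)$) within 3-sigma
binomial bands over 10,000 runs.

Within a batch, samples are placed on a uniform random permutation of the
batch's usable wells: positional effects inside a batch are not modeled, so
any within-batch order is as good as any other, and spare wells simply stay
empty (they are emitted as blank rows in the output sheet).

## The shuffle optimizer

`optimal_shuffle()` — the default algorithm — block-randomizes once over
*all* covariates, then performs a greedy local search: each of `n_attempts`
(default 5000) proposals draws $k$ samples (default $k = 2$) from pairwise
distinct batches and exchanges their wells cyclically. A proposal that
strictly lowers $V$ is accepted; $V$ never increases.

Two numerical details matter:

* **Tolerance.** "Strictly lower" means $\Delta V < -10^{-9}$; $V$ is a sum
  of squares of rationals and exact ties are common, so a tolerance keeps
  floating-point noise from masquerading as improvement.
* **Tie-breaking on the optimal plateau.** For unbalanced collections the
  objective has many tied optima: once every stratum is within one sample
  of expectation everywhere, *which* batches carry the unavoidable +1
  remainders is free. Different choices give visibly different per-covariate
  marginals — the quantity the chi-square diagnostics actually test — at
  identical $V$. On the 576-sample demonstration setting the search
  provably reaches the global minimum of $V$ (it matches the analytic
  column-wise lower bound $\sum_j m\,\bar\delta_j(1-\bar\delta_j)$), yet
  with arbitrary tie selection roughly one seed in eight lands on an
  optimum where some marginal chi-square p-value dips just below 0.99.
  The default acceptance rule is therefore lexicographic: a $V$-neutral
  exchange is accepted when it strictly reduces the summed squared
  deviation of every covariate's batch-by-level marginal from its own
  expectation. The search then drifts across the $V$-optimal plateau toward
  the marginal-balanced optimum; final $V$ is unchanged and the
  accepted-objective sequence remains non-increasing.
  `shuffle_config(tie_break = "none")` restores plain strict descent.

Attempts are counted whether accepted or not, so runtime is bounded. $k=2$
is the default because a pairwise swap is the smallest move that preserves
per-batch fill counts; larger $k$ performs a cyclic exchange. Because every
move exchanges well addresses (not just batch labels), the positional
output stays valid throughout, and the incrementally maintained count
matrix is asserted equal to a full recomputation in the test suite.

A consequence of swap-only moves is that per-batch fill counts are fixed by
the initial block randomization. For saturated containers (every well used)
this is no restriction at all — row sums are forced to $B_i$ — and the
package's exhaustive-enumeration checks therefore use saturated instances,
where the swap neighbourhood is connected over all feasible count matrices
and the greedy search recovers the brute-force minimum in at least 99% of
seeds. With many spare wells the fill profile itself is frozen at its
block-randomized (floor + $\delta$-proportional) values, which is the
behaviour one wants in practice but means the search does not explore
alternative fill profiles.

## The pool-selection optimizer

`optimal_block()` — the alternative algorithm — serves the case where
blocking the primary variable is essential and balancing the confounders is
desirable but secondary. It generates `pool_size` (default 1000) block
randomizations blocked on the chosen variables only, then selects the
candidate minimizing the objective computed over the strata of *all*
variables. The blocked variables are guaranteed floor-dominant with respect
to their own expectation (each batch-by-level count within one of
expectation); the unblocked covariates are only as balanced as the best
candidate happens to be. We compute the selection objective on the joint
strata of all variables (the unified-variable reading); a per-variable
marginal alternative is available as `marginal_objective()` and can be
passed as the `objective` of either optimizer.

`complete_randomization()` is the deliberately naive baseline: a uniform
random injection of samples into wells. On unbalanced collections it
regularly produces setups where covariates are significantly associated
with batch, which is the failure mode the optimizers exist to avoid.

## Diagnostics

`diagnose()` reports, per covariate, the batch-by-level contingency table
and the plain Pearson chi-square test of independence (no continuity
correction), with df $=(m'-1)(L-1)$ where $m'$ counts non-empty batches
and $L$ the levels present. For six batches this gives df = 5 for a
two-level covariate and df = 20 for a five-level one. Expected cell counts
below 5 trigger a warning but do not block the test — the tool reports the
conventional statistic on whatever table the design produced — and
degenerate single-level tables return df = 0, p = 1 with a warning.
P-values are printed to 7 significant digits.

## The synthetic study generator

`simulate_samples()` draws each record independently from a joint
categorical law given by per-variable marginals, optionally tilted by an
odds-ratio-like multiplier between two variables; `quota = TRUE` instead
realizes exact largest-remainder cell counts, which is how the balanced
RCBD fixtures used in the degenerate-case tests are constructed.
`study_fixture()` is the canonical demonstration setting: 576 samples with
`SampleType` (case/control, 55/45), `Race` (A/B, 70/30) and `AgeGrp`
(five levels, 30/25/20/15/10), on six 96-well bead-array plates (8 chips of
6 × 2 wells each) with batches at plate level — a saturated container.

The marginal probabilities are fixture constants chosen to emulate an
unbalanced clinical collection; they are not measurements of any real
cohort. Two features of real collections are deliberately *not* emulated by
default: association between covariates (the default multiplier is 1, so
covariates are independent; real race/age/disease variables are usually
correlated) and structured missingness. Passing tests on this generator
therefore demonstrates the allocation machinery on realistically unbalanced
marginals, not robustness to every real-data pathology. One measurable
consequence: with independent covariates, a complete randomization in which
*all three* covariates are simultaneously dependent on batch (all p < 0.05)
is roughly a one-in-a-thousand event, so demonstrations that hunt for such
an "undesired setup" within a thousand draws sit near the edge of what the
independence assumption supports.

## Parameters at a glance

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `n_attempts` | `shuffle_config()` | 5000 | proposals, accepted or not |
| `k` | `shuffle_config()` | 2 | samples exchanged per proposal |
| `tie_break` | `shuffle_config()` | `"marginal"` | plateau rule (see above) |
| `pool_size` | `block_pool_config()` | 1000 | candidates generated |
| `blocking_variables` | `block_pool_config()` | — | variables blocked in the pool |
| `batch_level` | `make_container()` | `"plate"` | batch granularity |
| `seed` | all stochastic entry points | — | single integer; recorded in run metadata |

## Problem sizes used by the test suite

The suite works at desk scale: the 576-sample fixture with 20 optimizer
seeds, 10,000-run Monte-Carlo checks of the remainder law on two-batch toy
instances, 1000-draw complete-randomization searches, and brute-force
enumeration on instances with $m \le 3$, $s \le 3$, $n \le 9$. These sizes
were chosen so the whole suite exercises every claim in about a minute
while keeping the Monte-Carlo bands (3-sigma binomial) tight enough to be
meaningful.

## Known limitations

* Covariates must be categorical; continuous covariates are not binned
  automatically.
* A single batch axis: reagent lots, operators or scan dates are not
  modeled as crossed batch factors.
* The greedy search never accepts a $V$-worsening move (no annealing); for
  saturated containers this is provably sufficient on small instances, but
  no optimality guarantee is claimed in general.
* Paired-specimen constraints (forcing sample pairs onto one chip) are not
  supported.
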