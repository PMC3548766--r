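# batchalloc

Optimal sample-to-batch allocation for genomics experiments.

## The problem

Genomics experiments of any size are processed in batches — microtitre
plates, or the chips within them — and systematic differences between
batches can rival the biology of interest. An ideal study is a randomized
complete block design, but the collection that actually reaches the
instrument is usually unbalanced and incomplete, and naive complete
randomization then carries a real risk of confounding batch with the very
groups being compared. `batchalloc` is for the person who has the final
sample list in hand and must decide *which sample goes into which well*:
it produces an assignment under which every categorical covariate —
case/control status, demographics, any discretized confounder — is as
evenly spread over batches as the collection permits, and quantifies the
result with Pearson chi-square tests of batch association.

## The method

Crossing the covariates gives *optimization strata* $j = 1,\dots,s$ with
sizes $S_j$; the container gives $m$ batches with $B_i$ usable wells. The
expected allocation and the objective are

$$E_{ij} = \frac{B_i S_j}{\sum_i B_i}, \qquad
  V = \sum_{ij}\left(n_{ij} - E_{ij}\right)^2 ,$$

where $n_{ij}$ are the realized counts. A *block randomization* step places
$\lfloor E_{ij}\rfloor$ samples of each stratum in each batch and assigns
the leftovers with probability proportional to the fractional parts
$\delta_{ij}$ (for a balanced design all $\delta_{ij}=0$ and $V=0$ with no
further work). An *optimization* step then either

* `optimal_shuffle()` — greedily swaps samples between batches, keeping
  strictly $V$-improving moves (5000 attempts by default), breaking ties on
  the $V$-optimal plateau in favour of better per-covariate marginal
  balance; or
* `optimal_block()` — generates a pool of block randomizations blocked on
  the primary variable(s) only and selects the member minimizing $V$ over
  all covariates.

`complete_randomization()` provides the unblocked baseline.

## Worked example

Simulate an unbalanced 576-sample study (case/control, two-level race,
five-level age group) on six 96-well bead-array plates, optimize, and
inspect:

```r
library(batchalloc)

fx <- study_fixture(seed = 1)          # samples + 6-plate container
res <- optimal_shuffle(fx$samples, fx$container, shuffle_config(seed = 1))
res$trace
#> Optimization trace: initial V = 46.66667, final V = 18.66667, 31 recorded step(s) of 5000 attempts
diagnose(res$assignment, fx$samples, fx$container)
#> Batch association diagnostics (objective V = 18.66667)
#>    Variable DF Chi.square   P.value
#>  SampleType  5 0.03512923 0.9999879
#>        Race  5 0.07644326 0.9999164
#>      AgeGrp 20 0.12637120 1.0000000
```

The objective drops from 46.7 (one block randomization) to 18.7, and every
covariate is far from batch-dependent (all p > 0.999): no batch is enriched
for cases, either race, or any age group. Compare a complete
randomization of the same collection:

```r
base <- complete_randomization(fx$samples, fx$container, seed = 11)
diagnose(base, fx$samples, fx$container)
#> Batch association diagnostics (objective V = 506.6667)
#>    Variable DF Chi.square   P.value
#>  SampleType  5   9.140627 0.1035848
#>        Race  5   5.070737 0.4073086
#>      AgeGrp 20  21.563480 0.3646593
```

Unlucky draws go much further than this; searching a few hundred seeds
turns up setups with *all three* covariates significant at p < 0.05.

Real sample lists come in via `load_samples("samples.csv")`, containers via
`make_container("illumina-beadchip-96", n_plates = 6)` or a YAML config
(`container_from_config()`), and `run_allocation()` (or the
`inst/cli/batchalloc.R` script with `allocate` / `simulate` / `diagnose`
subcommands) writes the plate-map `assignment.csv`, the diagnostics tables,
and a `metadata.json` sufficient to reproduce the run.

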