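#' Simulate a categorical sample collection
#'
#' Draws `n` sample records whose covariates follow given marginal
#' distributions, optionally with a pairwise association between two
#' variables. By default each record is drawn independently from the joint
#' law (multinomial sampling), so stratum counts vary across seeds the way
#' real unbalanced collections do; `quota = TRUE` instead fixes the joint
#' cell counts to a largest-remainder rounding of `n` times the cell
#' probabilities, which is how exactly balanced block-design fixtures are
#' built.
#'
#' The association knob multiplies the joint probability of the *first*
#' level of `association$variables[1]` co-occurring with the first level of
#' `association$variables[2]` by `association$multiplier` (then renormalizes)
#' — an odds-ratio-like dependence; a multiplier of 1 leaves the variables
#' independent.
#'
#' @param n number of samples.
#' @param variables named list; each element is a named numeric vector of
#'   level probabilities summing to 1 (names are the level labels).
#' @param association optional list with `variables` (two variable names)
#'   and `multiplier` (> 0).
#' @param quota if `TRUE`, realize exact largest-remainder cell counts
#'   instead of sampling them.
#' @param seed optional integer seed.
#' @param id_prefix prefix for generated sample ids (`"S0001"`, ...).
#' @return a [sample_table()].
#' @examples
#' st <- simulate_samples(100, list(Group = c(case = 0.5, control = 0.5)),
#'                        seed = 1)
#' @export
simulate_samples <- function(n, variables, association = NULL, quota = FALSE,
                             seed = NULL, id_prefix = "S") {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1L, length(variables) >= 1L, !is.null(names(variables)))
  for (v in names(variables)) {
    p <- variables[[v]]
    if (is.null(names(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("marginal probabilities for '", v,
           "' must be named, non-negative and sum to 1", call. = FALSE)
  }

  # joint law over the full cross of levels (variables independent unless an
  # association multiplier is given)
  level_sets <- lapply(variables, names)
  grid <- expand.grid(rev(level_sets), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(level_sets)), drop = FALSE]
  names(grid) <- names(variables)
  pj <- rep(1, nrow(grid))
  for (v in names(variables)) pj <- pj * variables[[v]][grid[[v]]]
  if (!is.null(association)) {
    va <- association$variables
    mult <- association$multiplier
    if (length(va) != 2L || !all(va %in% names(variables)) ||
        !is.numeric(mult) || mult <= 0)
      stop("association needs two declared variable names and a positive ",
           "multiplier", call. = FALSE)
    hit <- grid[[va[1L]]] == names(variables[[va[1L]]])[1L] &
           grid[[va[2L]]] == names(variables[[va[2L]]])[1L]
    pj[hit] <- pj[hit] * mult
  }
  pj <- pj / sum(pj)

  counts <- if (quota) .largest_remainder(n * pj) else
    as.integer(stats::rmultinom(1L, n, pj))
  rows <- rep.int(seq_len(nrow(grid)), counts)
  rows <- if (length(rows) > 1L) sample(rows) else rows

  width <- max(4L, nchar(as.character(n)))
  out <- data.frame(ID = sprintf(paste0(id_prefix, "%0", width, "d"),
                                 seq_len(n)),
                    grid[rows, , drop = FALSE],
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  sample_table(out, id_column = "ID", variables = names(variables))
}

# integer apportionment: floor everything, hand the shortfall to the cells
# with the largest fractional parts
.largest_remainder <- function(x) {
  f <- floor(x + 1e-9)
  rem <- x - f
  short <- round(sum(x)) - sum(f)
  if (short > 0) {
    top <- order(rem, decreasing = TRUE)[seq_len(short)]
    f[top] <- f[top] + 1
  }
  as.integer(f)
}

#' Demonstration study fixture: 576 unbalanced samples on 6 plates
#'
#' Generates the canonical demonstration setting used throughout the
#' package's tests and examples: 576 samples with a two-level case/control
#' variable (`SampleType`, 55/45), a two-level confounder (`Race`, 70/30)
#' and a five-level confounder (`AgeGrp`, 30/25/20/15/10) — all drawn
#' independently, so realized stratum counts are unbalanced and vary by
#' seed — plus a container of 6 bead-array plates of 96 wells each
#' (saturated: 576 wells for 576 samples), with batches at plate level.
#'
#' The marginal probabilities are fixture constants chosen to emulate an
#' unbalanced clinical collection; they are synthetic, not measured from any
#' real cohort.
#'
#' @param seed integer seed realizing the table.
#' @return list with elements `samples` (a [sample_table()]) and
#'   `container` (a [make_container()] container).
#' @export
study_fixture <- function(seed = 1L) {
  samples <- simulate_samples(
    576L,
    list(SampleType = c(case = 0.55, control = 0.45),
         Race = c(A = 0.70, B = 0.30),
         AgeGrp = c(G1 = 0.30, G2 = 0.25, G3 = 0.20, G4 = 0.15, G5 = 0.10)),
    seed = seed)
  container <- make_container(predefined_layout("illumina-beadchip-96"), 6L,
                              batch_level = "plate")
  list(samples = samples, container = container)
}
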