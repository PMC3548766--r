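#' Expected batch-by-stratum allocation
#'
#' For batches of capacity \eqn{B_i} and strata of size \eqn{S_j}, the
#' expected count of stratum-\eqn{j} samples in batch \eqn{i} is
#' \deqn{E_{ij} = B_i S_j / \sum_i B_i,}
#' which reduces to \eqn{S_j / m} when all batches have equal capacity. Each
#' \eqn{E_{ij}} splits into its integer part \eqn{\lfloor E_{ij}\rfloor} and
#' fractional part \eqn{\delta_{ij}}; in a perfectly balanced randomized
#' complete block design all \eqn{\delta_{ij}} are zero. The leftovers after
#' placing the integer parts are \eqn{r_j} samples per stratum and \eqn{w_i}
#' free wells per batch.
#'
#' @param strata a [build_strata()] index.
#' @param container a [make_container()] container.
#' @return an object of class `expected_allocation`: list with the m x s
#'   matrices `E`, `floor_E`, `delta`, the leftover vectors `r` (per
#'   stratum) and `w` (per batch), and copies of `S`, `B`, `m`, `s`.
#' @export
expected_counts <- function(strata, container) {
  stopifnot(inherits(strata, "strata_index"), inherits(container, "container"))
  S <- strata$S
  B <- container$B
  if (sum(S) > sum(B))
    stop("capacity exceeded: ", sum(S), " samples but only ", sum(B),
         " usable wells", call. = FALSE)
  E <- outer(B, S) / sum(B)
  # guard against 9.999...96-style representation error before flooring
  floor_E <- floor(E + 1e-9)
  delta <- E - floor_E
  delta[delta < 0] <- 0
  r <- as.integer(S - colSums(floor_E))
  w <- as.integer(B - rowSums(floor_E))
  structure(list(E = E, floor_E = floor_E, delta = delta, r = r, w = w,
                 S = S, B = B, m = container$m, s = strata$s),
            class = "expected_allocation")
}

#' Least-squares allocation objective
#'
#' \deqn{V = \sum_{ij} (n_{ij} - E_{ij})^2} — the squared deviation of the
#' realized batch-by-stratum counts from their expectation. Zero if and only
#' if the assignment matches the expectation exactly; lower is more
#' homogeneous.
#'
#' @param n m x s matrix of realized counts.
#' @param expected an [expected_counts()] object (or a bare m x s matrix E).
#' @return a non-negative scalar.
#' @export
objective_value <- function(n, expected) {
  E <- if (inherits(expected, "expected_allocation")) expected$E else expected
  if (!all(dim(n) == dim(E)))
    stop("count matrix and expectation have different shapes: ",
         paste(dim(n), collapse = "x"), " vs ",
         paste(dim(E), collapse = "x"), call. = FALSE)
  sum((n - E)^2)
}

#' Per-variable marginal objective variant
#'
#' Builds an objective function (same signature as [objective_value()]) that
#' scores an assignment by the summed squared deviation of each covariate's
#' batch-by-level *marginal* counts from their expectations, instead of the
#' joint batch-by-stratum deviation. Marginals are obtained by aggregating
#' the stratum columns that share a level, so the returned closure can be
#' passed straight to [optimal_shuffle()] or [optimal_block()] as their
#' `objective`.
#'
#' @param strata the [build_strata()] index the count matrices are tallied
#'   over.
#' @return a function `(n, expected) -> non-negative real`.
#' @export
marginal_objective <- function(strata) {
  # indicator matrix per variable: stratum j contributes to its level column
  aggregators <- lapply(strata$variables, function(v) {
    lv <- sort(unique(strata$levels[[v]]), method = "radix")
    A <- matrix(0, strata$s, length(lv))
    A[cbind(seq_len(strata$s), match(strata$levels[[v]], lv))] <- 1
    A
  })
  function(n, expected) {
    E <- if (inherits(expected, "expected_allocation")) expected$E
         else expected
    sum(vapply(aggregators,
               function(A) sum((n %*% A - E %*% A)^2), 0))
  }
}

#' One block randomization of samples into batches
#'
#' First places \eqn{\lfloor E_{ij}\rfloor} randomly chosen samples of each
#' stratum \eqn{j} into each batch \eqn{i}. The \eqn{r_j} leftover samples of
#' each stratum are then assigned one at a time (strata visited in random
#' order) to a batch with remaining free wells, drawn with probability
#' proportional to the fractional parts \eqn{\delta_{ij}} over the eligible
#' batches; if every eligible batch has \eqn{\delta_{ij} = 0} the draw falls
#' back to uniform so the allocation always completes. Finally each batch's
#' samples are placed on a uniform random permutation of its usable wells;
#' wells beyond the batch's sample count stay empty.
#'
#' For a balanced randomized complete block design every \eqn{\delta_{ij}}
#' is zero, the leftover stage is empty and the objective is exactly zero.
#'
#' @param strata a [build_strata()] index.
#' @param container a [make_container()] container.
#' @param expected optional precomputed [expected_counts()] for the same
#'   strata and container.
#' @param seed optional integer seed for reproducibility.
#' @return an object of class `assignment`: list with `placement` (integer
#'   vector named by sample id, giving the row of `container$wells` each
#'   sample occupies), the count matrix `n`, and the objective `V`.
#' @export
block_randomize <- function(strata, container, expected = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(expected)) expected <- expected_counts(strata, container)
  m <- container$m
  s <- strata$s

  n <- expected$floor_E
  cap <- expected$w            # free wells per batch after integer placement
  for (j in sample.int(s)) {   # strata in random order
    rj <- expected$r[j]
    while (rj > 0L) {
      elig <- which(cap > 0L)
      p <- expected$delta[elig, j]
      i <- if (sum(p) > 0) {
        if (length(elig) == 1L) elig else elig[sample.int(length(elig), 1L, prob = p)]
      } else {
        if (length(elig) == 1L) elig else elig[sample.int(length(elig), 1L)]
      }
      n[i, j] <- n[i, j] + 1L
      cap[i] <- cap[i] - 1L
      rj <- rj - 1L
    }
  }
  placement <- .realize_placement(n, strata, container)
  new_assignment(placement, n, objective_value(n, expected))
}

# turn a feasible count matrix into a concrete sample -> well placement:
# samples of each stratum are shuffled and dealt to batches per n[, j]; each
# batch's samples then land on a random permutation of its wells
.realize_placement <- function(n, strata, container) {
  m <- container$m
  batch_of_well <- container$wells$batch
  ids <- names(strata$stratum_of)
  batch_members <- vector("list", m)
  for (j in seq_len(strata$s)) {
    sj <- ids[strata$stratum_of == j]
    sj <- if (length(sj) > 1L) sample(sj) else sj
    pos <- 0L
    for (i in seq_len(m)) {
      k <- n[i, j]
      if (k > 0L) {
        batch_members[[i]] <- c(batch_members[[i]], sj[pos + seq_len(k)])
        pos <- pos + k
      }
    }
  }
  placement <- integer(length(ids))
  names(placement) <- ids
  for (i in seq_len(m)) {
    mem <- batch_members[[i]]
    if (length(mem) == 0L) next
    wi <- which(batch_of_well == i)
    wi <- if (length(wi) > 1L) sample(wi) else wi
    placement[mem] <- wi[seq_along(mem)]
  }
  placement
}

new_assignment <- function(placement, n, V, meta = list()) {
  structure(list(placement = placement, n = n, V = V, meta = meta),
            class = "assignment")
}

#' Recompute the batch-by-stratum count matrix of an assignment
#'
#' @param assignment an `assignment`.
#' @param strata the strata the counts should be tallied over.
#' @param container the container the assignment refers to.
#' @return an m x s integer matrix.
#' @export
count_matrix <- function(assignment, strata, container) {
  b <- container$wells$batch[assignment$placement]
  j <- strata$stratum_of[names(assignment$placement)]
  n <- matrix(0L, nrow = container$m, ncol = strata$s)
  for (k in seq_along(b)) n[b[k], j[k]] <- n[b[k], j[k]] + 1L
  n
}

#' @export
print.assignment <- function(x, ...) {
  cat("Assignment: ", length(x$placement), " samples across ",
      nrow(x$n), " batch(es); objective V = ", format(x$V), "\n", sep = "")
  if (length(x$meta) > 0L)
    cat("  method: ", x$meta$method %||% "?",
        if (!is.null(x$meta$seed)) paste0(", seed ", x$meta$seed), "\n",
        sep = "")
  invisible(x)
}
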