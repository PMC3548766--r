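#' Shuffle optimizer configuration
#'
#' @param n_attempts number of proposed shuffles (accepted or not); 5000 by
#'   default.
#' @param k number of samples exchanged per attempt (k = 2 is a pairwise
#'   swap, the smallest move that preserves per-batch fill counts).
#' @param seed optional integer seed.
#' @param tie_break `"marginal"` (default) also accepts moves that leave the
#'   objective V unchanged but strictly improve the balance of each
#'   covariate's batch-by-level marginal; `"none"` accepts strictly
#'   V-improving moves only. See [optimal_shuffle()].
#' @export
shuffle_config <- function(n_attempts = 5000L, k = 2L, seed = NULL,
                           tie_break = c("marginal", "none")) {
  stopifnot(n_attempts >= 1L, k >= 2L)
  structure(list(n_attempts = as.integer(n_attempts), k = as.integer(k),
                 seed = seed, tie_break = match.arg(tie_break)),
            class = "shuffle_config")
}

#' Pool-selection optimizer configuration
#'
#' @param blocking_variables variables blocked when generating the candidate
#'   pool (typically the primary variable only).
#' @param pool_size number of block-randomized candidate setups to generate.
#' @param seed optional integer seed.
#' @export
block_pool_config <- function(blocking_variables, pool_size = 1000L,
                              seed = NULL) {
  stopifnot(length(blocking_variables) >= 1L, pool_size >= 1L)
  structure(list(blocking_variables = blocking_variables,
                 pool_size = as.integer(pool_size), seed = seed),
            class = "block_pool_config")
}

new_trace <- function(step_index, objective, initial_V, final_V,
                      attempts = NA_integer_) {
  structure(list(step_index = step_index, objective = objective,
                 initial_V = initial_V, final_V = final_V,
                 attempts = attempts),
            class = "optimization_trace")
}

#' @export
print.optimization_trace <- function(x, ...) {
  cat("Optimization trace: initial V = ", format(x$initial_V),
      ", final V = ", format(x$final_V), ", ",
      length(x$step_index), " recorded step(s)",
      if (!is.na(x$attempts)) paste0(" of ", x$attempts, " attempts"),
      "\n", sep = "")
  invisible(x)
}

#' Greedy swap-based shuffle optimization
#'
#' The default allocation algorithm: block-randomize once over all
#' optimization variables, then repeatedly propose exchanging the wells of
#' `k` samples drawn from distinct batches. A proposal is accepted if it
#' strictly lowers the objective \eqn{V = \sum_{ij} (n_{ij}-E_{ij})^2}; the
#' accepted-objective sequence is therefore non-increasing and the search
#' stops after `n_attempts` proposals, accepted or not.
#'
#' The objective typically has many tied optima: once every stratum's counts
#' are within one of expectation, which batches carry the unavoidable +1
#' remainders is free, and different choices give visibly different
#' per-covariate marginals even at identical V. Under the default
#' `tie_break = "marginal"`, a proposal that leaves V unchanged is accepted
#' when it strictly reduces the summed squared deviation of every
#' covariate's batch-by-level marginal from its own expectation, so the
#' search drifts across the V-optimal plateau toward the assignment whose
#' marginals are most homogeneous — the quantity the chi-square diagnostics
#' test. V itself never increases either way; `tie_break = "none"` restores
#' the plain strict-descent rule.
#'
#' @param samples a [sample_table()].
#' @param container a [make_container()] container.
#' @param config a [shuffle_config()].
#' @param strata optional precomputed strata (defaults to crossing all
#'   declared variables).
#' @param objective objective function with the signature of
#'   [objective_value()]; custom objectives forgo the fast incremental
#'   update and are re-evaluated in full at each proposal.
#' @return list with elements `assignment` and `trace`.
#' @export
optimal_shuffle <- function(samples, container, config = shuffle_config(),
                            strata = NULL, objective = NULL) {
  stopifnot(inherits(config, "shuffle_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(strata)) strata <- build_strata(samples)
  expected <- expected_counts(strata, container)
  asg <- block_randomize(strata, container, expected)

  well_of <- asg$placement
  batch_of <- container$wells$batch[well_of]
  j_of <- as.integer(strata$stratum_of[names(well_of)])
  n <- asg$n
  E <- expected$E
  custom <- !is.null(objective)
  V <- if (custom) objective(n, expected) else asg$V
  initial_V <- V

  # marginal-balance bookkeeping for the tie-break: per covariate, the
  # batch-by-level count matrix and its own expected allocation
  tie_break <- !custom && identical(config$tie_break, "marginal")
  vars <- attr(samples, "variables")
  ids <- sample_ids(samples)
  m <- container$m
  if (tie_break) {
    lev_of <- nv <- Ev <- vector("list", length(vars))
    ord <- match(names(well_of), ids)
    for (q in seq_along(vars)) {
      lv <- sort(unique(samples[[vars[q]]]), method = "radix")
      lev_of[[q]] <- match(samples[[vars[q]]][ord], lv)
      nq <- matrix(0, m, length(lv))
      for (t in seq_along(batch_of))
        nq[batch_of[t], lev_of[[q]][t]] <- nq[batch_of[t], lev_of[[q]][t]] + 1
      nv[[q]] <- nq
      Ev[[q]] <- outer(container$B,
                       tabulate(lev_of[[q]], length(lv))) / sum(container$B)
    }
  }

  k <- config$k
  n_samp <- length(well_of)
  acc_step <- integer(0)
  acc_V <- numeric(0)
  accepted <- 0L
  distinct_batches <- length(unique(batch_of))

  if (distinct_batches >= 2L && n_samp >= k) {
    for (attempt in seq_len(config$n_attempts)) {
      # draw k samples from pairwise distinct batches
      idx <- integer(k)
      used_b <- integer(0)
      ok <- TRUE
      for (t in seq_len(k)) {
        pool <- which(!(batch_of %in% used_b))
        if (length(pool) == 0L) { ok <- FALSE; break }
        idx[t] <- if (length(pool) == 1L) pool else pool[sample.int(length(pool), 1L)]
        used_b <- c(used_b, batch_of[idx[t]])
      }
      if (!ok) next
      bs <- batch_of[idx]
      js <- j_of[idx]
      new_bs <- bs[c(seq_len(k)[-1L], 1L)]  # cyclic shift of batch targets

      if (custom) {
        n2 <- n
        for (t in seq_len(k)) {
          n2[bs[t], js[t]] <- n2[bs[t], js[t]] - 1L
          n2[new_bs[t], js[t]] <- n2[new_bs[t], js[t]] + 1L
        }
        V2 <- objective(n2, expected)
        take <- V2 < V - 1e-9
      } else {
        # incremental evaluation on the touched cells only
        cells_from <- (js - 1L) * m + bs
        cells_to <- (js - 1L) * m + new_bs
        touched <- unique(c(cells_from, cells_to))
        d <- integer(length(touched))
        for (t in seq_len(k)) {
          d[match(cells_from[t], touched)] <- d[match(cells_from[t], touched)] - 1L
          d[match(cells_to[t], touched)] <- d[match(cells_to[t], touched)] + 1L
        }
        old <- n[touched]
        dV <- sum((old + d - E[touched])^2) - sum((old - E[touched])^2)
        V2 <- V + dV
        take <- dV < -1e-9
        dMq <- NULL
        if (!take && tie_break && abs(dV) <= 1e-9) {
          # V-neutral: accept if the covariate marginals strictly improve
          dM <- 0
          dMq <- vector("list", length(vars))
          for (q in seq_along(vars)) {
            lq <- lev_of[[q]][idx]
            cf <- (lq - 1L) * m + bs
            ct <- (lq - 1L) * m + new_bs
            tq <- unique(c(cf, ct))
            dq <- integer(length(tq))
            for (t in seq_len(k)) {
              dq[match(cf[t], tq)] <- dq[match(cf[t], tq)] - 1L
              dq[match(ct[t], tq)] <- dq[match(ct[t], tq)] + 1L
            }
            oq <- nv[[q]][tq]
            dM <- dM + sum((oq + dq - Ev[[q]][tq])^2) -
              sum((oq - Ev[[q]][tq])^2)
            dMq[[q]] <- list(tq = tq, dq = dq)
          }
          take <- dM < -1e-9
          is_tie <- take
          if (is_tie) V2 <- V   # V-neutral by construction; avoid fp drift
        } else is_tie <- FALSE
        if (take) {
          n2 <- n
          n2[touched] <- old + d
          if (tie_break) {
            if (is_tie) {
              for (q in seq_along(vars))
                nv[[q]][dMq[[q]]$tq] <- nv[[q]][dMq[[q]]$tq] + dMq[[q]]$dq
            } else {
              for (q in seq_along(vars)) {
                lq <- lev_of[[q]][idx]
                for (t in seq_len(k)) {
                  nv[[q]][bs[t], lq[t]] <- nv[[q]][bs[t], lq[t]] - 1
                  nv[[q]][new_bs[t], lq[t]] <- nv[[q]][new_bs[t], lq[t]] + 1
                }
              }
            }
          }
        }
      }

      if (take) {
        # apply: rotate wells among the k chosen samples
        wells_k <- well_of[idx]
        well_of[idx] <- wells_k[c(seq_len(k)[-1L], 1L)]
        batch_of[idx] <- new_bs
        n <- n2
        V <- V2
        accepted <- accepted + 1L
        acc_step <- c(acc_step, attempt)
        acc_V <- c(acc_V, V)
      }
    }
  }

  placement <- well_of
  out <- new_assignment(placement, n, V,
                        meta = list(method = "shuffle", seed = config$seed,
                                    n_attempts = config$n_attempts,
                                    k = k, accepted = accepted,
                                    initial_V = initial_V))
  trace <- new_trace(acc_step, acc_V, initial_V, V, config$n_attempts)
  list(assignment = out, trace = trace)
}

#' Pool-selection optimization with blocking on chosen variables
#'
#' The alternative allocation algorithm: generate `pool_size` block
#' randomizations blocked on `blocking_variables` only (guaranteeing near-
#' uniform distribution of those variables), then keep the candidate
#' minimizing the objective computed over the strata of *all* variables
#' considered.
#'
#' @param samples a [sample_table()].
#' @param container a [make_container()] container.
#' @param config a [block_pool_config()].
#' @param all_variables variables the selection objective is computed over;
#'   defaults to all declared variables.
#' @param objective objective function with the signature of
#'   [objective_value()]; default least squares.
#' @return list with elements `assignment` and `trace` (`objective` holds
#'   each candidate's V in generation order; `final_V` is the minimum).
#' @export
optimal_block <- function(samples, container, config,
                          all_variables = NULL, objective = objective_value) {
  stopifnot(inherits(config, "block_pool_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(all_variables)) all_variables <- attr(samples, "variables")
  if (!all(config$blocking_variables %in% all_variables))
    stop("blocking variables must be a subset of the variables considered",
         call. = FALSE)
  strata_block <- build_strata(samples, config$blocking_variables)
  strata_all <- build_strata(samples, all_variables)
  expected_block <- expected_counts(strata_block, container)
  expected_all <- expected_counts(strata_all, container)

  best <- NULL
  best_V <- Inf
  Vs <- numeric(config$pool_size)
  for (p in seq_len(config$pool_size)) {
    cand <- block_randomize(strata_block, container, expected_block)
    n_all <- count_matrix(cand, strata_all, container)
    V_all <- objective(n_all, expected_all)
    Vs[p] <- V_all
    if (V_all < best_V) {
      best_V <- V_all
      best <- new_assignment(cand$placement, n_all, V_all,
                             meta = list(method = "block", seed = config$seed,
                                         pool_size = config$pool_size,
                                         blocking_variables =
                                           config$blocking_variables,
                                         n_blocked = cand$n,
                                         initial_V = Vs[1L]))
    }
  }
  trace <- new_trace(seq_len(config$pool_size), Vs, Vs[1L], best_V,
                     config$pool_size)
  list(assignment = best, trace = trace)
}

#' Create an optimized sample-to-batch setup
#'
#' Dispatch wrapper over the two optimizers.
#'
#' @param method `"shuffle"` (default algorithm) or `"block"`.
#' @param samples a [sample_table()].
#' @param container a [make_container()] container.
#' @param config a [shuffle_config()] or [block_pool_config()] matching the
#'   method.
#' @param ... passed through to the optimizer.
#' @return list with elements `assignment` and `trace`.
#' @export
create_optimized_setup <- function(method, samples, container, config, ...) {
  switch(method,
         shuffle = optimal_shuffle(samples, container, config, ...),
         block = optimal_block(samples, container, config, ...),
         stop("unknown method '", method,
              "'; valid methods: shuffle, block", call. = FALSE))
}

#' Complete randomization baseline
#'
#' Uniformly random assignment of samples to usable wells, with no blocking
#' and no optimization — the baseline whose failure mode (covariates
#' statistically dependent on batch) motivates optimized allocation.
#'
#' @param samples a [sample_table()].
#' @param container a [make_container()] container.
#' @param seed optional integer seed.
#' @param strata optional strata used to tally `n` and `V` (defaults to all
#'   declared variables).
#' @return an `assignment`.
#' @export
complete_randomization <- function(samples, container, seed = NULL,
                                   strata = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(strata)) strata <- build_strata(samples)
  expected <- expected_counts(strata, container)
  ids <- sample_ids(samples)
  placement <- sample.int(nrow(container$wells), length(ids))
  names(placement) <- ids
  asg <- new_assignment(placement, NULL, NA_real_,
                        meta = list(method = "random", seed = seed))
  asg$n <- count_matrix(asg, strata, container)
  asg$V <- objective_value(asg$n, expected)
  asg
}
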