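test_that("the accepted-objective sequence never increases", {
  fx <- study_fixture(seed = 4)
  res <- optimal_shuffle(fx$samples, fx$container,
                         shuffle_config(n_attempts = 2000, seed = 4))
  tr <- res$trace
  expect_equal(tr$final_V, res$assignment$V)
  expect_lte(tr$final_V, tr$initial_V)
  if (length(tr$objective) > 1)
    expect_true(all(diff(tr$objective) <= 1e-9))
  if (length(tr$objective) > 0) {
    expect_lte(tr$objective[1], tr$initial_V)
    expect_equal(tr$objective[length(tr$objective)], tr$final_V)
  }

  # the verbatim strict-descent rule: every accepted step lowers V
  res2 <- optimal_shuffle(fx$samples, fx$container,
                          shuffle_config(n_attempts = 2000, seed = 4,
                                         tie_break = "none"))
  if (length(res2$trace$objective) > 1)
    expect_true(all(diff(res2$trace$objective) < 0))
  # tie-breaking never worsens the primary objective
  expect_lte(res$assignment$V, res2$assignment$V + 1e-9)
})

test_that("shuffle keeps placement, counts and objective mutually consistent", {
  fx <- study_fixture(seed = 8)
  sx <- build_strata(fx$samples)
  ea <- expected_counts(sx, fx$container)
  res <- optimal_shuffle(fx$samples, fx$container,
                         shuffle_config(n_attempts = 1000, seed = 8))
  asg <- res$assignment
  # incremental bookkeeping must equal full recomputation
  expect_equal(count_matrix(asg, sx, fx$container), asg$n)
  expect_equal(objective_value(asg$n, ea), asg$V)
  expect_false(anyDuplicated(asg$placement) > 0)
  expect_equal(sort(names(asg$placement)), sort(fx$samples$ID))
})

test_that("k > 2 cyclic shuffles stay sound", {
  fx <- study_fixture(seed = 12)
  sx <- build_strata(fx$samples)
  ea <- expected_counts(sx, fx$container)
  res <- optimal_shuffle(fx$samples, fx$container,
                         shuffle_config(n_attempts = 500, k = 3, seed = 12))
  asg <- res$assignment
  expect_equal(count_matrix(asg, sx, fx$container), asg$n)
  expect_equal(objective_value(asg$n, ea), asg$V)
  if (length(res$trace$objective) > 1)
    expect_true(all(diff(res$trace$objective) <= 1e-9))
})

test_that("an already-balanced design needs no optimization", {
  fx <- rcbd_fixture()
  res <- optimal_shuffle(fx$samples, fx$container,
                         shuffle_config(n_attempts = 500, seed = 31))
  expect_equal(res$trace$initial_V, 0)
  expect_equal(res$assignment$V, 0)
  expect_equal(res$assignment$meta$accepted, 0L)
})

test_that("shuffle reaches the brute-force optimum on exhaustable instances", {
  instances <- list(list(B = c(3L, 3L), S = c(4L, 2L)),
                    list(B = c(3L, 3L, 3L), S = c(4L, 3L, 2L)),
                    list(B = c(5L, 4L), S = c(3L, 3L, 3L)),
                    list(B = c(2L, 3L, 4L), S = c(5L, 4L)))
  for (inst in instances) {
    target <- brute_force_min_V(inst$B, inst$S)
    samples <- toy_samples(inst$S)
    cont <- toy_container(inst$B)
    hits <- 0L
    for (seed in 1:25) {
      res <- optimal_shuffle(samples, cont,
                             shuffle_config(n_attempts = 5000, seed = seed))
      if (res$assignment$V <= target + 1e-9) hits <- hits + 1L
    }
    expect_gte(hits, 24L)  # >= 96% per instance; joint rate tested at acceptance
  }
})

test_that("pool selection returns the pool minimum and blocks the blocked variable", {
  fx <- study_fixture(seed = 6)
  cfg <- block_pool_config("SampleType", pool_size = 150, seed = 6)
  res <- optimal_block(fx$samples, fx$container, cfg)
  expect_equal(res$assignment$V, min(res$trace$objective))
  expect_equal(res$trace$final_V, min(res$trace$objective))
  expect_equal(length(res$trace$objective), 150L)

  # blocked variable honours floor-dominance of its own expectation
  sx_block <- build_strata(fx$samples, "SampleType")
  ea_block <- expected_counts(sx_block, fx$container)
  n_block <- count_matrix(res$assignment, sx_block, fx$container)
  expect_true(all(n_block >= ea_block$floor_E))
  expect_true(all(abs(n_block - ea_block$E) <= 1))

  # counts over all variables are consistent with the stored objective
  sx_all <- build_strata(fx$samples)
  expect_equal(objective_value(count_matrix(res$assignment, sx_all,
                                            fx$container),
                               expected_counts(sx_all, fx$container)),
               res$assignment$V)
})

test_that("pool of size one is the identity selection and seeds reproduce", {
  fx <- study_fixture(seed = 9)
  one <- optimal_block(fx$samples, fx$container,
                       block_pool_config("SampleType", pool_size = 1,
                                         seed = 5))
  expect_equal(one$assignment$V, one$trace$objective[1])

  a <- optimal_block(fx$samples, fx$container,
                     block_pool_config("SampleType", pool_size = 40,
                                       seed = 123))
  b <- optimal_block(fx$samples, fx$container,
                     block_pool_config("SampleType", pool_size = 40,
                                       seed = 123))
  expect_identical(a$assignment$placement, b$assignment$placement)
  expect_identical(a$trace$objective, b$trace$objective)
})

test_that("the dispatcher routes and rejects methods", {
  fx <- study_fixture(seed = 10)
  d <- create_optimized_setup("shuffle", fx$samples, fx$container,
                              shuffle_config(n_attempts = 200, seed = 44))
  direct <- optimal_shuffle(fx$samples, fx$container,
                            shuffle_config(n_attempts = 200, seed = 44))
  expect_identical(d$assignment$placement, direct$assignment$placement)
  expect_equal(d$assignment$V, direct$assignment$V)
  expect_equal(d$assignment$meta$method, "shuffle")

  expect_error(create_optimized_setup("anneal", fx$samples, fx$container,
                                      shuffle_config()),
               "shuffle, block")
})

test_that("complete randomization is an unblocked uniform baseline", {
  fx <- study_fixture(seed = 13)
  sx <- build_strata(fx$samples)
  asg <- complete_randomization(fx$samples, fx$container, seed = 13)
  expect_equal(colSums(asg$n), as.numeric(sx$S))
  expect_false(anyDuplicated(asg$placement) > 0)
  # saturated container: every well is used exactly once
  expect_equal(sort(unname(asg$placement)), seq_len(576L))

  # same seed reproduces; different seed does not
  asg2 <- complete_randomization(fx$samples, fx$container, seed = 13)
  expect_identical(asg$placement, asg2$placement)
  asg3 <- complete_randomization(fx$samples, fx$container, seed = 14)
  expect_false(identical(asg$placement, asg3$placement))
})

test_that("the marginal objective variant aggregates strata to level counts", {
  fx <- study_fixture(seed = 18)
  sx <- build_strata(fx$samples)
  ea <- expected_counts(sx, fx$container)
  asg <- block_randomize(sx, fx$container, ea, seed = 18)
  obj <- marginal_objective(sx)

  # independent construction: contingency tables per variable
  direct <- 0
  for (v in attr(fx$samples, "variables")) {
    tab <- contingency(asg, fx$samples, v, fx$container)
    Ev <- outer(fx$container$B, colSums(tab)) / sum(fx$container$B)
    direct <- direct + sum((tab - Ev)^2)
  }
  expect_equal(obj(asg$n, ea), direct)

  # usable as a selection objective in the pool optimizer
  res <- optimal_block(fx$samples, fx$container,
                       block_pool_config("SampleType", pool_size = 25,
                                         seed = 18),
                       objective = obj)
  expect_equal(res$assignment$V, min(res$trace$objective))
})

test_that("a custom objective hook is honoured", {
  fx <- study_fixture(seed = 15)
  # L1 objective instead of least squares
  l1 <- function(n, expected) {
    E <- if (inherits(expected, "expected_allocation")) expected$E else expected
    sum(abs(n - E))
  }
  res <- optimal_shuffle(fx$samples, fx$container,
                         shuffle_config(n_attempts = 300, seed = 15),
                         objective = l1)
  sx <- build_strata(fx$samples)
  ea <- expected_counts(sx, fx$container)
  if (length(res$trace$objective) > 1)
    expect_true(all(diff(res$trace$objective) < 0))
  expect_equal(res$trace$final_V, l1(res$assignment$n, ea))
})
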