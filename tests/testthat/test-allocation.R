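test_that("expected counts follow E_ij = B_i S_j / sum(B) with exact parts", {
  # equal batches: reduction to S_j / m
  fx <- study_fixture(seed = 2)
  sx <- build_strata(fx$samples)
  ea <- expected_counts(sx, fx$container)
  expect_equal(ea$E, outer(rep(96, 6), sx$S) / 576)
  expect_equal(ea$E[1, ], sx$S / 6)
  expect_equal(ea$E, ea$floor_E + ea$delta)
  expect_true(all(ea$delta >= 0 & ea$delta < 1))
  expect_equal(colSums(ea$E), as.numeric(sx$S))
  expect_equal(ea$r, as.integer(sx$S - colSums(ea$floor_E)))
  expect_true(all(ea$r >= 0) && all(ea$w >= 0))
  expect_lte(sum(ea$r), sum(ea$w))

  # worked arithmetic: one stratum of 100 over six 96-well batches
  ea2 <- expected_counts(build_strata(toy_samples(100L)),
                         toy_container(rep(96L, 6)))
  expect_equal(ea2$E[1, 1], 100 * 96 / 576)
  expect_equal(ea2$floor_E[1, 1], 16)
  expect_equal(ea2$delta[1, 1], 2 / 3)
  expect_equal(ea2$r, 100L - 6L * 16L)
})

test_that("over-capacity input raises an error reporting both totals", {
  expect_error(expected_counts(build_strata(toy_samples(c(5L, 5L))),
                               toy_container(c(4L, 4L))),
               "10 samples.*8 usable wells")
})

test_that("balanced complete-block designs have all-zero fractional parts", {
  fx <- rcbd_fixture()
  sx <- build_strata(fx$samples)
  ea <- expected_counts(sx, fx$container)
  expect_true(all(ea$delta == 0))
  expect_equal(ea$r, rep(0L, sx$s))
})

test_that("objective is the elementwise squared deviation", {
  E <- matrix(c(2, 2, 3, 3), 2)
  expect_equal(objective_value(E, E), 0)
  n <- E
  n[1, 1] <- n[1, 1] + 1
  n[2, 1] <- n[2, 1] - 1
  expect_equal(objective_value(n, E), 2)

  # brute-force double-loop oracle on a random integer matrix
  set.seed(11)
  n4 <- matrix(rpois(12, 4), 4, 3)
  E4 <- matrix(runif(12, 0, 8), 4, 3)
  v <- 0
  for (i in 1:4) for (j in 1:3) v <- v + (n4[i, j] - E4[i, j])^2
  expect_equal(objective_value(n4, E4), v)

  expect_error(objective_value(matrix(0, 2, 2), matrix(0, 2, 3)),
               "different shapes")
})

test_that("block randomization satisfies floor-dominance, conservation and capacity", {
  set.seed(5)
  for (rep in 1:20) {
    m <- sample(2:4, 1)
    B <- sample(3:9, m, replace = TRUE)
    s <- sample(1:4, 1)
    S <- pmax(1L, as.integer(rmultinom(1, sample(sum(B), 1), rep(1, s))))
    while (sum(S) > sum(B)) S[which.max(S)] <- S[which.max(S)] - 1L
    sx <- build_strata(toy_samples(S))
    cont <- toy_container(B)
    ea <- expected_counts(sx, cont)
    asg <- block_randomize(sx, cont, ea)
    expect_true(all(asg$n >= ea$floor_E))
    expect_equal(colSums(asg$n), as.numeric(S))
    expect_true(all(rowSums(asg$n) <= B))
    # placement is injective into usable wells and matches n
    expect_false(anyDuplicated(asg$placement) > 0)
    expect_equal(count_matrix(asg, sx, cont), asg$n)
    # V decomposes over the remainder placement
    x <- asg$n - ea$floor_E
    expect_equal(asg$V, sum((x - ea$delta)^2))
  }
})

test_that("balanced complete-block randomization is exact with V = 0", {
  fx <- rcbd_fixture()
  sx <- build_strata(fx$samples)
  ea <- expected_counts(sx, fx$container)
  asg <- block_randomize(sx, fx$container, ea, seed = 21)
  expect_equal(asg$n, ea$floor_E)
  expect_equal(asg$V, 0)
})

test_that("remainder assignment follows the fractional-part law", {
  # two batches of 10, one stratum of 11: E = 5.5 each, the single leftover
  # sample should land in batch 1 half the time
  sx <- build_strata(toy_samples(11L))
  cont <- toy_container(c(10L, 10L))
  ea <- expected_counts(sx, cont)
  n_runs <- 10000L
  set.seed(101)
  hits <- 0L
  for (i in seq_len(n_runs)) {
    asg <- block_randomize(sx, cont, ea)
    if (asg$n[1, 1] == 6L) hits <- hits + 1L
  }
  freq <- hits / n_runs
  expect_lt(abs(freq - 0.5), 3 * sqrt(0.25 / n_runs))
})

test_that("skewed fractional parts steer the leftover proportionally", {
  # B = (6, 2), S = 7: E = (5.25, 1.75), delta = (0.25, 0.75) -> the single
  # leftover goes to batch 2 three times as often as to batch 1
  sx <- build_strata(toy_samples(7L))
  cont <- toy_container(c(6L, 2L))
  ea <- expected_counts(sx, cont)
  expect_equal(ea$delta[, 1], c(0.25, 0.75))
  set.seed(202)
  counts <- c(0L, 0L)
  for (i in 1:4000) {
    asg <- block_randomize(sx, cont, ea)
    extra <- which(asg$n[, 1] > ea$floor_E[, 1])
    counts[extra] <- counts[extra] + 1L
  }
  gof <- chisq.test(counts, p = c(0.25, 0.75))
  expect_gt(gof$p.value, 0.001)
})
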