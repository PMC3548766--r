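# Shared fixtures and independent oracles for the test suite.

# one-variable sample table whose stratum sizes are exactly `S`
# (levels L01, L02, ... sort in stratum order)
toy_samples <- function(S) {
  lev <- sprintf("L%02d", seq_along(S))
  df <- data.frame(ID = sprintf("s%03d", seq_len(sum(S))),
                   g = rep(lev, S), stringsAsFactors = FALSE)
  sample_table(df, "ID")
}

# container with one batch per plate and arbitrary capacities `B`,
# realized by excluding the surplus wells of a max(B)-well plate
toy_container <- function(B) {
  lay <- plate_layout("toy", 1L, max(B), 1L)
  excl <- NULL
  for (i in seq_along(B)) {
    if (B[i] < max(B))
      excl <- rbind(excl,
                    data.frame(plate = i, chip = 1L,
                               row = seq(B[i] + 1L, max(B)), column = 1L))
  }
  make_container(lay, length(B), batch_level = "plate", excluded = excl)
}

# balanced complete-block fixture: `m` equal batches, every stratum size
# divisible by m, container saturated -> all fractional parts are zero
rcbd_fixture <- function(m = 4L, per_cell = 3L) {
  samples <- simulate_samples(
    4L * per_cell * m,
    list(u = c(a = 0.5, b = 0.5), v = c(x = 0.5, y = 0.5)),
    quota = TRUE, seed = 99L)
  lay <- plate_layout("rcbd", 1L, 4L * per_cell, 1L)
  container <- make_container(lay, m, batch_level = "plate")
  list(samples = samples, container = container)
}

# all compositions of n into m non-negative parts
compositions <- function(n, m) {
  if (m == 1L) return(matrix(n, ncol = 1L))
  out <- NULL
  for (k in 0:n)
    out <- rbind(out, cbind(k, compositions(n - k, m - 1L)))
  unname(out)
}

# brute-force oracle: minimum V over every count matrix with column sums S
# and row sums exactly B (saturated container)
brute_force_min_V <- function(B, S) {
  m <- length(B)
  E <- outer(B, S) / sum(B)
  per_col <- lapply(S, compositions, m = m)
  best <- Inf
  idx <- rep(1L, length(S))
  sizes <- vapply(per_col, nrow, 0L)
  repeat {
    n <- vapply(seq_along(S), function(j) per_col[[j]][idx[j], ], numeric(m))
    n <- matrix(n, nrow = m)
    if (all(rowSums(n) == B)) best <- min(best, sum((n - E)^2))
    j <- 1L
    while (j <= length(S)) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= sizes[j]) break
      idx[j] <- 1L
      j <- j + 1L
    }
    if (j > length(S)) break
  }
  best
}

# textbook Pearson chi-square, coded independently of the package
pearson_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

fixture_spec <- list(SampleType = c(case = 0.55, control = 0.45),
                     Race = c(A = 0.70, B = 0.30),
                     AgeGrp = c(G1 = 0.30, G2 = 0.25, G3 = 0.20,
                                G4 = 0.15, G5 = 0.10))
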