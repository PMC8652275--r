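test_that("partition bookkeeping enforces the canonical order and invariants", {
  p <- blanket_partition(2, 1, 1, 2)
  expect_equal(p$d_b, 2L)
  expect_equal(p$d, 6L)
  expect_equal(part_idx(p, "eta"), 1:2)
  expect_equal(part_idx(p, "b"), 3:4)
  expect_equal(part_idx(p, "mu"), 5:6)
  expect_equal(part_idx(p, "bmu"), 3:6)
  expect_error(blanket_partition(0, 1, 0, 1), "d_eta")
  expect_error(blanket_partition(1, 0, 0, 1), "blanket dimension")
  expect_error(blanket_partition(1, 1.5, 0, 1), "integer")
})

test_that("stationary density validates symmetry, positivity and Pi Sigma = I", {
  dens <- ex22_density()
  expect_equal(dens$covariance, ex22_covariance(), tolerance = 1e-12)
  expect_lt(max(abs(dens$precision %*% dens$covariance - diag(3))), 1e-12)
  P <- blanket_partition(1, 1, 0, 1)
  Pi_bad <- ex22_precision(); Pi_bad[1, 3] <- 0.5
  expect_error(stationary_density(Pi_bad, P), "symmetric")
  expect_error(stationary_density(-diag(3), P), "positive-definite")
  expect_error(stationary_density(diag(4), P), "dimension")
})

test_that("blanket detection reads the (eta, mu) precision block", {
  expect_true(is_markov_blanket(ex22_density()))
  P <- blanket_partition(1, 1, 0, 1)
  expect_true(is_markov_blanket(stationary_density(diag(3), P)))
  Pi <- ex22_precision(); Pi[1, 3] <- Pi[3, 1] <- 0.5
  expect_false(is_markov_blanket(stationary_density(Pi, P)))
})

test_that("conditional independence residual vanishes iff the blanket holds", {
  expect_lt(max(abs(conditional_independence_residual(ex22_density()))), 1e-14)
  P <- blanket_partition(1, 1, 0, 1)
  bd <- stationary_density(diag(c(2, 3, 4)), P)
  expect_lt(max(abs(conditional_independence_residual(bd))), 1e-14)
  Pi <- ex22_precision(); Pi[1, 3] <- Pi[3, 1] <- 0.5
  leaky <- stationary_density(Pi, P)
  # brute-force Schur complement oracle
  S <- solve(Pi)
  oracle <- S[1, 3] - S[1, 2] * S[3, 2] / S[2, 2]
  expect_equal(as.numeric(conditional_independence_residual(leaky)), oracle)
  expect_gt(abs(oracle), 1e-3)
})

test_that("conditionals given the blanket have the closed-form means and precisions", {
  dens <- ex22_density()
  cond <- conditional_given_blanket(dens, 1)
  expect_equal(cond$eta$mean, -0.5)
  expect_equal(as.numeric(cond$eta$precision), 2)
  expect_equal(cond$mu$mean, -0.5)
  expect_equal(as.numeric(cond$mu$precision), 2)
  zero <- conditional_given_blanket(dens, 0)
  expect_equal(zero$eta$mean, 0)
  expect_equal(zero$mu$mean, 0)
  es <- expected_states(dens, 2)
  expect_equal(es$eta_bar, -1)
  expect_equal(es$mu_bar, -1)
  Pi <- ex22_precision(); Pi[1, 3] <- Pi[3, 1] <- 0.5
  leaky <- stationary_density(Pi, blanket_partition(1, 1, 0, 1))
  expect_error(conditional_given_blanket(leaky, 1), "no Markov blanket")
})

test_that("expected_states matches conditional_given_blanket on random inputs", {
  dens <- random_fixture(11)
  set.seed(42)
  for (i in 1:100) {
    b <- rnorm(dens$partition$d_b)
    es <- expected_states(dens, b)
    cond <- conditional_given_blanket(dens, b)
    expect_equal(es$eta_bar, cond$eta$mean)
    expect_equal(es$mu_bar, cond$mu$mean)
  }
})

test_that("conditional covariance identity holds under the blanket", {
  for (seed in c(3, 7, 21)) {
    dens <- random_fixture(seed)
    S_e <- dblock(dens, "eta", "eta")
    S_eb <- dblock(dens, "eta", "b")
    S_b <- dblock(dens, "b", "b")
    lhs <- S_e - S_eb %*% solve(S_b, t(S_eb))
    rhs <- solve(dblock(dens, "eta", "eta", of = "precision"))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("sampled blanket precisions are deterministic, sparse and positive-definite", {
  p <- blanket_partition(2, 1, 1, 2)
  d1 <- sample_blanket_precision(p, 5)
  d2 <- sample_blanket_precision(p, 5)
  expect_identical(d1$precision, d2$precision)
  for (seed in 1:25) {
    dens <- sample_blanket_precision(p, seed)
    expect_true(is_markov_blanket(dens))
    expect_identical(max(abs(dblock(dens, "eta", "mu", of = "precision"))), 0)
    ev <- eigen(dens$precision, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
  }
})

test_that("stationary sampling reproduces moments and respects seeds and means", {
  dens <- ex22_density()
  X <- sample_stationary(dens, 1e5, seed = 7)
  Sig <- dens$covariance
  # entrywise 5 standard errors, se ~ sqrt((S_ii S_jj + S_ij^2)/n)
  for (i in 1:3) for (j in 1:3) {
    se <- sqrt((Sig[i, i] * Sig[j, j] + Sig[i, j]^2) / nrow(X))
    expect_lt(abs(stats::cov(X)[i, j] - Sig[i, j]), 5 * se)
  }
  expect_identical(X, sample_stationary(dens, 1e5, seed = 7))
  shifted <- stationary_density(ex22_precision(), blanket_partition(1, 1, 0, 1),
                                mean = c(1, 1, 1))
  Y <- sample_stationary(shifted, 2e4, seed = 1)
  expect_equal(unname(colMeans(Y)), c(1, 1, 1), tolerance = 0.05)
  expect_error(sample_stationary(dens, 0, seed = 1), "positive")
})
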