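test_that("beliefs have the synchronization-map mean and posterior precision", {
  dens <- ex22_density()
  m <- build_sync_map(dens)
  q0 <- belief_of(0, m, dens)
  expect_equal(q0$mean, 0)
  expect_equal(as.numeric(q0$precision), 2)
  # belief at mu(b) equals the true posterior p(eta | b)
  b <- 1.7
  es <- expected_states(dens, b)
  q <- belief_of(es$mu_bar, m, dens)
  cond <- conditional_given_blanket(dens, b)
  expect_equal(q$mean, cond$eta$mean)
  expect_equal(q$precision, cond$eta$precision)
  # equal predictions give identical beliefs
  expect_equal(belief_of(0.5, m, dens), belief_of(0.5, m, dens))
})

test_that("KL to the posterior is the precision-weighted squared gap", {
  dens <- ex22_density()
  m <- build_sync_map(dens)
  expect_equal(kl_to_posterior(1, 0, dens, m), 1)        # 0.5 * 1 * 2 * 1
  expect_equal(kl_to_posterior(expected_states(dens, 2)$mu_bar, 2, dens, m), 0)
  set.seed(8)
  for (i in 1:200) {
    kl <- kl_to_posterior(rnorm(1), rnorm(1), dens, m)
    expect_gte(kl, 0)
  }
})

test_that("free energy carries full constants and both decompositions are exact", {
  dens <- ex22_density()
  m <- build_sync_map(dens)
  fe <- free_energy(0, 0, dens, m)
  expect_equal(fe$total, 0.5 * log(2 * pi^2))   # det Sigma_{b:mu} = 0.5
  expect_equal(fe$kl, 0)
  set.seed(31)
  fixtures <- c(list(dens), lapply(1:5, random_fixture))
  for (dd in fixtures) {
    mm <- build_sync_map(dd)
    for (i in 1:20) {
      b <- rnorm(dd$partition$d_b); mu <- rnorm(dd$partition$d_mu)
      f <- free_energy(b, mu, dd, mm)
      expect_equal(f$total, f$kl + f$neg_log_joint_particular, tolerance = 1e-12)
      expect_equal(f$total, f$energy - f$entropy, tolerance = 1e-10)
      expect_equal(f$kl, kl_to_posterior(mu, b, dd, mm), tolerance = 1e-12)
    }
  }
})

test_that("the free-energy minimizer is the expected internal state", {
  dens <- ex22_density()
  m <- build_sync_map(dens)
  expect_equal(minimize_free_energy(2, dens, m), -1)
  expect_equal(minimize_free_energy(0, dens, m), 0)
  set.seed(77)
  for (seed in 1:20) {
    dd <- random_fixture(seed)
    mm <- build_sync_map(dd)
    for (i in 1:5) {
      b <- rnorm(dd$partition$d_b)
      mu_hat <- minimize_free_energy(b, dd, mm)
      expect_lt(max(abs(mu_hat - expected_states(dd, b)$mu_bar)), 1e-6)
    }
  }
})

test_that("the closed-form minimizer agrees with an independent numeric optimizer", {
  dd <- random_fixture(13)
  mm <- build_sync_map(dd)
  b <- c(0.8, -1.4)
  f_obj <- function(mu) free_energy(b, mu, dd, mm)$total
  num <- stats::optim(rep(0, dd$partition$d_mu), f_obj, method = "BFGS",
                      control = list(reltol = 1e-14))$par
  expect_equal(minimize_free_energy(b, dd, mm), num, tolerance = 1e-5)
})

test_that("prediction errors follow the precision-weighted residual formula", {
  dens <- ex22_density()
  m <- build_sync_map(dens)
  expect_equal(prediction_error(1, 0, dens, m), 2)
  b <- -0.6
  es <- expected_states(dens, b)
  expect_equal(prediction_error(es$eta_bar, es$mu_bar, dens, m), 0)
})

test_that("steady-state prediction errors have mean zero and covariance Pi_eta", {
  dens <- random_fixture(21)
  m <- build_sync_map(dens)
  p <- dens$partition
  X <- sample_stationary(dens, 5e4, seed = 4)
  Bm <- X[, part_idx(p, "b"), drop = FALSE]
  gain_m <- dblock(dens, "mu", "b") %*% solve(dblock(dens, "b", "b"))
  Mu_exp <- Bm %*% t(gain_m)
  gap <- X[, part_idx(p, "eta"), drop = FALSE] - Mu_exp %*% t(m$matrix)
  Xi <- gap %*% dblock(dens, "eta", "eta", of = "precision")
  Pi_eta <- dblock(dens, "eta", "eta", of = "precision")
  for (j in seq_len(p$d_eta)) {
    se <- sqrt(Pi_eta[j, j] / nrow(Xi))
    expect_lt(abs(mean(Xi[, j])), 5 * se)
  }
  emp <- stats::cov(Xi)
  for (i in seq_len(p$d_eta)) for (j in seq_len(p$d_eta)) {
    se <- sqrt((Pi_eta[i, i] * Pi_eta[j, j] + Pi_eta[i, j]^2) / nrow(Xi))
    expect_lt(abs(emp[i, j] - Pi_eta[i, j]), 5 * se)
  }
})

test_that("unperturbed ensembles keep a flat mean free energy", {
  mod <- remark32_model()
  out <- relaxation_experiment(mod, b0 = NULL, n_paths = 400, dt = 5e-3,
                               t_end = 2, seed = 6, record_every = 40)
  ref <- stationary_free_energy(mod$density, build_sync_map(mod$density),
                                n = 2e4, seed = 7)
  dev <- abs(out$mean_F - ref$mean) / sqrt(out$se_F^2 + ref$se^2)
  expect_lt(stats::median(dev), 4)
  expect_lt(abs(out$mean_F[1] - out$mean_F[nrow(out)]) /
              sqrt(out$se_F[1]^2 + out$se_F[nrow(out)]^2), 4)
})

test_that("clamping the blanket at its mean starts F at the conditional floor", {
  # b0 = 0 is the mildest conditioning: KL = 0 and the log joint is
  # maximal, so mean F begins at its floor and relaxes upward by well
  # under a nat to the stationary level
  mod <- remark32_model()
  out <- relaxation_experiment(mod, b0 = 0, n_paths = 300, dt = 5e-3,
                               t_end = 4, seed = 6, record_every = 40)
  m <- build_sync_map(mod$density)
  expect_equal(out$mean_F[1], free_energy(0, 0, mod$density, m)$total,
               tolerance = 1e-10)
  ref <- stationary_free_energy(mod$density, m, n = 2e4, seed = 7)
  expect_gt(ref$mean, out$mean_F[1])
  last <- nrow(out)
  expect_lt(abs(out$mean_F[last] - ref$mean) /
              sqrt(out$se_F[last]^2 + ref$se^2), 4)
})

test_that("relaxation from an improbable blanket state decreases the mean free energy", {
  pre <- get_preset("fig6_like")
  mod <- pre$model
  b0 <- improbable_blanket(mod$density, 3)
  out <- relaxation_experiment(mod, b0, n_paths = 400, dt = 5e-3, t_end = 4,
                               seed = 2, record_every = 40,
                               internal_mode = "realized")
  expect_gt(out$mean_F[1], out$mean_F[nrow(out)])
  ref <- stationary_free_energy(mod$density, build_sync_map(mod$density),
                                n = 2e4, seed = 3, internal_mode = "realized")
  final_dev <- abs(out$mean_F[nrow(out)] - ref$mean) /
    sqrt(out$se_F[nrow(out)]^2 + ref$se^2)
  expect_lt(final_dev, 3)
})

test_that("improbable blanket preset displaces the first coordinate by k sds", {
  dens <- random_fixture(2)
  b0 <- improbable_blanket(dens, 3)
  expect_equal(b0[1], 3 * sqrt(dblock(dens, "b", "b")[1, 1]))
  expect_equal(b0[-1], rep(0, dens$partition$d_b - 1))
})
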