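test_that("the worked solenoidal model reproduces its printed drift", {
  mod <- remark32_model()
  expect_equal(drift_field(mod, c(1, 0, 0)), c(-1, -0.5, 2))
  B_expected <- -matrix(c(1, 1.5, 2,
                          0.5, 1, 0.5,
                          -2, -0.5, 1), 3, 3, byrow = TRUE)
  expect_equal(drift_matrix(mod), B_expected)
  # drift vanishes at the mean for constant fields
  expect_equal(drift_field(mod, c(0, 0, 0)), c(0, 0, 0))
})

test_that("Q must be antisymmetric and dimensions are checked", {
  dens <- ex22_density()
  expect_error(diffusion_model(dens, Q = diag(3)), "antisymmetric")
  mod <- remark32_model()
  expect_error(drift_field(mod, c(1, 0)), "length")
})

test_that("divergence of constant fields is exactly zero", {
  mod <- remark32_model()
  expect_identical(divergence_term(mod, c(0.3, -1, 2)), c(0, 0, 0))
})

test_that("finite-difference divergence recovers hand values and analytic fields", {
  dens <- ex22_density()
  # Q13 = x3 contributes (div)_1 = d/dx3 Q13 = 1; all else zero
  qf <- function(x) matrix(c(0, 0, x[3],
                             0, 0, 0,
                             -x[3], 0, 0), 3, 3, byrow = TRUE)
  mod <- diffusion_model(dens, Q = qf, divergence_mode = "finite_difference")
  x <- c(0.2, -0.7, 1.3)
  expect_equal(divergence_term(mod, x), c(1, 0, 0), tolerance = 1e-6)
  # analytic vs finite differences on a quadratic field
  qf2 <- function(x) matrix(c(0, x[1]^2, 0,
                              -x[1]^2, 0, x[2]^2,
                              0, -x[2]^2, 0), 3, 3, byrow = TRUE)
  # hand: (div)_1 = d/dx2(x1^2) = 0; (div)_2 = d/dx1(-x1^2) = -2 x1;
  #       (div)_3 = d/dx2(-x2^2) = -2 x2
  div2 <- function(x) c(0, -2 * x[1], -2 * x[2])
  m_an <- diffusion_model(dens, Q = qf2, divergence_mode = "analytic",
                          div_fun = div2)
  m_fd <- diffusion_model(dens, Q = qf2, divergence_mode = "finite_difference")
  for (x in list(c(1, 2, 3), c(-0.5, 0.1, 0))) {
    expect_equal(divergence_term(m_an, x), divergence_term(m_fd, x),
                 tolerance = 1e-6)
    expect_equal(drift_field(m_an, x), drift_field(m_fd, x), tolerance = 1e-6)
  }
})

test_that("the Lyapunov identity certifies stationarity of every constant model", {
  expect_lt(max(abs(stationarity_residual(remark32_model()))), 1e-12)
  dens <- ex22_density()
  expect_lt(max(abs(stationarity_residual(diffusion_model(dens)))), 1e-12)
  for (seed in 1:10) {
    d2 <- random_fixture(seed)
    Q <- blanketflow:::random_solenoidal(d2$partition$d, seed + 100, 2)
    m <- diffusion_model(d2, Q = Q)
    expect_lt(max(abs(stationarity_residual(m))), 1e-10)
  }
  # a drift NOT of the dissipative + solenoidal form fails the identity
  B_bad <- drift_matrix(remark32_model()) + diag(c(1, 0, 0))
  S <- dens$covariance
  expect_gt(max(abs(B_bad %*% S + S %*% t(B_bad) + diag(3))), 0.1)
})

test_that("closed-form transition moments have the right limits", {
  mod <- remark32_model()
  x0 <- c(1, -2, 0.5)
  t0 <- ou_transition_moments(mod, x0, 0)
  expect_equal(t0$mean, x0)
  expect_lt(max(abs(t0$covariance)), 1e-12)
  tinf <- ou_transition_moments(mod, x0, 50)
  expect_equal(tinf$mean, c(0, 0, 0), tolerance = 1e-8)
  expect_equal(tinf$covariance, mod$density$covariance, tolerance = 1e-8)
})

test_that("simulated ensembles match the closed-form transition moments", {
  mod <- remark32_model()
  x0 <- c(1, 0, -1)
  n <- 4000
  ens <- simulate_diffusion(mod, init = x0, dt = 2e-3, t_end = 0.5,
                            n_paths = n, seed = 12, record_every = 250)
  Xend <- ens$paths[, length(ens$times), ]
  cf <- ou_transition_moments(mod, x0, 0.5)
  for (j in 1:3) {
    se <- sqrt(cf$covariance[j, j] / n)
    expect_lt(abs(mean(Xend[, j]) - cf$mean[j]), 5 * se + 0.02)
  }
  emp_cov <- stats::cov(Xend)
  for (i in 1:3) for (j in 1:3) {
    se <- sqrt((cf$covariance[i, i] * cf$covariance[j, j] +
                  cf$covariance[i, j]^2) / n)
    expect_lt(abs(emp_cov[i, j] - cf$covariance[i, j]), 5 * se + 0.02)
  }
})

test_that("stationarity is preserved for ensembles started at the steady state", {
  mod <- remark32_model()
  n <- 5000
  ens <- simulate_diffusion(mod, init = "stationary", dt = 5e-3, t_end = 5e-3,
                            n_paths = n, seed = 5)
  Xend <- ens$paths[, length(ens$times), ]
  Sig <- mod$density$covariance
  for (i in 1:3) for (j in 1:3) {
    se <- sqrt((Sig[i, i] * Sig[j, j] + Sig[i, j]^2) / n)
    expect_lt(abs(stats::cov(Xend)[i, j] - Sig[i, j]), 5 * se + 5e-3)
  }
})

test_that("noiseless conservative flow preserves the quadratic invariant", {
  dens <- ex22_density()
  Q <- matrix(c(0, 0, 1, 0, 0, 0, -1, 0, 0), 3, 3, byrow = TRUE)
  mod <- diffusion_model(dens, sigma = matrix(0, 3, 3), Q = Q)
  x0 <- c(1, 0.5, -0.5)
  ens <- simulate_diffusion(mod, init = x0, dt = 1e-3, t_end = 5, seed = 1,
                            record_every = 100, method = "rk4")
  energy <- apply(ens$paths[1, , ], 1, function(x)
    as.numeric(crossprod(x, dens$precision %*% x)))
  expect_lt(max(abs(energy - energy[1])), 1e-8)
})

test_that("simulation is reproducible and path-count invariant", {
  mod <- remark32_model()
  e1 <- simulate_diffusion(mod, init = c(1, 0, 0), dt = 0.01, t_end = 0.1,
                           n_paths = 2, seed = 42)
  e2 <- simulate_diffusion(mod, init = c(1, 0, 0), dt = 0.01, t_end = 0.1,
                           n_paths = 5, seed = 42)
  expect_identical(e1$paths[1:2, , ], e2$paths[1:2, , ])
  expect_error(simulate_diffusion(mod, init = c(1, 0, 0), dt = -1, t_end = 1,
                                  seed = 1), "positive")
})

test_that("blow-ups abort with the offending step index", {
  dens <- ex22_density()
  mod <- diffusion_model(dens, sigma = diag(3) * 30)  # Gamma huge -> unstable at dt = 1
  expect_error(simulate_diffusion(mod, init = c(1, 1, 1), dt = 1, t_end = 50,
                                  seed = 1), "step")
})
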