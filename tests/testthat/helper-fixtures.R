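# Fixtures built in code; the 3 x 3 worked example and seeded random
# blanket densities used across the suite.

ex22_precision <- function() {
  matrix(c(2, 1, 0,
           1, 2, 1,
           0, 1, 2), 3, 3, byrow = TRUE)
}

# hand-derived covariance oracle: adj(Pi) / det(Pi), det = 4
ex22_covariance <- function() {
  matrix(c(0.75, -0.5, 0.25,
           -0.5, 1.0, -0.5,
           0.25, -0.5, 0.75), 3, 3, byrow = TRUE)
}

ex22_density <- function() {
  stationary_density(ex22_precision(), blanket_partition(1, 1, 0, 1))
}

degenerate_density <- function() {
  # Pi_mu,b = 0 but Pi_eta,b != 0: the sync map exists only as the zero map
  Pi <- matrix(c(2, 1, 0,
                 1, 2, 0,
                 0, 0, 2), 3, 3, byrow = TRUE)
  stationary_density(Pi, blanket_partition(1, 1, 0, 1))
}

remark32_model <- function() {
  Q <- matrix(c(0, 0, 1,
                0, 0, 0,
                -1, 0, 0), 3, 3, byrow = TRUE)
  diffusion_model(ex22_density(), sigma = diag(3), Q = Q)
}

# random blanket fixture with d_b <= d_mu (sync map exists generically)
random_fixture <- function(seed, d_eta = 2, d_s = 1, d_a = 1, d_mu = 2) {
  sample_blanket_precision(blanket_partition(d_eta, d_s, d_a, d_mu), seed)
}

# generic Gaussian conditional mean of block `ir` given block `ic` = v
gaussian_cond_mean <- function(S, ir, ic, v) {
  as.numeric(S[ir, ic, drop = FALSE] %*% solve(S[ic, ic, drop = FALSE], v))
}
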