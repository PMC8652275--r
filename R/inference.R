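#' Belief over external states encoded by an internal state
#'
#' Associates with an internal state `mu` the Gaussian belief
#' `q_mu(eta) = N(eta; sigma(mu), Pi_eta^-1)`: the mean is the
#' synchronization-map prediction and the covariance is fixed to that of
#' the true posterior `p(eta | b)`.  The belief equals the true
#' posterior exactly when `mu` is the expected internal state `mu(b)`.
#'
#' @param mu internal vector of length `d_mu`.
#' @param map a [build_sync_map()] result.
#' @param density the underlying [stationary_density()].
#' @return a list of class `belief` with fields `mean` and `precision`.
#' @export
belief_of <- function(mu, map, density) {
  stopifnot(inherits(map, "sync_map"), inherits(density, "stationary_density"))
  structure(list(mean = predict_external(map, mu),
                 precision = dblock(density, "eta", "eta", of = "precision")),
            class = "belief")
}

#' Kullback-Leibler divergence from a belief to the true posterior
#'
#' Both distributions share the covariance `Pi_eta^-1`, so the KL
#' divergence reduces to the squared precision-weighted mean gap
#' `0.5 * (sigma(mu) - eta(b))' Pi_eta (sigma(mu) - eta(b))`.  Zero
#' exactly when the belief mean matches the posterior mean.
#'
#' @param mu internal vector.
#' @param b blanket vector.
#' @param density a [stationary_density()] satisfying the blanket condition.
#' @param map a [build_sync_map()] result.
#' @return nonnegative scalar (nats).
#' @export
kl_to_posterior <- function(mu, b, density, map) {
  gap <- predict_external(map, mu) - expected_states(density, b)$eta_bar
  0.5 * as.numeric(crossprod(gap, dblock(density, "eta", "eta", of = "precision") %*% gap))
}

#' Variational free energy of a particular state and internal belief
#'
#' Computes `F(b, mu) = KL[q_mu || p(. | b)] - log p(b, mu)` with all
#' additive normalization constants retained, so the two standard
#' decompositions hold as exact identities:
#' `total = kl + neg_log_joint_particular` and
#' `total = energy - entropy`, where energy is the belief-averaged
#' negative log joint density and entropy is the belief entropy.
#'
#' @inheritParams kl_to_posterior
#' @return a list of class `free_energy_breakdown` with scalar fields
#'   `total`, `kl`, `neg_log_joint_particular`, `energy`, `entropy`
#'   (all in nats).
#' @export
free_energy <- function(b, mu, density, map) {
  stopifnot(inherits(density, "stationary_density"), inherits(map, "sync_map"))
  p <- density$partition
  b <- as.numeric(b); mu <- as.numeric(mu)
  kl <- kl_to_posterior(mu, b, density, map)

  # -log p(b, mu): marginal Gaussian on the particular states
  S_p <- dblock(density, "bmu", "bmu")
  z <- c(b, mu) - density$mean[part_idx(p, "bmu")]
  d_p <- length(z)
  nlj <- 0.5 * (as.numeric(crossprod(z, solve(S_p, z))) +
                  d_p * log(2 * pi) + logdet_pd(S_p))

  # energy: E_q[-log p(x)] with eta ~ q_mu, (b, mu) fixed
  xhat <- c(predict_external(map, mu), b, mu) - density$mean
  Pi <- density$precision
  Pi_eta <- dblock(density, "eta", "eta", of = "precision")
  energy <- 0.5 * (as.numeric(crossprod(xhat, Pi %*% xhat)) + p$d_eta +
                     p$d * log(2 * pi) - logdet_pd(Pi))
  entropy <- 0.5 * (p$d_eta * (1 + log(2 * pi)) - logdet_pd(Pi_eta))

  structure(list(total = kl + nlj, kl = kl, neg_log_joint_particular = nlj,
                 energy = energy, entropy = entropy),
            class = "free_energy_breakdown")
}

#' @export
print.free_energy_breakdown <- function(x, ...) {
  cat(sprintf("Free energy: %.6f nats (KL %.6f  -log p(b,mu) %.6f | energy %.6f  entropy %.6f)\n",
              x$total, x$kl, x$neg_log_joint_particular, x$energy, x$entropy))
  invisible(x)
}

#' Minimize the free energy over internal states
#'
#' `F(b, .)` is a strictly convex quadratic in `mu`, so the minimizer is
#' obtained by a closed-form linear solve; the gradient at the solution
#' is verified against `solver_tol` and a diagnostic error is raised if
#' it fails.  The minimizer coincides with the expected internal state
#' `mu(b) = Sigma_mu,b Sigma_b^-1 b` whenever the synchronization map
#' exists.
#'
#' @inheritParams kl_to_posterior
#' @param solver_tol tolerance on the gradient norm at the reported
#'   minimizer (default `1e-8`).
#' @return internal vector of length `d_mu`.
#' @export
minimize_free_energy <- function(b, density, map, solver_tol = 1e-8) {
  stopifnot(inherits(density, "stationary_density"), inherits(map, "sync_map"))
  p <- density$partition
  b <- as.numeric(b)
  bc <- b - mean_block(density, "b")
  S <- map$matrix
  Pi_eta <- dblock(density, "eta", "eta", of = "precision")
  K <- solve(dblock(density, "bmu", "bmu"))           # precision of p(b, mu)
  ib <- seq_len(p$d_b); im <- p$d_b + seq_len(p$d_mu)
  K_mu <- K[im, im, drop = FALSE]
  K_mub <- K[im, ib, drop = FALSE]
  eta_bar <- expected_states(density, b)$eta_bar - mean_block(density, "eta")
  H <- crossprod(S, Pi_eta %*% S) + K_mu
  g <- crossprod(S, Pi_eta %*% eta_bar) - K_mub %*% bc
  mu_c <- solve(H, g)
  grad <- H %*% mu_c - g
  if (max(abs(grad)) > solver_tol * max(1, max(abs(g))))
    stop(sprintf("free-energy minimization did not converge (|grad| = %.3g)",
                 max(abs(grad))), call. = FALSE)
  as.numeric(mu_c) + mean_block(density, "mu")
}

#' Precision-weighted prediction error
#'
#' `xi = Pi_eta (eta - sigma(mu))` in centered coordinates.  The caller
#' chooses the convention: `eta` may be a realized external sample or an
#' expected state `eta(b)`, and `mu` a realized internal state or
#' `mu(b)`.  With realized `eta` and expected `mu(b)` at steady state,
#' `xi` has mean zero and covariance `Pi_eta`.
#'
#' @param eta external vector.
#' @param mu internal vector.
#' @param density a [stationary_density()].
#' @param map a [build_sync_map()] result.
#' @return external vector of length `d_eta`.
#' @export
prediction_error <- function(eta, mu, density, map) {
  stopifnot(inherits(density, "stationary_density"), inherits(map, "sync_map"))
  gap <- (as.numeric(eta) - mean_block(density, "eta")) -
    as.numeric(map$matrix %*% (as.numeric(mu) - mean_block(density, "mu")))
  as.numeric(dblock(density, "eta", "eta", of = "precision") %*% gap)
}

# Vectorized free energy over rows of Bm (blanket) and Mm (internal);
# returns the per-row total F.  Same algebra as free_energy().
free_energy_rows <- function(Bm, Mm, density, map) {
  p <- density$partition
  Bc <- sweep(Bm, 2, mean_block(density, "b"))
  Mc <- sweep(Mm, 2, mean_block(density, "mu"))
  S_b <- dblock(density, "b", "b")
  gain_e <- dblock(density, "eta", "b") %*% solve(S_b)
  Pi_eta <- dblock(density, "eta", "eta", of = "precision")
  pred <- Mc %*% t(map$matrix)
  gap <- pred - Bc %*% t(gain_e)
  kl <- 0.5 * quad_rows(gap, Pi_eta)
  S_p <- dblock(density, "bmu", "bmu")
  Z <- cbind(Bc, Mc)
  nlj <- 0.5 * (quad_rows(Z, solve(S_p)) + ncol(Z) * log(2 * pi) + logdet_pd(S_p))
  kl + nlj
}

#' Stationary expectation of the free energy
#'
#' Monte-Carlo estimate of `E_p[F(b, mu)]` under the steady state, with
#' the internal argument taken as the expected state `mu(b)`
#' (`internal_mode = "expected"`) or as the realized sample
#' (`"realized"`).  Serves as the reference level that relaxation
#' experiments converge to.
#'
#' @param density a [stationary_density()].
#' @param map a [build_sync_map()] result.
#' @param n number of i.i.d. draws.
#' @param seed integer seed.
#' @param internal_mode `"expected"` or `"realized"`.
#' @return list with `mean`, `se` and the per-draw values `F`.
#' @export
stationary_free_energy <- function(density, map, n = 1e4, seed = 1,
                                   internal_mode = c("expected", "realized")) {
  internal_mode <- match.arg(internal_mode)
  p <- density$partition
  X <- sample_stationary(density, n, seed)
  Bm <- X[, part_idx(p, "b"), drop = FALSE]
  Mm <- if (internal_mode == "realized") X[, part_idx(p, "mu"), drop = FALSE]
  else {
    Bc <- sweep(Bm, 2, mean_block(density, "b"))
    gain_m <- dblock(density, "mu", "b") %*% solve(dblock(density, "b", "b"))
    sweep(Bc %*% t(gain_m), 2, mean_block(density, "mu"), `+`)
  }
  Fv <- free_energy_rows(Bm, Mm, density, map)
  list(mean = mean(Fv), se = stats::sd(Fv) / sqrt(length(Fv)), F = Fv)
}

#' Relaxation from an improbable blanket state
#'
#' Simulates an ensemble of constant-coefficient stationary diffusions
#' initialized at the steady state conditioned on a blanket value `b0`
#' (`eta` and `mu` drawn independently from their conditionals, `b`
#' clamped to `b0`), and records how the mean free energy and the
#' precision-weighted prediction errors relax towards their stationary
#' levels.  `internal_mode = "expected"` evaluates `F(b_t, mu(b_t))`
#' (the event-averaged protocol); `"realized"` evaluates
#' `F(b_t, mu_t)` with the simulated internal states.
#'
#' @param model a constant-coefficient [diffusion_model()].
#' @param b0 blanket vector of length `d_b`, or `NULL` to skip the
#'   conditioning and start every path from the full steady state (the
#'   unperturbed control condition, under which the mean free energy is
#'   flat).  Note that clamping the blanket even at its mean value is a
#'   mild perturbation: the free energy then starts at its conditional
#'   floor and relaxes upward to the stationary level.
#' @param n_paths number of trajectories (default 500).
#' @param dt integration step (default 1e-3).
#' @param t_end final time (default 5).
#' @param seed integer seed.
#' @param internal_mode `"expected"` or `"realized"`.
#' @param record_every record every this many steps (default 10).
#' @param map optional precomputed [build_sync_map()].
#' @return data frame with columns `time`, `mean_F`, `se_F` and
#'   `mean_xi_*` (one per external coordinate).  Attributes: `F_paths`
#'   (per-path free energy at every recorded time), `xi_final`
#'   (per-path prediction errors at the final time), `ensemble` (the
#'   raw trajectories).
#' @export
relaxation_experiment <- function(model, b0, n_paths = 500, dt = 1e-3,
                                  t_end = 5, seed = 1,
                                  internal_mode = c("expected", "realized"),
                                  record_every = 10, map = NULL) {
  stopifnot(inherits(model, "diffusion_model"))
  if (!model$constant_fields)
    stop("relaxation experiments use constant-coefficient models", call. = FALSE)
  internal_mode <- match.arg(internal_mode)
  density <- model$density
  p <- density$partition
  if (!is.null(b0) && length(b0) != p$d_b)
    stop("b0 has wrong length", call. = FALSE)
  map <- map %||% build_sync_map(density)

  X0 <- if (is.null(b0))
    sample_stationary(density, n_paths, derive_seed(seed, 0))
  else conditional_initial_states(density, clamp = "b", value = b0,
                                  n = n_paths, seed = derive_seed(seed, 0))
  ens <- simulate_diffusion(model, init = X0, dt = dt, t_end = t_end,
                            n_paths = n_paths, seed = seed,
                            record_every = record_every)
  n_t <- length(ens$times)
  gain_m <- dblock(density, "mu", "b") %*% solve(dblock(density, "b", "b"))
  Fmat <- matrix(NA_real_, n_paths, n_t)
  Xi_mean <- matrix(NA_real_, n_t, p$d_eta)
  Pi_eta <- dblock(density, "eta", "eta", of = "precision")
  for (it in seq_len(n_t)) {
    Xt <- ens$paths[, it, , drop = FALSE]
    dim(Xt) <- dim(ens$paths)[c(1, 3)]
    Bm <- Xt[, part_idx(p, "b"), drop = FALSE]
    Mu_exp <- sweep(sweep(Bm, 2, mean_block(density, "b")) %*% t(gain_m),
                    2, mean_block(density, "mu"), `+`)
    Mm <- if (internal_mode == "expected") Mu_exp
    else Xt[, part_idx(p, "mu"), drop = FALSE]
    Fmat[, it] <- free_energy_rows(Bm, Mm, density, map)
    Em <- sweep(Xt[, part_idx(p, "eta"), drop = FALSE], 2, mean_block(density, "eta"))
    gap <- Em - sweep(Mm, 2, mean_block(density, "mu")) %*% t(map$matrix)
    Xi_mean[it, ] <- colMeans(gap %*% Pi_eta)
    if (it == n_t) xi_final <- gap %*% Pi_eta
  }
  out <- data.frame(time = ens$times,
                    mean_F = colMeans(Fmat),
                    se_F = apply(Fmat, 2, stats::sd) / sqrt(n_paths))
  colnames(Xi_mean) <- paste0("mean_xi_", seq_len(p$d_eta))
  out <- cbind(out, as.data.frame(Xi_mean))
  attr(out, "F_paths") <- Fmat
  attr(out, "xi_final") <- xi_final
  attr(out, "ensemble") <- ens
  out
}

# Draw n initial states with one block clamped and the complementary
# blocks sampled from their exact Gaussian conditional.
# clamp = "b" uses the factorized blanket conditionals; clamp = "s"
# uses generic conditioning of (eta, a, mu) on the sensory block.
conditional_initial_states <- function(density, clamp = c("b", "s"),
                                       value, n, seed) {
  clamp <- match.arg(clamp)
  p <- density$partition
  d <- p$d
  ic <- part_idx(p, clamp)
  ir <- setdiff(seq_len(d), ic)
  S <- density$covariance
  mean_r <- density$mean[ir] +
    S[ir, ic, drop = FALSE] %*%
    solve(S[ic, ic, drop = FALSE], as.numeric(value) - density$mean[ic])
  cov_r <- symm(S[ir, ir, drop = FALSE] -
                  S[ir, ic, drop = FALSE] %*%
                  solve(S[ic, ic, drop = FALSE], S[ic, ir, drop = FALSE]))
  R <- chol(cov_r + 1e-12 * diag(length(ir)))
  Z <- with_seed(seed, matrix(stats::rnorm(n * length(ir)), n, length(ir)))
  Xr <- Z %*% R + matrix(mean_r, n, length(ir), byrow = TRUE)
  X0 <- matrix(NA_real_, n, d)
  X0[, ic] <- matrix(as.numeric(value), n, length(ic), byrow = TRUE)
  X0[, ir] <- Xr
  X0
}

#' An improbable blanket state
#'
#' Returns the blanket vector displaced from the mean by `k` marginal
#' standard deviations along the first blanket coordinate -- the default
#' "surprising stimulus" used by the relaxation experiments.
#'
#' @param density a [stationary_density()].
#' @param k displacement in marginal standard deviations (default 3).
#' @return blanket vector of length `d_b`.
#' @export
improbable_blanket <- function(density, k = 3) {
  p <- density$partition
  b0 <- mean_block(density, "b")
  b0[1] <- b0[1] + k * sqrt(dblock(density, "b", "b")[1, 1])
  b0
}
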