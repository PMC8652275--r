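#' Expected active states given sensory states
#'
#' The conditional mean `a(s) = Sigma_a,s Sigma_s^-1 s` (centered
#' coordinates): the action that active inference and optimal stochastic
#' control single out in response to a sensory state.
#'
#' @param density a [stationary_density()] with `d_s >= 1` and `d_a >= 1`.
#' @param s sensory vector of length `d_s`.
#' @return active vector of length `d_a`.
#' @export
expected_action <- function(density, s) {
  stopifnot(inherits(density, "stationary_density"))
  p <- density$partition
  if (p$d_a < 1 || p$d_s < 1)
    stop("expected_action needs d_s >= 1 and d_a >= 1", call. = FALSE)
  s <- as.numeric(s)
  if (length(s) != p$d_s) stop("s has wrong length", call. = FALSE)
  sc <- s - mean_block(density, "s")
  as.numeric(dblock(density, "a", "s") %*%
               solve(dblock(density, "s", "s"), sc)) + mean_block(density, "a")
}

#' Control gain matrix of the steady state
#'
#' The precision matrix of the particular states,
#' `K = Sigma_(s,a,mu)^-1`, interpreted as the gain matrix of the
#' quadratic control objective: deviations of `(s, a, mu)` from their
#' set-point are penalized in the metric `K`.
#'
#' @param density a [stationary_density()].
#' @return an object of class `control_spec` with fields `gain` (the
#'   `(d_b + d_mu)`-dimensional matrix `K`) and `partition`.
#' @export
control_gain_matrix <- function(density) {
  stopifnot(inherits(density, "stationary_density"))
  S_p <- dblock(density, "bmu", "bmu")
  K <- tryCatch(symm(solve(S_p)),
                error = function(e) stop("particular-state covariance block is ",
                                         "numerically singular", call. = FALSE))
  structure(list(gain = K, partition = density$partition,
                 mean_bmu = density$mean[part_idx(density$partition, "bmu")]),
            class = "control_spec")
}

#' @export
print.control_spec <- function(x, ...) {
  p <- x$partition
  cat(sprintf("Control gain K (%d x %d) over (s, a, mu) = (%d, %d, %d)\n",
              nrow(x$gain), ncol(x$gain), p$d_s, p$d_a, p$d_mu))
  invisible(x)
}

#' Quadratic control objective
#'
#' Evaluates `[s, a, mu] K [s, a, mu]'` (centered at the set-point):
#' the cost the expected autonomous states minimize.
#'
#' @param spec a [control_gain_matrix()] result.
#' @param s sensory vector.
#' @param a active vector (length 0 allowed when `d_a = 0`).
#' @param mu internal vector.
#' @return nonnegative scalar.
#' @export
control_objective <- function(spec, s, a, mu) {
  stopifnot(inherits(spec, "control_spec"))
  z <- c(as.numeric(s), as.numeric(a), as.numeric(mu)) - spec$mean_bmu
  if (length(z) != nrow(spec$gain))
    stop("(s, a, mu) has wrong total length", call. = FALSE)
  as.numeric(crossprod(z, spec$gain %*% z))
}

#' Optimal autonomous states given a sensory state
#'
#' Closed-form minimizer of the quadratic objective over `(a, mu)` at
#' fixed `s` (a block solve in the gain matrix).  Because `K` is the
#' precision of `p(s, a, mu)`, this minimizer equals the conditional
#' expectation `E[(a, mu) | s]`.
#'
#' @param spec a [control_gain_matrix()] result with `d_a >= 1`.
#' @param s sensory vector.
#' @return list with components `a` and `mu`.
#' @export
optimal_autonomous <- function(spec, s) {
  stopifnot(inherits(spec, "control_spec"))
  p <- spec$partition
  if (p$d_a < 1) stop("optimal_autonomous needs d_a >= 1", call. = FALSE)
  s <- as.numeric(s)
  if (length(s) != p$d_s) stop("s has wrong length", call. = FALSE)
  is_ <- seq_len(p$d_s)
  iam <- p$d_s + seq_len(p$d_a + p$d_mu)
  K <- spec$gain
  sc <- s - spec$mean_bmu[is_]
  am <- -solve(K[iam, iam, drop = FALSE],
               K[iam, is_, drop = FALSE] %*% sc)
  am <- as.numeric(am) + spec$mean_bmu[iam]
  list(a = am[seq_len(p$d_a)], mu = am[p$d_a + seq_len(p$d_mu)])
}

#' Active relaxation from an improbable sensory state
#'
#' Simulates an ensemble initialized at the steady state conditioned on
#' a sensory value `s0` (the remaining coordinates drawn from their
#' exact Gaussian conditional), and records the realized sensory and
#' active trajectories, the optimal action `a(s_t)`, the mean distance
#' between realized and optimal actions, and the free energy of the
#' expected internal state.
#'
#' @param model a constant-coefficient [diffusion_model()] whose
#'   partition has `d_s >= 1` and `d_a >= 1`.
#' @param s0 sensory vector of length `d_s`.
#' @param n_paths,dt,t_end,seed,record_every as in
#'   [relaxation_experiment()].
#' @param map optional precomputed [build_sync_map()].
#' @return data frame with columns `time`, `mean_s_*`, `mean_a_*`,
#'   `mean_a_opt_*`, `mean_action_gap`, `se_action_gap`, `mean_F`,
#'   `se_F`.  Attribute `ensemble` holds the raw trajectories.
#' @export
active_relaxation_experiment <- function(model, s0, n_paths = 500, dt = 1e-3,
                                         t_end = 5, seed = 1,
                                         record_every = 10, map = NULL) {
  stopifnot(inherits(model, "diffusion_model"))
  if (!model$constant_fields)
    stop("active relaxation uses constant-coefficient models", call. = FALSE)
  density <- model$density
  p <- density$partition
  if (p$d_a < 1 || p$d_s < 1)
    stop("active relaxation needs d_s >= 1 and d_a >= 1", call. = FALSE)
  if (length(s0) != p$d_s) stop("s0 has wrong length", call. = FALSE)
  map <- map %||% build_sync_map(density)

  X0 <- conditional_initial_states(density, clamp = "s", value = s0,
                                   n = n_paths, seed = derive_seed(seed, 0))
  ens <- simulate_diffusion(model, init = X0, dt = dt, t_end = t_end,
                            n_paths = n_paths, seed = seed,
                            record_every = record_every)
  n_t <- length(ens$times)
  gain_a <- dblock(density, "a", "s") %*% solve(dblock(density, "s", "s"))
  gain_m <- dblock(density, "mu", "b") %*% solve(dblock(density, "b", "b"))
  rows <- vector("list", n_t)
  for (it in seq_len(n_t)) {
    Xt <- ens$paths[, it, , drop = FALSE]
    dim(Xt) <- dim(ens$paths)[c(1, 3)]
    Sm <- Xt[, part_idx(p, "s"), drop = FALSE]
    Am <- Xt[, part_idx(p, "a"), drop = FALSE]
    Aopt <- sweep(sweep(Sm, 2, mean_block(density, "s")) %*% t(gain_a),
                  2, mean_block(density, "a"), `+`)
    gapn <- sqrt(rowSums((Am - Aopt)^2))
    Bm <- Xt[, part_idx(p, "b"), drop = FALSE]
    Mu_exp <- sweep(sweep(Bm, 2, mean_block(density, "b")) %*% t(gain_m),
                    2, mean_block(density, "mu"), `+`)
    Fv <- free_energy_rows(Bm, Mu_exp, density, map)
    rows[[it]] <- c(time = ens$times[it],
                    veccols("mean_s", colMeans(Sm)),
                    veccols("mean_a", colMeans(Am)),
                    veccols("mean_a_opt", colMeans(Aopt)),
                    mean_action_gap = mean(gapn),
                    se_action_gap = stats::sd(gapn) / sqrt(n_paths),
                    mean_F = mean(Fv),
                    se_F = stats::sd(Fv) / sqrt(n_paths))
  }
  out <- as.data.frame(do.call(rbind, rows))
  attr(out, "ensemble") <- ens
  out
}

#' Stationary level of the action gap
#'
#' Monte-Carlo estimate of `E ||a - a(s)||` under the steady state: the
#' reference level the active relaxation statistics settle at.
#'
#' @param density a [stationary_density()] with `d_s, d_a >= 1`.
#' @param n number of i.i.d. draws.
#' @param seed integer seed.
#' @return list with `mean` and `se`.
#' @export
stationary_action_gap <- function(density, n = 1e4, seed = 1) {
  p <- density$partition
  X <- sample_stationary(density, n, seed)
  Sm <- X[, part_idx(p, "s"), drop = FALSE]
  Am <- X[, part_idx(p, "a"), drop = FALSE]
  gain_a <- dblock(density, "a", "s") %*% solve(dblock(density, "s", "s"))
  Aopt <- sweep(sweep(Sm, 2, mean_block(density, "s")) %*% t(gain_a),
                2, mean_block(density, "a"), `+`)
  g <- sqrt(rowSums((Am - Aopt)^2))
  list(mean = mean(g), se = stats::sd(g) / sqrt(n))
}
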