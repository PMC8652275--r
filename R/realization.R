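#' Build a linear integrator chain
#'
#' Constructs the nested linear diffusion
#' `ds(i) = (A_i s(i) + C_i s(i+1)) dt + vol_i dW(i)` for
#' `i = 0, ..., n-1` and `ds(n) = A_n s(n) dt + vol_n dW(n)`: an
#' integrator chain whose levels encode successive orders of motion
#' (integral, position, velocity, ...).  The stacked system must be
#' stable (all drift eigenvalues with negative real part) so that a
#' stationary density exists; it is computed by a Lyapunov solve.  The
#' output process is `s_t = f(s~_t) = sum_i F_i s(i)_t`.
#'
#' @param order chain order `n >= 0`.
#' @param self list of `n + 1` square matrices (or scalars) `A_i`, the
#'   within-level drifts.
#' @param coupling list of `n` matrices `C_i` coupling level `i` to
#'   level `i + 1` (empty for `order = 0`).
#' @param volatility list of `n + 1` volatility matrices (or scalars).
#' @param output optional list of `n + 1` output matrices `F_i`;
#'   default selects level 1 (`F_1 = I`) when `order >= 1`, else level 0
#'   -- the proportional output convention.
#' @return an object of class `integrator_chain` with fields `order`,
#'   `A` (stacked drift), `vol` (stacked volatility), `Sigma`
#'   (stationary covariance of the stacked state), `f` (output matrix),
#'   `F_blocks`, `level_dims`, `level_index`.
#' @export
build_chain <- function(order, self, coupling = list(), volatility,
                        output = NULL) {
  if (order != round(order) || order < 0)
    stop("order must be a nonnegative integer", call. = FALSE)
  n <- as.integer(order)
  as_m <- function(x) if (is.matrix(x)) x else matrix(as.numeric(x),
                                                      length(x), length(x)) * diag(length(x))
  self <- lapply(self, as_m)
  volatility <- lapply(volatility, as_m)
  coupling <- lapply(coupling, function(x) if (is.matrix(x)) x else as_m(x))
  if (length(self) != n + 1 || length(volatility) != n + 1)
    stop("self and volatility must each have order + 1 entries", call. = FALSE)
  if (length(coupling) != n)
    stop("coupling must have `order` entries", call. = FALSE)
  k <- vapply(self, nrow, 1L)
  offs <- cumsum(c(0L, k))
  d <- offs[n + 2]
  level_index <- lapply(seq_len(n + 1), function(i) offs[i] + seq_len(k[i]))
  A <- matrix(0, d, d)
  V <- matrix(0, d, d)
  for (i in seq_len(n + 1)) {
    A[level_index[[i]], level_index[[i]]] <- self[[i]]
    V[level_index[[i]], level_index[[i]]] <- volatility[[i]]
    if (i <= n) A[level_index[[i]], level_index[[i + 1]]] <- coupling[[i]]
  }
  ev <- eigen(A, only.values = TRUE)$values
  if (max(Re(ev)) >= 0)
    stop(sprintf("chain drift is not stable; eigenvalue real parts: %s",
                 paste(sprintf("%.4g", Re(ev)), collapse = ", ")), call. = FALSE)
  Sigma <- lyapunov_solve(A, tcrossprod(V))
  if (is.null(output)) {
    lev <- if (n >= 1) 2L else 1L
    output <- rep(list(NULL), n + 1)
    output[[lev]] <- diag(k[lev])
  }
  out_dim <- NULL
  for (i in seq_len(n + 1)) if (!is.null(output[[i]])) {
    output[[i]] <- as.matrix(output[[i]])
    out_dim <- out_dim %||% nrow(output[[i]])
  }
  if (is.null(out_dim)) stop("output must select at least one level", call. = FALSE)
  f <- matrix(0, out_dim, d)
  F_blocks <- vector("list", n + 1)
  for (i in seq_len(n + 1)) {
    F_blocks[[i]] <- if (is.null(output[[i]])) matrix(0, out_dim, k[i])
    else output[[i]]
    f[, level_index[[i]]] <- F_blocks[[i]]
  }
  structure(list(order = n, A = A, vol = V, Sigma = Sigma, f = f,
                 F_blocks = F_blocks, level_dims = k,
                 level_index = level_index),
            class = "integrator_chain")
}

#' @export
print.integrator_chain <- function(x, ...) {
  cat(sprintf("Integrator chain: order %d, stacked dimension %d, output dim %d\n",
              x$order, nrow(x$A), nrow(x$f)))
  invisible(x)
}

#' Autocovariance of the chain output process
#'
#' Analytic mode evaluates `C(tau) = f exp(A tau) Sigma~ f'` on the
#' stationary chain; empirical mode estimates lagged sample averages
#' from a single long Euler-Maruyama trajectory started at stationarity
#' (after a burn-in).  Negative lags are rejected: by stationarity
#' `C(-tau) = C(tau)'`.
#'
#' @param chain a [build_chain()] result.
#' @param lags nonnegative time lags.
#' @param mode `"analytic"` or `"empirical"`.
#' @param dt,n_steps,seed simulation parameters for empirical mode.
#' @param burn_in steps discarded before estimating (default
#'   `min(n_steps %/% 10, 10 / dt)`).
#' @return an object of class `autocovariance_table`: `lags`, `values`
#'   (list of matrices), `source`.
#' @export
chain_autocovariance <- function(chain, lags, mode = c("analytic", "empirical"),
                                 dt = 0.01, n_steps = 1e5, seed = 1,
                                 burn_in = NULL) {
  stopifnot(inherits(chain, "integrator_chain"))
  mode <- match.arg(mode)
  lags <- as.numeric(lags)
  if (any(lags < 0))
    stop("negative lags rejected: C(-tau) = t(C(tau)) by stationarity",
         call. = FALSE)
  if (mode == "analytic") {
    vals <- lapply(lags, function(tau)
      chain$f %*% mat_expm(chain$A * tau) %*% chain$Sigma %*% t(chain$f))
  } else {
    d <- nrow(chain$A)
    burn_in <- as.integer(burn_in %||% min(n_steps %/% 10, ceiling(10 / dt)))
    R <- chol(chain$Sigma + 1e-12 * diag(d))
    x <- with_seed(derive_seed(seed, 0), as.numeric(stats::rnorm(d) %*% R))
    n_tot <- n_steps + burn_in
    Z <- with_seed(derive_seed(seed, 1), matrix(stats::rnorm(n_tot * d), n_tot, d))
    sdt <- sqrt(dt)
    S_out <- matrix(NA_real_, n_steps, nrow(chain$f))
    for (k in seq_len(n_tot)) {
      x <- x + dt * as.numeric(chain$A %*% x) + sdt * as.numeric(chain$vol %*% Z[k, ])
      if (k > burn_in) S_out[k - burn_in, ] <- chain$f %*% x
    }
    vals <- lapply(lags, function(tau) {
      kk <- round(tau / dt)
      if (kk >= n_steps) stop("lag exceeds simulated span", call. = FALSE)
      idx <- seq_len(n_steps - kk)
      crossprod(S_out[idx + kk, , drop = FALSE], S_out[idx, , drop = FALSE]) /
        length(idx)
    })
  }
  structure(list(lags = lags, values = vals, source = mode),
            class = "autocovariance_table")
}

#' @export
print.autocovariance_table <- function(x, ...) {
  cat(sprintf("Autocovariance table (%s): %d lag(s) in [%g, %g]\n",
              x$source, length(x$lags), min(x$lags), max(x$lags)))
  invisible(x)
}

#' Long-format view of an autocovariance table
#'
#' @param table an [chain_autocovariance()] result.
#' @return data frame with columns `lag`, `row`, `col`, `value`, `source`.
#' @export
as_long_autocovariance <- function(table) {
  stopifnot(inherits(table, "autocovariance_table"))
  do.call(rbind, lapply(seq_along(table$lags), function(i) {
    M <- table$values[[i]]
    data.frame(lag = table$lags[i],
               row = rep(seq_len(nrow(M)), ncol(M)),
               col = rep(seq_len(ncol(M)), each = nrow(M)),
               value = as.vector(M),
               source = table$source)
  }))
}

#' Control objective on the extended (chain) state
#'
#' Evaluates the quadratic objective with the sensory argument replaced
#' by the chain output, `[f(s~), a, mu] K [f(s~), a, mu]'`.  Reduces
#' exactly to [control_objective()] when the chain has order 0 and
#' identity output.
#'
#' @param spec a [control_gain_matrix()] result whose sensory dimension
#'   equals the chain's output dimension.
#' @param chain a [build_chain()] result.
#' @param s_tilde stacked chain state.
#' @param a active vector.
#' @param mu internal vector.
#' @return nonnegative scalar.
#' @export
extended_control_objective <- function(spec, chain, s_tilde, a, mu) {
  stopifnot(inherits(spec, "control_spec"), inherits(chain, "integrator_chain"))
  if (nrow(chain$f) != spec$partition$d_s)
    stop("chain output dimension does not match d_s", call. = FALSE)
  s_tilde <- as.numeric(s_tilde)
  if (length(s_tilde) != ncol(chain$f))
    stop("s_tilde has wrong length", call. = FALSE)
  control_objective(spec, as.numeric(chain$f %*% s_tilde), a, mu)
}

#' Per-order feedback gains of the extended control objective
#'
#' Writes the closed-form minimizer of the extended objective as a
#' linear feedback on the chain levels,
#' `a*(s~) = -sum_i L_i s(i)`, with
#' `L_i = [K_(a,mu)^-1 K_(a,mu),s]_a-rows F_i`.  The gains are defined
#' as these per-order coefficients; for an order-2 chain they are
#' labelled `integral`, `proportional` and `derivative`, recovering
#' PID-like control from the steady-state precision.
#'
#' @param spec a [control_gain_matrix()] result with `d_a >= 1`.
#' @param chain a [build_chain()] result (linear output).
#' @return list of `d_a x k_i` gain matrices `L_0 ... L_n`, named
#'   `integral`/`proportional`/`derivative` when `order = 2`, else
#'   `L0 ... Ln`.
#' @export
pid_gains <- function(spec, chain) {
  stopifnot(inherits(spec, "control_spec"), inherits(chain, "integrator_chain"))
  p <- spec$partition
  if (p$d_a < 1) stop("pid_gains needs d_a >= 1", call. = FALSE)
  if (nrow(chain$f) != p$d_s)
    stop("chain output dimension does not match d_s", call. = FALSE)
  is_ <- seq_len(p$d_s)
  iam <- p$d_s + seq_len(p$d_a + p$d_mu)
  K <- spec$gain
  G <- solve(K[iam, iam, drop = FALSE], K[iam, is_, drop = FALSE])
  G_a <- G[seq_len(p$d_a), , drop = FALSE]
  gains <- lapply(chain$F_blocks, function(Fi) G_a %*% Fi)
  names(gains) <- if (chain$order == 2) c("integral", "proportional", "derivative")
  else paste0("L", seq_along(gains) - 1)
  gains
}

#' Reconstruct the optimal action from per-order gains
#'
#' @param gains a [pid_gains()] result.
#' @param chain the matching [build_chain()] result.
#' @param s_tilde stacked chain state.
#' @return active vector `-sum_i L_i s(i)`.
#' @export
action_from_gains <- function(gains, chain, s_tilde) {
  s_tilde <- as.numeric(s_tilde)
  out <- 0
  for (i in seq_along(gains))
    out <- out - gains[[i]] %*% s_tilde[chain$level_index[[i]]]
  as.numeric(out)
}
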