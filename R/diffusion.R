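#' Stationary diffusion model with dissipative and solenoidal flow
#'
#' Defines the Ito diffusion
#' `dx = (Gamma + Q)(x) grad log p(x) dt + div(Gamma + Q)(x) dt + sigma(x) dW`
#' with `Gamma = sigma sigma' / 2` (symmetric positive-semidefinite
#' diffusion tensor, dissipative flow) and `Q` antisymmetric (solenoidal
#' flow).  Any such drift leaves the Gaussian density `p` stationary;
#' the divergence correction matters only for state-dependent fields.
#' `sigma == 0` is legal and yields a deterministic conservative flow
#' along the contours of `p`.
#'
#' @param density the Gaussian steady state, a [stationary_density()].
#' @param sigma volatility: a constant `d x m` matrix or a function
#'   `x -> matrix`.  Default: identity (`Gamma = I/2`).
#' @param Q solenoidal field: a constant antisymmetric `d x d` matrix or
#'   a function `x -> matrix`.  Default: zero.
#' @param divergence_mode one of `"zero"` (constant fields),
#'   `"analytic"` (requires `div_fun`), `"finite_difference"`.
#'   Default: `"zero"` when both fields are constant, otherwise
#'   `"finite_difference"`.
#' @param div_fun optional function `x -> vector` returning the row-wise
#'   divergence of `Gamma + Q` for `"analytic"` mode.
#' @return an object of class `diffusion_model`.
#' @export
diffusion_model <- function(density, sigma = NULL, Q = NULL,
                            divergence_mode = NULL, div_fun = NULL) {
  stopifnot(inherits(density, "stationary_density"))
  d <- density$partition$d
  if (is.null(sigma)) sigma <- diag(d)
  if (is.null(Q)) Q <- matrix(0, d, d)
  const_sigma <- is.matrix(sigma) || (is.numeric(sigma) && !is.function(sigma))
  const_Q <- is.matrix(Q) || (is.numeric(Q) && !is.function(Q))
  sigma_field <- if (const_sigma) {
    sm <- as.matrix(sigma)
    if (nrow(sm) != d) stop("sigma must have d rows", call. = FALSE)
    function(x) sm
  } else sigma
  q_field <- if (const_Q) {
    qm <- as.matrix(Q)
    stopifnot_square(qm, "Q")
    if (nrow(qm) != d) stop("Q must be d x d", call. = FALSE)
    function(x) qm
  } else Q
  constant_fields <- const_sigma && const_Q
  if (is.null(divergence_mode))
    divergence_mode <- if (constant_fields) "zero" else "finite_difference"
  divergence_mode <- match.arg(divergence_mode,
                               c("zero", "analytic", "finite_difference"))
  if (divergence_mode == "analytic" && is.null(div_fun))
    stop("analytic divergence mode requires div_fun", call. = FALSE)
  # probe antisymmetry of Q at the mean and a fixed off-mean point
  for (x0 in list(density$mean, density$mean + seq_len(d) / d)) {
    Qx <- q_field(x0)
    if (max(abs(Qx + t(Qx))) > 1e-8 * max(1, max(abs(Qx))))
      stop("Q(x) is not antisymmetric", call. = FALSE)
  }
  structure(list(density = density, sigma_field = sigma_field,
                 q_field = q_field, constant_fields = constant_fields,
                 divergence_mode = divergence_mode, div_fun = div_fun),
            class = "diffusion_model")
}

#' @export
print.diffusion_model <- function(x, ...) {
  cat(sprintf("Stationary diffusion: d = %d, %s fields, divergence mode '%s'\n",
              x$density$partition$d,
              if (x$constant_fields) "constant" else "state-dependent",
              x$divergence_mode))
  invisible(x)
}

flow_matrix <- function(model, x) {
  s <- model$sigma_field(x)
  tcrossprod(s) / 2 + model$q_field(x)        # Gamma(x) + Q(x)
}

# constant-coefficient drift matrix B = -(Gamma + Q) Pi
drift_matrix <- function(model) {
  if (!model$constant_fields)
    stop("drift_matrix requires constant fields", call. = FALSE)
  -flow_matrix(model, model$density$mean) %*% model$density$precision
}

#' Divergence correction of the drift
#'
#' Row-wise divergence of the matrix field `Gamma + Q`:
#' `(div M)_i = sum_j d/dx_j M_ij`.  Exactly zero for constant fields;
#' otherwise taken from the user-supplied analytic expression or from
#' central finite differences with step `1e-5 * (1 + |x_j|)` per
#' coordinate.
#'
#' @param model a [diffusion_model()].
#' @param x state vector.
#' @return numeric vector of length `d`.
#' @export
divergence_term <- function(model, x) {
  stopifnot(inherits(model, "diffusion_model"))
  x <- as.numeric(x)
  d <- model$density$partition$d
  if (length(x) != d) stop("x has wrong length", call. = FALSE)
  switch(model$divergence_mode,
         zero = numeric(d),
         analytic = as.numeric(model$div_fun(x)),
         finite_difference = {
           out <- numeric(d)
           for (j in seq_len(d)) {
             h <- 1e-5 * (1 + abs(x[j]))
             xp <- x; xp[j] <- xp[j] + h
             xm <- x; xm[j] <- xm[j] - h
             Dj <- (flow_matrix(model, xp) - flow_matrix(model, xm)) / (2 * h)
             out <- out + Dj[, j]
           }
           out
         })
}

#' Drift field of the stationary diffusion
#'
#' Evaluates `-(Gamma + Q)(x) Pi (x - mean) + div(Gamma + Q)(x)`.
#'
#' @inheritParams divergence_term
#' @return numeric drift vector of length `d`.
#' @export
drift_field <- function(model, x) {
  stopifnot(inherits(model, "diffusion_model"))
  x <- as.numeric(x)
  d <- model$density$partition$d
  if (length(x) != d) stop("x has wrong length", call. = FALSE)
  as.numeric(-flow_matrix(model, x) %*%
               (model$density$precision %*% (x - model$density$mean))) +
    divergence_term(model, x)
}

#' Lyapunov residual of the stationary drift decomposition
#'
#' For constant fields the drift is linear, `B = -(Gamma + Q) Pi`, and
#' stationarity of `N(mean, Sigma)` is equivalent to the continuous
#' Lyapunov identity `B Sigma + Sigma B' + sigma sigma' = 0`, which this
#' function evaluates.  It vanishes identically (up to floating point)
#' for every model built from a valid steady state -- an algebraic
#' consequence of the drift decomposition.
#'
#' @param model a constant-coefficient [diffusion_model()].
#' @return a `d x d` residual matrix.
#' @export
stationarity_residual <- function(model) {
  stopifnot(inherits(model, "diffusion_model"))
  if (!model$constant_fields)
    stop("stationarity_residual supports constant-coefficient models only",
         call. = FALSE)
  B <- drift_matrix(model)
  S <- model$density$covariance
  s <- model$sigma_field(model$density$mean)
  B %*% S + S %*% t(B) + tcrossprod(s)
}

#' Closed-form transition moments of the constant-coefficient diffusion
#'
#' With constant fields the process is a multivariate
#' Ornstein-Uhlenbeck process, whose transition density from `x0` over
#' time `t` is Gaussian with mean `exp(Bt) x0` and covariance
#' `Sigma - exp(Bt) Sigma exp(B't)` (centered coordinates).  Used as the
#' exact oracle for simulation checks.
#'
#' @param model a constant-coefficient [diffusion_model()].
#' @param x0 initial state vector.
#' @param t elapsed time (>= 0).
#' @return list with `mean` (length `d`) and `covariance` (`d x d`).
#' @export
ou_transition_moments <- function(model, x0, t) {
  stopifnot(inherits(model, "diffusion_model"))
  if (!model$constant_fields)
    stop("transition moments are closed-form for constant fields only",
         call. = FALSE)
  if (t < 0) stop("t must be nonnegative", call. = FALSE)
  mu0 <- model$density$mean
  S <- model$density$covariance
  E <- mat_expm(drift_matrix(model) * t)
  list(mean = as.numeric(E %*% (as.numeric(x0) - mu0)) + mu0,
       covariance = symm(S - E %*% S %*% t(E)))
}

#' Simulate trajectories of the stationary diffusion
#'
#' Fixed-step Euler-Maruyama integration (optionally classical
#' Runge-Kutta 4 for noiseless conservative flows).  Each path uses its
#' own noise stream derived deterministically from `(seed, path index)`,
#' so results do not depend on how many paths are requested.
#'
#' @param model a [diffusion_model()].
#' @param init initial condition: a length-`d` vector shared by all
#'   paths, an `n_paths x d` matrix of per-path starts, or the string
#'   `"stationary"` to draw starts from the steady state.
#' @param dt step size (> 0).
#' @param t_end final time (>= dt).
#' @param n_paths number of trajectories.
#' @param seed integer seed.
#' @param record_every record the state every this many steps (the
#'   initial state is always recorded).
#' @param method `"euler"` (Euler-Maruyama) or `"rk4"` (deterministic,
#'   requires zero volatility).
#' @return an object of class `trajectory_ensemble`: `times` (recorded
#'   times), `paths` (array `n_paths x n_times x d`), `dt`, `seed`.
#' @export
simulate_diffusion <- function(model, init, dt, t_end, n_paths = 1, seed,
                               record_every = 1, method = c("euler", "rk4")) {
  stopifnot(inherits(model, "diffusion_model"))
  method <- match.arg(method)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (t_end < dt) stop("t_end must be at least dt", call. = FALSE)
  d <- model$density$partition$d
  n_steps <- floor(t_end / dt + 1e-9)
  rec_idx <- seq(0L, n_steps, by = as.integer(record_every))
  times <- rec_idx * dt
  m <- ncol(model$sigma_field(model$density$mean))
  noiseless <- max(abs(model$sigma_field(model$density$mean))) == 0 &&
    model$constant_fields
  if (method == "rk4" && !noiseless)
    stop("rk4 integration is for noiseless (sigma == 0) models", call. = FALSE)

  if (is.character(init) && identical(init, "stationary")) {
    X0 <- sample_stationary(model$density, n_paths, derive_seed(seed, 0))
  } else if (is.matrix(init)) {
    if (nrow(init) != n_paths || ncol(init) != d)
      stop("init matrix must be n_paths x d", call. = FALSE)
    X0 <- init
  } else {
    if (length(init) != d) stop("init has wrong length", call. = FALSE)
    X0 <- matrix(as.numeric(init), n_paths, d, byrow = TRUE)
  }

  const <- model$constant_fields
  B <- if (const) drift_matrix(model) else NULL
  Sg <- if (const) model$sigma_field(model$density$mean) else NULL
  mu0 <- model$density$mean
  sdt <- sqrt(dt)
  paths <- array(NA_real_, c(n_paths, length(times), d))

  for (ip in seq_len(n_paths)) {
    x <- X0[ip, ]
    Z <- if (!noiseless)
      with_seed(derive_seed(seed, ip), matrix(stats::rnorm(n_steps * m), n_steps, m))
    else NULL
    ri <- 1L
    paths[ip, ri, ] <- x
    for (k in seq_len(n_steps)) {
      if (method == "rk4") {
        f <- function(y) as.numeric(B %*% (y - mu0))
        k1 <- f(x); k2 <- f(x + dt / 2 * k1)
        k3 <- f(x + dt / 2 * k2); k4 <- f(x + dt * k3)
        x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      } else if (const) {
        x <- x + dt * as.numeric(B %*% (x - mu0)) +
          if (noiseless) 0 else sdt * as.numeric(Sg %*% Z[k, ])
      } else {
        x <- x + dt * drift_field(model, x) +
          sdt * as.numeric(model$sigma_field(x) %*% Z[k, ])
      }
      if (any(!is.finite(x)) || max(abs(x)) > 1e8)
        stop(sprintf("trajectory blow-up at step %d (path %d): reduce dt",
                     k, ip), call. = FALSE)
      if (k %% record_every == 0L) {
        ri <- ri + 1L
        paths[ip, ri, ] <- x
      }
    }
  }
  dimnames(paths) <- list(NULL, NULL, coord_names(model$partition %||% model$density$partition))
  structure(list(times = times, paths = paths, dt = dt, seed = seed,
                 partition = model$density$partition),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("Trajectory ensemble: %d path(s), %d recorded times, dt = %g\n",
              dim(x$paths)[1], dim(x$paths)[2], x$dt))
  invisible(x)
}

#' Flatten a trajectory ensemble into long format
#'
#' @param ensemble a [simulate_diffusion()] result.
#' @return data frame with columns `path_id`, `time`, `coordinate_name`,
#'   `value`.
#' @export
as_long_trajectories <- function(ensemble) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  dims <- dim(ensemble$paths)
  cn <- dimnames(ensemble$paths)[[3]]
  data.frame(
    path_id = rep(seq_len(dims[1]), times = dims[2] * dims[3]),
    time = rep(rep(ensemble$times, each = dims[1]), times = dims[3]),
    coordinate_name = rep(cn, each = dims[1] * dims[2]),
    value = as.vector(ensemble$paths))
}
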