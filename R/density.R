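#' Gaussian steady-state density with a blanket partition
#'
#' Represents the stationary density `p(x) = N(x; mean, Pi^-1)` of a
#' `d`-dimensional state together with its blanket partition.  The
#' precision matrix `Pi` must be symmetric positive-definite; the
#' covariance `Sigma = Pi^-1` is computed once and cached.  All block
#' formulas in the package act on centered coordinates, so nonzero means
#' (set-points away from the origin) are supported throughout.
#'
#' @param precision symmetric positive-definite `d x d` precision matrix.
#' @param partition a [blanket_partition()] with total dimension `d`.
#' @param mean optional length-`d` mean vector (default all zeros).
#' @param tol relative tolerance for the symmetry and `Pi Sigma = I`
#'   consistency checks, as a multiple of `max(abs(precision))`.
#' @return an object of class `stationary_density` with fields
#'   `precision`, `covariance`, `mean`, `partition`.
#' @examples
#' P <- blanket_partition(1, 1, 0, 1)
#' Pi <- matrix(c(2, 1, 0, 1, 2, 1, 0, 1, 2), 3, 3)
#' stationary_density(Pi, P)
#' @export
stationary_density <- function(precision, partition, mean = NULL, tol = 1e-8) {
  stopifnot_square(precision, "precision")
  if (!inherits(partition, "blanket_partition"))
    stop("partition must be a blanket_partition", call. = FALSE)
  d <- partition$d
  if (nrow(precision) != d)
    stop(sprintf("precision is %d x %d but the partition has total dimension %d",
                 nrow(precision), ncol(precision), d), call. = FALSE)
  scale <- max(abs(precision))
  if (max(abs(precision - t(precision))) > tol * scale)
    stop("precision matrix is not symmetric", call. = FALSE)
  precision <- symm(precision)
  ev <- eigen(precision, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("precision matrix is not positive-definite (min eigenvalue %.3g)",
                 min(ev)), call. = FALSE)
  covariance <- symm(chol2inv(chol(precision)))
  if (max(abs(precision %*% covariance - diag(d))) > max(tol, 1e-8) * max(1, scale))
    stop("Pi %*% Sigma deviates from the identity beyond tolerance", call. = FALSE)
  if (is.null(mean)) mean <- numeric(d)
  if (length(mean) != d) stop("mean has wrong length", call. = FALSE)
  structure(list(precision = precision, covariance = covariance,
                 mean = as.numeric(mean), partition = partition),
            class = "stationary_density")
}

#' @export
print.stationary_density <- function(x, ...) {
  p <- x$partition
  cat(sprintf("Gaussian steady state: d = %d  [eta: %d | s: %d | a: %d | mu: %d]\n",
              p$d, p$d_eta, p$d_s, p$d_a, p$d_mu))
  cat(sprintf("  Markov blanket (Pi_eta,mu = 0): %s\n", is_markov_blanket(x)))
  invisible(x)
}

# Block extraction in the usual submatrix notation:
# dblock(density, "eta", "b") is Pi_{eta,b} or Sigma_{eta,b}.
dblock <- function(density, rows, cols = rows,
                   of = c("covariance", "precision")) {
  of <- match.arg(of)
  M <- density[[of]]
  p <- density$partition
  M[part_idx(p, rows), part_idx(p, cols), drop = FALSE]
}

mean_block <- function(density, which) {
  density$mean[part_idx(density$partition, which)]
}

#' Test the Markov blanket condition on a stationary density
#'
#' For a Gaussian density the conditional independence
#' `eta _||_ mu | b` is equivalent to a zero `(eta, mu)` block of the
#' precision matrix.  The test passes when every entry of that block has
#' magnitude at most `tol`.
#'
#' @param density a [stationary_density()].
#' @param tol absolute tolerance on the off-block entries; defaults to
#'   `1e-8 * max(abs(precision))`.
#' @return `TRUE` or `FALSE`.
#' @export
is_markov_blanket <- function(density, tol = NULL) {
  stopifnot(inherits(density, "stationary_density"))
  tol <- tol %||% (1e-8 * max(abs(density$precision)))
  max(abs(dblock(density, "eta", "mu", of = "precision"))) <= tol
}

#' Conditional cross-covariance of external and internal states given the blanket
#'
#' Returns `Sigma_eta,mu - Sigma_eta,b Sigma_b^-1 Sigma_b,mu`, the
#' cross-covariance of `(eta, mu)` in the conditional distribution given
#' `b`.  It vanishes (to numerical precision) exactly when the blanket
#' condition holds, so this residual quantifies the failure of the
#' factorization `p(eta, mu | b) = p(eta | b) p(mu | b)`.
#'
#' @param density a [stationary_density()].
#' @return a `d_eta x d_mu` matrix.
#' @export
conditional_independence_residual <- function(density) {
  stopifnot(inherits(density, "stationary_density"))
  S_eb <- dblock(density, "eta", "b")
  S_bm <- dblock(density, "b", "mu")
  S_b <- dblock(density, "b", "b")
  kap <- tryCatch(solve(S_b, S_bm),
                  error = function(e) stop("Sigma_b is numerically singular: ",
                                           conditionMessage(e), call. = FALSE))
  dblock(density, "eta", "mu") - S_eb %*% kap
}

#' Conditional distributions of external and internal states given a blanket state
#'
#' Under the blanket condition the conditionals factorize as
#' `p(eta | b) = N(Sigma_eta,b Sigma_b^-1 b, Pi_eta^-1)` and
#' `p(mu | b) = N(Sigma_mu,b Sigma_b^-1 b, Pi_mu^-1)`, where `Pi_eta`,
#' `Pi_mu` are principal blocks of the precision matrix (coordinates
#' centered at the density's mean).
#'
#' @param density a [stationary_density()] satisfying the blanket condition.
#' @param b blanket vector of length `d_b`.
#' @return a list with components `eta` and `mu`, each a
#'   `conditional_gaussian` list with fields `mean` and `precision`.
#' @export
conditional_given_blanket <- function(density, b) {
  stopifnot(inherits(density, "stationary_density"))
  if (!is_markov_blanket(density))
    stop("no Markov blanket: the (eta, mu) precision block is nonzero, so the ",
         "factorized conditionals do not apply", call. = FALSE)
  p <- density$partition
  b <- as.numeric(b)
  if (length(b) != p$d_b)
    stop(sprintf("b has length %d but d_b = %d", length(b), p$d_b), call. = FALSE)
  bc <- b - mean_block(density, "b")
  S_b <- dblock(density, "b", "b")
  gain_e <- t(solve(S_b, t(dblock(density, "eta", "b"))))
  gain_m <- t(solve(S_b, t(dblock(density, "mu", "b"))))
  mk <- function(mean, precision)
    structure(list(mean = as.numeric(mean), precision = symm(precision)),
              class = "conditional_gaussian")
  list(eta = mk(mean_block(density, "eta") + gain_e %*% bc,
                dblock(density, "eta", "eta", of = "precision")),
       mu = mk(mean_block(density, "mu") + gain_m %*% bc,
               dblock(density, "mu", "mu", of = "precision")))
}

#' Expected external and internal states given a blanket state
#'
#' Convenience accessor for the two conditional means
#' `eta(b) = Sigma_eta,b Sigma_b^-1 b` and
#' `mu(b) = Sigma_mu,b Sigma_b^-1 b` (centered coordinates).
#'
#' @inheritParams conditional_given_blanket
#' @return list with numeric vectors `eta_bar` and `mu_bar`.
#' @export
expected_states <- function(density, b) {
  cond <- conditional_given_blanket(density, b)
  list(eta_bar = cond$eta$mean, mu_bar = cond$mu$mean)
}

#' Draw a random precision matrix with an exact Markov blanket
#'
#' Fixture generator: draws a symmetric matrix with standard-normal
#' entries, zeroes the `(eta, mu)` block exactly, and shifts the
#' diagonal by `max(0, -lambda_min) + scale` to force positive
#' definiteness.  The shift preserves the zero block, so every output
#' satisfies the blanket condition by construction.  Deterministic given
#' `seed`; the caller's RNG state is left untouched.
#'
#' @param partition a [blanket_partition()].
#' @param seed integer seed.
#' @param scale positive diagonal margin added beyond the minimal
#'   positive-definiteness shift (default 1).
#' @return a [stationary_density()].
#' @export
sample_blanket_precision <- function(partition, seed, scale = 1) {
  stopifnot(inherits(partition, "blanket_partition"), scale > 0)
  d <- partition$d
  Pi <- with_seed(seed, symm(matrix(stats::rnorm(d * d), d, d)))
  ie <- part_idx(partition, "eta"); im <- part_idx(partition, "mu")
  Pi[ie, im] <- 0
  Pi[im, ie] <- 0
  lam <- min(eigen(Pi, symmetric = TRUE, only.values = TRUE)$values)
  Pi <- Pi + (max(0, -lam) + scale) * diag(d)
  stationary_density(Pi, partition)
}

#' Draw independent samples from the stationary density
#'
#' @param density a [stationary_density()].
#' @param n number of draws (>= 1).
#' @param seed integer seed; draws are reproducible and the caller's RNG
#'   state is left untouched.
#' @return an `n x d` matrix with columns in the canonical
#'   `[eta, s, a, mu]` order, named by coordinate.
#' @export
sample_stationary <- function(density, n, seed) {
  stopifnot(inherits(density, "stationary_density"))
  if (!is.numeric(n) || n < 1) stop("n must be a positive count", call. = FALSE)
  n <- as.integer(n)
  d <- density$partition$d
  R <- chol(density$covariance)
  Z <- with_seed(seed, matrix(stats::rnorm(n * d), n, d))
  X <- Z %*% R + matrix(density$mean, n, d, byrow = TRUE)
  colnames(X) <- coord_names(density$partition)
  X
}
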