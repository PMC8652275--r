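# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# symmetrize (guards against round-off asymmetry before chol/eigen)
symm <- function(M) (M + t(M)) / 2

is_square <- function(M) is.matrix(M) && nrow(M) == ncol(M)

stopifnot_square <- function(M, what = "matrix") {
  if (!is_square(M)) stop(sprintf("%s must be a square matrix", what), call. = FALSE)
}

# log-determinant of a symmetric positive-definite matrix via Cholesky
logdet_pd <- function(M) 2 * sum(log(diag(chol(symm(M)))))

# rowwise quadratic forms x_i' M x_i for X with rows x_i
quad_rows <- function(X, M) rowSums((X %*% M) * X)

#' Moore-Penrose pseudo-inverse with a scale-invariant rank cutoff
#'
#' Singular values below `rank_tol` times the largest singular value are
#' treated as exactly zero.  The all-zero matrix maps to the all-zero
#' transpose, consistent with the Moore-Penrose definition.
#'
#' @param A numeric matrix (not necessarily square).
#' @param rank_tol nonnegative relative cutoff for singular values.
#' @return the pseudo-inverse, a `ncol(A) x nrow(A)` matrix.
#' @keywords internal
pinv <- function(A, rank_tol = 1e-10) {
  A <- as.matrix(A)
  if (length(A) == 0L || all(A == 0)) return(matrix(0, ncol(A), nrow(A)))
  sv <- svd(A)
  keep <- sv$d > rank_tol * max(sv$d)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  sv$v[, keep, drop = FALSE] %*% ((1 / sv$d[keep]) * t(sv$u[, keep, drop = FALSE]))
}

# orthogonal projector onto ker(A) (A acts on column vectors): I - A^- A
kernel_projector <- function(A, rank_tol = 1e-10) {
  diag(ncol(A)) - pinv(A, rank_tol) %*% A
}

mat_expm <- function(A) {
  as.matrix(Matrix::expm(Matrix::Matrix(A, sparse = FALSE)))
}

# Solve A X + X A' + C = 0 for X (continuous Lyapunov equation) via the
# Kronecker vectorization; fine for the small dimensions used here.
lyapunov_solve <- function(A, C) {
  stopifnot_square(A, "A"); stopifnot_square(C, "C")
  d <- nrow(A)
  M <- kronecker(diag(d), A) + kronecker(A, diag(d))
  X <- matrix(solve(M, -as.vector(C)), d, d)
  symm(X)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library calls never disturb user simulations.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-stream seed derivation: one independent stream per
# (base seed, stream index), stable under changes in stream count.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + as.numeric(k) * 16807 + 12345) %% 2147483629)
}
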