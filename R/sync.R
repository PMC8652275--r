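#' Existence test for the synchronization map
#'
#' A map `sigma` with `sigma(mu(b)) = eta(b)` for every blanket state
#' exists exactly when `ker Sigma_mu,b` is contained in
#' `ker Sigma_eta,b` (equivalently, with the corresponding precision
#' blocks).  The kernel inclusion is tested as
#' `max|Sigma_eta,b (I - Sigma_mu,b^- Sigma_mu,b)| <= rank_tol`, i.e. by
#' applying `Sigma_eta,b` to the orthogonal projector onto
#' `ker Sigma_mu,b`.  The same test on the precision blocks is reported
#' as a diagnostic; the two verdicts agree in exact arithmetic.
#'
#' @param density a [stationary_density()] satisfying the blanket condition.
#' @param rank_tol relative singular-value cutoff for rank decisions and
#'   absolute tolerance (relative to the block scale) for the residuals.
#' @return a list: `exists` (covariance-block verdict), and
#'   `diagnostics` with `cov_residual`, `prec_residual`,
#'   `exists_precision_form` and `verdicts_agree`.
#' @export
sync_exists <- function(density, rank_tol = 1e-10) {
  stopifnot(inherits(density, "stationary_density"))
  if (!is_markov_blanket(density))
    stop("no Markov blanket: synchronization analysis requires one", call. = FALSE)
  test_blocks <- function(A_eta_b, A_mu_b) {
    proj <- kernel_projector(A_mu_b, rank_tol)
    res <- max(abs(A_eta_b %*% proj))
    scale <- max(abs(A_eta_b), 1)
    list(residual = res, ok = res <= rank_tol * scale * 1e2 + rank_tol)
  }
  cv <- test_blocks(dblock(density, "eta", "b"), dblock(density, "mu", "b"))
  pr <- test_blocks(dblock(density, "eta", "b", of = "precision"),
                    dblock(density, "mu", "b", of = "precision"))
  list(exists = cv$ok,
       diagnostics = list(cov_residual = cv$residual,
                          prec_residual = pr$residual,
                          exists_precision_form = pr$ok,
                          verdicts_agree = identical(cv$ok, pr$ok)))
}

#' Construct the synchronization map
#'
#' Builds the linear map `sigma` from internal to external coordinates
#' in both closed forms: the covariance form
#' `Sigma_eta,b Sigma_mu,b^-` and the precision form
#' `Pi_eta^-1 Pi_eta,b Pi_mu,b^- Pi_mu` (pseudo-inverses with a
#' scale-invariant rank cutoff).  The map is defined even when the
#' existence condition fails; in that degenerate regime it no longer
#' carries expected internal states to expected external states and the
#' two forms are not asserted to agree.
#'
#' @inheritParams sync_exists
#' @return an object of class `sync_map` with fields `matrix`
#'   (covariance form, `d_eta x d_mu`), `matrix_precision_form`,
#'   `exists`, `construction = "covariance_form"` and `diagnostics`.
#' @export
build_sync_map <- function(density, rank_tol = 1e-10) {
  ex <- sync_exists(density, rank_tol)
  S_cov <- dblock(density, "eta", "b") %*% pinv(dblock(density, "mu", "b"), rank_tol)
  Pi_eta <- dblock(density, "eta", "eta", of = "precision")
  S_prec <- solve(Pi_eta,
                  dblock(density, "eta", "b", of = "precision") %*%
                    pinv(dblock(density, "mu", "b", of = "precision"), rank_tol) %*%
                    dblock(density, "mu", "mu", of = "precision"))
  structure(list(matrix = S_cov,
                 matrix_precision_form = S_prec,
                 exists = ex$exists,
                 construction = "covariance_form",
                 diagnostics = ex$diagnostics,
                 partition = density$partition,
                 mean_eta = mean_block(density, "eta"),
                 mean_mu = mean_block(density, "mu")),
            class = "sync_map")
}

#' @export
print.sync_map <- function(x, ...) {
  cat(sprintf("Synchronization map (%d x %d), exists: %s\n",
              nrow(x$matrix), ncol(x$matrix), x$exists))
  invisible(x)
}

#' Predict external coordinates from internal coordinates
#'
#' Applies the synchronization map: `sigma(mu)` in centered coordinates,
#' shifted back by the external mean.  When the map exists and `mu` is
#' an expected internal state `mu(b)`, the result is the expected
#' external state `eta(b)`.
#'
#' @param map a [build_sync_map()] result.
#' @param mu internal vector of length `d_mu`.
#' @return external vector of length `d_eta`.
#' @export
predict_external <- function(map, mu) {
  stopifnot(inherits(map, "sync_map"))
  mu <- as.numeric(mu)
  if (length(mu) != ncol(map$matrix))
    stop(sprintf("mu has length %d but the map expects %d", length(mu),
                 ncol(map$matrix)), call. = FALSE)
  as.numeric(map$matrix %*% (mu - map$mean_mu)) + map$mean_eta
}

#' Empirical synchronization check by blanket binning
#'
#' Implements the binned protocol for one-dimensional blankets: the
#' sampled blanket values are split into equal-probability (quantile)
#' bins, the empirical conditional means of `eta` and `mu` are computed
#' per bin, and the synchronization map is applied to the empirical
#' internal means.  Agreement of `sigma(mu_bar)` with `eta_bar` across
#' bins is the observable signature of synchronization; in degenerate
#' fixtures the predictions collapse to zero.  Bins with fewer than
#' `min_per_bin` samples are dropped.
#'
#' @param samples `n x d` sample matrix in canonical coordinate order,
#'   drawn i.i.d. from the density or from a stationary diffusion with
#'   that steady state.
#' @param density the [stationary_density()] the samples target; its
#'   blanket must be one-dimensional.
#' @param n_bins number of quantile bins (default 20).
#' @param min_per_bin minimum occupancy for a bin to be reported
#'   (default 100).
#' @param map optional precomputed [build_sync_map()]; built from
#'   `density` when omitted.
#' @return a data frame with one row per retained bin and columns
#'   `bin_center`, `mean_b`, `bin_count`, `empirical_eta_bar`,
#'   `empirical_mu_bar`, `sigma_of_mu_bar`, `se_eta_bar`, `se_pred`
#'   (coordinate-suffixed when `d_eta > 1` or `d_mu > 1`).  `se_pred`
#'   combines the binwise standard errors of `eta_bar` and of the mapped
#'   `mu_bar`, the yardstick for the agreement check.
#' @export
empirical_sync_table <- function(samples, density, n_bins = 20,
                                 min_per_bin = 100, map = NULL) {
  stopifnot(inherits(density, "stationary_density"))
  p <- density$partition
  if (p$d_b != 1)
    stop("binned synchronization check supports one-dimensional blankets only",
         call. = FALSE)
  samples <- as.matrix(samples)
  if (ncol(samples) != p$d)
    stop("samples have wrong number of columns", call. = FALSE)
  map <- map %||% build_sync_map(density)
  bvals <- samples[, part_idx(p, "b")]
  edges <- unique(stats::quantile(bvals, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- findInterval(bvals, edges, rightmost.closed = TRUE, all.inside = TRUE)
  E <- samples[, part_idx(p, "eta"), drop = FALSE]
  M <- samples[, part_idx(p, "mu"), drop = FALSE]
  Smat <- map$matrix
  rows <- lapply(seq_len(length(edges) - 1L), function(k) {
    in_bin <- bin == k
    n_k <- sum(in_bin)
    if (n_k < min_per_bin) return(NULL)
    eta_bar <- colMeans(E[in_bin, , drop = FALSE])
    mu_bar <- colMeans(M[in_bin, , drop = FALSE])
    se_eta <- apply(E[in_bin, , drop = FALSE], 2, stats::sd) / sqrt(n_k)
    se_mu <- apply(M[in_bin, , drop = FALSE], 2, stats::sd) / sqrt(n_k)
    pred <- as.numeric(Smat %*% (mu_bar - map$mean_mu)) + map$mean_eta
    se_pred <- sqrt(se_eta^2 + as.numeric(Smat^2 %*% se_mu^2))
    c(bin_center = (edges[k] + edges[k + 1]) / 2,
      mean_b = mean(bvals[in_bin]), bin_count = n_k,
      veccols("empirical_eta_bar", eta_bar),
      veccols("empirical_mu_bar", mu_bar),
      veccols("sigma_of_mu_bar", pred),
      veccols("se_eta_bar", se_eta),
      veccols("se_pred", se_pred))
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows))
    stop("no bin reached min_per_bin samples; reduce n_bins or min_per_bin",
         call. = FALSE)
  as.data.frame(do.call(rbind, rows))
}

# name a vector's entries "base" (length 1) or "base_1", "base_2", ...
veccols <- function(base, v) {
  names(v) <- if (length(v) == 1) base else paste0(base, "_", seq_along(v))
  v
}
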