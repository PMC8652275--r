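#' Blanket partition of the state vector
#'
#' Bookkeeping for the ordered decomposition of a `d`-dimensional state
#' vector into external, sensory, active and internal coordinates,
#' `x = (eta, s, a, mu)`.  The blanket is `b = (s, a)`; analyses that do
#' not distinguish sensory from active states use `d_a = 0`.  The
#' canonical coordinate order `[eta, s, a, mu]` is used everywhere in the
#' package, including serialized matrices.
#'
#' @param d_eta number of external coordinates (>= 1).
#' @param d_s number of sensory coordinates.
#' @param d_a number of active coordinates (default 0).
#' @param d_mu number of internal coordinates (>= 1).
#' @return an object of class `blanket_partition` with fields `d_eta`,
#'   `d_s`, `d_a`, `d_mu`, `d_b = d_s + d_a` and total dimension `d`.
#' @examples
#' blanket_partition(1, 1, 0, 1)
#' blanket_partition(2, 1, 1, 2)
#' @export
blanket_partition <- function(d_eta, d_s, d_a = 0, d_mu) {
  dims <- c(d_eta = d_eta, d_s = d_s, d_a = d_a, d_mu = d_mu)
  if (any(dims != round(dims)) || any(dims < 0))
    stop("partition dimensions must be nonnegative integers", call. = FALSE)
  if (d_eta < 1) stop("d_eta must be >= 1", call. = FALSE)
  if (d_mu < 1) stop("d_mu must be >= 1", call. = FALSE)
  if (d_s + d_a < 1) stop("blanket dimension d_s + d_a must be >= 1", call. = FALSE)
  structure(
    list(d_eta = as.integer(d_eta), d_s = as.integer(d_s),
         d_a = as.integer(d_a), d_mu = as.integer(d_mu),
         d_b = as.integer(d_s + d_a),
         d = as.integer(d_eta + d_s + d_a + d_mu)),
    class = "blanket_partition")
}

#' @export
print.blanket_partition <- function(x, ...) {
  cat(sprintf("Blanket partition: d = %d  [eta: %d | s: %d | a: %d | mu: %d]\n",
              x$d, x$d_eta, x$d_s, x$d_a, x$d_mu))
  invisible(x)
}

# Index vectors for the canonical coordinate blocks.
# which: "eta", "s", "a", "mu", "b" (= s,a), "bmu" (= s,a,mu = particular),
#        "sam" (alias of bmu), "amu" (= a,mu = autonomous), "all"
part_idx <- function(p, which) {
  stopifnot(inherits(p, "blanket_partition"))
  e <- seq_len(p$d_eta)
  s <- p$d_eta + seq_len(p$d_s)
  a <- p$d_eta + p$d_s + seq_len(p$d_a)
  m <- p$d_eta + p$d_b + seq_len(p$d_mu)
  switch(which,
         eta = e, s = s, a = a, mu = m,
         b = c(s, a),
         bmu = c(s, a, m), sam = c(s, a, m),
         amu = c(a, m),
         all = seq_len(p$d),
         stop("unknown block name: ", which))
}

coord_names <- function(p) {
  c(paste0("eta_", seq_len(p$d_eta)),
    if (p$d_s) paste0("s_", seq_len(p$d_s)),
    if (p$d_a) paste0("a_", seq_len(p$d_a)),
    paste0("mu_", seq_len(p$d_mu)))
}
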