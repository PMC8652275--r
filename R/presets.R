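# Worked fixtures and figure-style presets.
#
# Two fixtures ship verbatim from the worked examples (the 3 x 3
# precision with a one-dimensional blanket, and its diffusion with
# solenoidal flow and identity volatility).  The figure-style presets
# reproduce the stated dimensions only; their matrices are seeded
# fixtures because no reference matrices are published for them.

example_precision_3x3 <- function() {
  matrix(c(2, 1, 0,
           1, 2, 1,
           0, 1, 2), 3, 3, byrow = TRUE)
}

solenoidal_3x3 <- function() {
  matrix(c(0, 0, 1,
           0, 0, 0,
           -1, 0, 0), 3, 3, byrow = TRUE)
}

# seeded antisymmetric matrix for solenoidal flow in figure-style presets
random_solenoidal <- function(d, seed, strength = 1) {
  M <- with_seed(seed, matrix(stats::rnorm(d * d), d, d))
  strength * (M - t(M)) / 2
}

preset_builders <- function() {
  list(
    example_2_2 = function() {
      part <- blanket_partition(1, 1, 0, 1)
      dens <- stationary_density(example_precision_3x3(), part)
      list(kind = "density", density = dens,
           description = "3x3 worked precision with a 1-D blanket")
    },
    remark_3_2 = function() {
      part <- blanket_partition(1, 1, 0, 1)
      dens <- stationary_density(example_precision_3x3(), part)
      list(kind = "model",
           density = dens,
           model = diffusion_model(dens, sigma = diag(3), Q = solenoidal_3x3()),
           description = "worked diffusion: identity volatility + solenoidal flow")
    },
    fig2_degenerate = function() {
      part <- blanket_partition(1, 1, 0, 1)
      Pi <- matrix(c(2, 1, 0,
                     1, 2, 0,
                     0, 0, 2), 3, 3, byrow = TRUE)
      dens <- stationary_density(Pi, part)
      list(kind = "density", density = dens,
           description = "degenerate fixture (Pi_mu,b = 0): sync map collapses to zero")
    },
    fig4b_transition = function() {
      part <- blanket_partition(1, 1, 0, 1)
      dens <- stationary_density(example_precision_3x3(), part)
      cfun <- function(x) 0.2 + 2 / (1 + x[1]^2)
      sig <- function(x) sqrt(2 * cfun(x)) * diag(3)
      dvf <- function(x) c(-4 * x[1] / (1 + x[1]^2)^2, 0, 0)
      list(kind = "model", density = dens,
           model = diffusion_model(dens, sigma = sig, Q = matrix(0, 3, 3),
                                   divergence_mode = "analytic", div_fun = dvf),
           description = "state-dependent volatility: non-Gaussian transitions, Gaussian marginal")
    },
    fig5_like = function() {
      part <- blanket_partition(2, 2, 0, 2)
      dens <- sample_blanket_precision(part, seed = 502, scale = 1)
      Q <- random_solenoidal(part$d, seed = 5020, strength = 1)
      list(kind = "model", density = dens,
           model = diffusion_model(dens, sigma = diag(part$d), Q = Q),
           description = "2+2+2 OU relaxation fixture with moderate solenoidal flow (seeded)")
    },
    fig6_like = function() {
      part <- blanket_partition(1, 1, 0, 1)
      dens <- sample_blanket_precision(part, seed = 601, scale = 1)
      Q <- random_solenoidal(part$d, seed = 6010, strength = 1.5)
      list(kind = "model", density = dens,
           model = diffusion_model(dens, sigma = diag(part$d), Q = Q),
           description = "1+1+1 OU relaxation fixture, realized internal states (seeded)")
    },
    fig8_like = function() {
      part <- blanket_partition(2, 1, 1, 2)
      dens <- sample_blanket_precision(part, seed = 802, scale = 1)
      Q <- random_solenoidal(part$d, seed = 8010, strength = 0.5)
      # strengthen the solenoidal coupling between the sensory and
      # active coordinates so action visibly trails sensation
      is_ <- part_idx(part, "s"); ia <- part_idx(part, "a")
      Q[is_, ia] <- Q[is_, ia] + 1.5
      Q[ia, is_] <- Q[ia, is_] - 1.5
      list(kind = "model", density = dens,
           model = diffusion_model(dens, sigma = diag(part$d), Q = Q),
           description = "2+1+1+2 active-inference fixture with s-a solenoidal coupling (seeded)")
    },
    chain_pid = function() {
      chain <- build_chain(order = 2,
                           self = list(-1, -1, -1),
                           coupling = list(1, 1),
                           volatility = list(1, 1, 1))
      part <- blanket_partition(2, 1, 1, 2)
      dens <- sample_blanket_precision(part, seed = 802, scale = 1)
      list(kind = "chain", chain = chain, density = dens,
           spec = control_gain_matrix(dens),
           description = "order-2 scalar integrator chain + gain matrix (PID extraction)")
    }
  )
}

#' List the shipped experiment presets
#'
#' @return data frame with columns `name` and `description`.
#' @export
list_presets <- function() {
  b <- preset_builders()
  data.frame(name = names(b),
             description = vapply(names(b), function(nm) b[[nm]]()$description, ""),
             row.names = NULL)
}

#' Retrieve a named preset
#'
#' @param name one of the names in [list_presets()].
#' @return a list with fields `kind` (`"density"`, `"model"` or
#'   `"chain"`), `density`, and where applicable `model`, `chain`,
#'   `spec`, plus `description`.
#' @export
get_preset <- function(name) {
  b <- preset_builders()
  if (!name %in% names(b))
    stop(sprintf("unknown preset '%s'; see list_presets()", name), call. = FALSE)
  out <- b[[name]]()
  out$name <- name
  out
}
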