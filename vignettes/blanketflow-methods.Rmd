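---
title: "Markov blankets at steady state: models, diagnostics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov blankets at steady state: models, diagnostics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blanketflow)
```

`blanketflow` is a simulation and analysis toolbox for a simple but
consequential class of models: stationary stochastic processes whose
Gaussian steady state carries a Markov blanket.  These models formalize
the idea of a persistent system — a cell behind its membrane, a nervous
system behind its receptors and muscles — whose internal states carry
information about the environment only through a boundary.  This
vignette explains the mathematical objects the package computes, the
tunable parameters and their defaults, the numerical choices, and what
the test suite does and does not establish.

## The steady-state model

The world's state is a vector $x \in \mathbb{R}^d$ partitioned in a
fixed canonical order into external, sensory, active and internal
coordinates,

$$x = (\eta, s, a, \mu), \qquad b = (s, a),$$

with $b$ the *blanket*.  The steady state is a non-degenerate Gaussian
$p(x) = \mathcal{N}(x; 0, \Pi^{-1})$ with precision matrix
$\Pi \succ 0$ (a nonzero mean is supported throughout and simply
translates the set-point; all block formulas act on centered
coordinates).  The blanket condition is the conditional independence
$\eta \perp \mu \mid b$, which for a Gaussian is exactly a sparsity
constraint:

$$\Pi_{\eta\mu} = 0 .$$

`is_markov_blanket()` tests this block directly;
`conditional_independence_residual()` computes the equivalent
covariance-side statement, the conditional cross-covariance
$\Sigma_{\eta\mu} - \Sigma_{\eta b}\Sigma_b^{-1}\Sigma_{b\mu}$, which
vanishes precisely when the factorization
$p(\eta, \mu \mid b) = p(\eta \mid b)\, p(\mu \mid b)$ holds.  Under the
blanket, the conditionals have closed forms
($\Sigma := \Pi^{-1}$):

$$p(\eta \mid b) = \mathcal{N}(\eta;\ \Sigma_{\eta b}\Sigma_b^{-1} b,\ \Pi_\eta^{-1}),
\qquad
p(\mu \mid b) = \mathcal{N}(\mu;\ \Sigma_{\mu b}\Sigma_b^{-1} b,\ \Pi_\mu^{-1}),$$

whose means $\bar\eta(b)$, $\bar\mu(b)$ are the *expected external* and
*expected internal* states (`conditional_given_blanket()`,
`expected_states()`).

### The synthetic fixture generator

`sample_blanket_precision()` is the package's study-condition
generator.  It draws a symmetric matrix with standard-normal entries,
zeroes the $(\eta, \mu)$ block exactly, and shifts the diagonal by
$\max(0, -\lambda_{\min}) + \texttt{scale}$ (default `scale = 1`).
This is the simplest construction that cannot violate the blanket
sparsity, and the diagonal shift preserves the zero block, so every
draw is a valid fixture by construction.  What it emulates is the
"generic coupled system with a boundary": dense couplings everywhere
except across the blanket.  What it does *not* emulate: structured
real-world precisions (banded, multiscale, or nearly singular ones),
non-Gaussian steady states, and any form of estimation of $\Pi$ from
data — user-supplied matrices are taken at face value.  Passing tests
on these fixtures therefore establish the algebraic and statistical
machinery, not the fit of the model class to any empirical system.

## The synchronization map

The scientific question behind the package is when and how expected
internal states *encode* expected external states: is there a map
$\sigma$ with $\sigma(\bar\mu(b)) = \bar\eta(b)$ for every blanket
state?  The exact criterion is a kernel inclusion,
$\ker \Sigma_{\mu b} \subset \ker \Sigma_{\eta b}$ (equivalently with
the precision blocks).  `sync_exists()` tests it as

$$\big\lVert \Sigma_{\eta b}\,(I - \Sigma_{\mu b}^- \Sigma_{\mu b}) \big\rVert_{\max} \le \text{tol},$$

i.e. by applying $\Sigma_{\eta b}$ to the orthogonal projector onto
$\ker \Sigma_{\mu b}$, and reports the same test on the precision
blocks as a cross-check; the two verdicts agree on all fixtures,
including degenerate ones.  Pseudo-inverses use an SVD with singular
values below `rank_tol` times the largest treated as zero
(`rank_tol = 1e-10` by default): a scale-invariant rank decision drives
both the kernel test and the construction.

`build_sync_map()` returns both closed forms

$$\sigma_{\text{cov}} = \Sigma_{\eta b}\Sigma_{\mu b}^-,
\qquad
\sigma_{\text{prec}} = \Pi_\eta^{-1}\Pi_{\eta b}\Pi_{\mu b}^-\Pi_\mu .$$

One subtlety the package is explicit about: $\sigma$ is defined on
$\mathrm{Image}(\bar\mu)$, and the two forms agree *as maps on that
domain* whenever the existence condition holds.  As raw matrices they
coincide only when $\Sigma_{\mu b}$ has full row rank $d_\mu$
(e.g. square full-rank cross-blocks); when
$\mathrm{rank}\,\Sigma_{\mu b} < d_\mu$ each pseudo-inverse annihilates
a different complement of the domain and the matrices differ there,
harmlessly.  The map is constructed even when existence fails; in that
degenerate regime it simply no longer carries $\bar\mu(b)$ to
$\bar\eta(b)$ (in the shipped `fig2_degenerate` fixture it collapses to
the zero map, so all predictions are zero).

The empirical counterpart (`empirical_sync_table()`) follows the
binning protocol used for one-dimensional blankets: split the sampled
blanket values into equal-probability (quantile) bins — default 20
bins, bins with fewer than 100 samples dropped — compute the per-bin
empirical means of $\eta$ and $\mu$, and compare
$\sigma(\hat{\bar\mu})$ with $\hat{\bar\eta}$ bin by bin.  Quantile
bins were chosen over equal-width bins to stabilize the tails; the
reported `se_pred` column combines the binwise standard errors of both
estimates and is the yardstick for agreement.

## Stationary diffusions

Dynamics enter through the Itô diffusion

$$dx_t = (\Gamma + Q)(x_t)\,\nabla \log p(x_t)\,dt
       + \nabla\!\cdot\!(\Gamma + Q)(x_t)\,dt + \varsigma(x_t)\,dW_t,
\qquad \Gamma := \tfrac{1}{2}\varsigma\varsigma^\top,\quad Q = -Q^\top,$$

which leaves $p$ stationary for any sufficiently smooth fields: the
symmetric part $\Gamma$ drives dissipative flow, the antisymmetric $Q$
drives solenoidal (circulating) flow that breaks detailed balance
without disturbing the steady state, and the divergence term
$(\nabla\!\cdot\! M)_i = \sum_j \partial_j M_{ij}$ corrects for state
dependence (it vanishes for constant fields).  $\varsigma \equiv 0$ is
legal and gives a deterministic conservative flow along the contours of
$p$.  The package assumes user-supplied fields are smooth; no
regularity checking beyond antisymmetry probing is attempted.

For constant fields the drift is linear, $B = -(\Gamma + Q)\Pi$, the
process is a multivariate Ornstein–Uhlenbeck process, and two exact
oracles are available:

* the Lyapunov identity
  $B\Sigma + \Sigma B^\top + \varsigma\varsigma^\top = 0$
  (`stationarity_residual()`), an algebraic consequence of the drift
  decomposition that holds to machine precision for every model built
  from a valid steady state; and
* closed-form transition moments
  $\mathbb{E}[x_t \mid x_0] = e^{Bt}x_0$,
  $\mathrm{Cov}[x_t \mid x_0] = \Sigma - e^{Bt}\Sigma e^{B^\top t}$
  (`ou_transition_moments()`), used to check the integrator.

Simulation (`simulate_diffusion()`) is fixed-step Euler–Maruyama.  The
default step is $dt = 10^{-3}$ in units where $\lVert B\rVert \approx
1$; experiment presets use $2\times10^{-3}$–$5\times10^{-3}$, sized so
that the $O(dt)$ discretization bias of the numerical steady state is
well below the Monte-Carlo standard errors the tests compare against.
Each path consumes its own noise stream derived deterministically from
`(seed, path index)`, so results are reproducible and independent of
how many paths are requested.  Noiseless conservative runs can use a
classical 4th-order Runge–Kutta step, under which the quadratic
invariant $x^\top \Pi x$ is conserved to integrator tolerance.
State-dependent fields are supported with analytic or central
finite-difference divergences (step $10^{-5}(1 + |x_j|)$); the shipped
`fig4b_transition` preset uses a bounded state-dependent volatility to
demonstrate that transition densities are then non-Gaussian even though
the time marginal remains the Gaussian steady state.  This
demonstration is asserted only qualitatively (a normality test on
transition samples rejects; the marginal scale matches), since the
effect size depends on the chosen field.

## Beliefs, free energy and relaxation

Each internal state $\mu$ is assigned the belief
$q_\mu(\eta) = \mathcal{N}(\eta;\ \sigma(\mu),\ \Pi_\eta^{-1})$: mean
given by the synchronization map, covariance fixed to the true
posterior's.  Because the covariances match, the KL divergence from
belief to posterior is the squared precision-weighted mean gap

$$D_{\mathrm{KL}}[q_\mu \,\Vert\, p(\cdot \mid b)]
  = \tfrac{1}{2}\,(\sigma(\mu) - \bar\eta(b))^\top \Pi_\eta\, (\sigma(\mu) - \bar\eta(b)),$$

zero exactly when $\mu$ is the expected internal state.  The
variational free energy is

$$F(b, \mu) = D_{\mathrm{KL}}[q_\mu \,\Vert\, p(\cdot \mid b)] - \log p(b, \mu),$$

and the package deliberately carries **all additive normalization
constants**, so that both standard decompositions hold as exact
identities rather than "up to a constant":
$F = \mathrm{KL} - \log p(b,\mu)$ and
$F = \text{energy} - \text{entropy}$ with
$\text{energy} = \mathbb{E}_{q_\mu}[-\log p(x)]$ and
$\text{entropy} = H[q_\mu]$.  Display-style outputs can subtract the
stationary minimum if parity with figure conventions is wanted.
$F(b,\cdot)$ is a strictly convex quadratic; `minimize_free_energy()`
solves it in closed form, verifies the gradient at the solution
(tolerance $10^{-8}$), and the suite cross-checks the solve against an
independent BFGS minimization.  The minimizer coincides with
$\bar\mu(b)$, which is also the MAP property: $\sigma(\bar\mu(b))$ is
the mode (= mean) of $p(\eta \mid b)$.

Precision-weighted prediction errors are
$\xi = \Pi_\eta(\eta - \sigma(\mu))$.  Two conventions are exposed,
because the quantity is ambiguous in figure-style protocols: with the
*expected* internal state and the *expected* external state $\xi$
vanishes identically, so the package treats the informative reading —
realized $\eta_t$ against $\sigma(\bar\mu(b_t))$ — as the default
analysis convention; at steady state it has mean zero and covariance
$\Pi_\eta \Pi_\eta^{-1} \Pi_\eta = \Pi_\eta$, which the tests verify.

`relaxation_experiment()` reproduces the "surprising stimulus"
protocol: paths start from the steady state conditioned on a blanket
value $b_0$ ($\eta$ and $\mu$ drawn independently from their exact
conditionals — legal because of the blanket — and $b$ clamped to
$b_0$), and the mean free energy is tracked as the ensemble relaxes.
The default "improbable" $b_0$ displaces the first blanket coordinate
by 3 marginal standard deviations; the value 3 is a convention (the
protocol only requires "improbable") and is exposed as a parameter.
Two design points deserve emphasis:

* **Flatness of the control condition.**  Clamping the blanket even at
  its *mean* is a mild conditioning: $F$ then starts at its
  conditional floor (KL $= 0$, maximal log joint) and relaxes *upward*
  by a sub-nat amount to the stationary level.  A genuinely flat
  control requires initializing from the full steady state, which
  `relaxation_experiment(b0 = NULL)` does; both behaviours are tested.
* **Monotonicity is not asserted.**  With solenoidal flow the mean
  free energy can transiently rise (the shipped `fig5_like` preset
  shows a visible oscillation); only the start-versus-end decrease and
  convergence to the independently estimated stationary expectation of
  $F$ are checked.

## Active states and stochastic control

Splitting the blanket into sensory and active coordinates, the expected
action given sensation is the conditional mean
$\bar a(s) = \Sigma_{as}\Sigma_s^{-1}s$ (`expected_action()`).  The
control view comes from the precision of the particular states,
$K = \Sigma_{(s,a,\mu)}^{-1}$ (`control_gain_matrix()`): expected
autonomous states minimize the quadratic objective
$[s, a, \mu]\, K\, [s, a, \mu]^\top$, and because $K$ is a precision
matrix the minimizer over $(a, \mu)$ at fixed $s$ *is* the conditional
expectation $\mathbb{E}[(a,\mu) \mid s]$ — a block solve the package
implements and tests against generic Gaussian conditioning.  Set-points
away from the origin are handled by the density's mean vector: the
objective is always computed in centered coordinates.

`active_relaxation_experiment()` runs the sensory analogue of the
relaxation protocol (initial states drawn from the conditional given a
surprising $s_0$).  The `fig8_like` preset (2 external, 1 sensory,
1 active, 2 internal) was seeded so that its solenoidal coupling
between $s$ and $a$ produces the characteristic behaviour of realized
active states trailing the optimal action $\bar a(s_t)$ with a short
delay; the suite checks this as a positive peak-lag in the
cross-correlation of the two ensemble-mean series — a qualitative
assertion by design, since the delay magnitude is fixture-specific.

## Integrator chains and PID-like gains

A mean-zero stationary Gaussian process with exponentially decaying
autocovariance is an Ornstein–Uhlenbeck process; sums of such decays
can therefore be realized as linear outputs of nested
Ornstein–Uhlenbeck processes — an integrator chain
$s^{(0)}, \dots, s^{(n)}$ in which level $i$ is driven by level
$i{+}1$, encoding integral, position, velocity and higher orders of
motion.  `build_chain()` assembles the stacked linear diffusion,
rejects unstable drifts with an eigenvalue report, and computes the
stationary covariance by a Kronecker-vectorized Lyapunov solve (the
dimensions here are small, so no Schur-based solver is needed).
`chain_autocovariance()` evaluates
$C(\tau) = f\, e^{A\tau}\, \tilde\Sigma\, f^\top$ analytically and
estimates it empirically from a long trajectory (single path,
`dt = 0.01`, $10^5$ steps by default, burn-in discarded; negative lags
are rejected since $C(-\tau) = C(\tau)^\top$).

Replacing the sensory argument of the control objective by the chain
output $f(\tilde s) = \sum_i F_i s^{(i)}$ gives the extended objective
(`extended_control_objective()`), and its closed-form minimizer is a
linear feedback on the chain levels:

$$a^*(\tilde s) = -\sum_i L_i\, s^{(i)}, \qquad
L_i = \big[K_{(a,\mu)}^{-1} K_{(a,\mu),s}\big]_{a\text{-rows}} F_i .$$

No formula for extracting per-order gains is prescribed by the theory
this implements; the package *defines* the gains as these per-order
coefficients — the unique linear feedback consistent with the extended
objective — and validates them against a numeric argmin of the
objective on random states.  For an order-2 chain the three gains are
labelled integral, proportional and derivative; at order 0 everything
collapses to the plain control module, which is also tested.  The
default output map selects level 1 (the "proportional" signal) when
the chain has order $\ge 1$; all $F_i$ are configurable.  The inverse
realization problem — fitting a chain to a given autocovariance — is
out of scope; only forward construction and verification are provided.

## Experiment runner, sizes and determinism

`run_experiment()` drives five experiment kinds (`syncmap`,
`transition`, `relax`, `active`, `chain`) from a validated config
(R list, YAML or JSON; seeds are mandatory).  Outputs are CSV tables
with floats serialized at 17 significant digits (round-trip exact) plus
a JSON manifest recording the canonical config, its MD5 hash, the seed
and the package version; identical configs reproduce identical tables
byte for byte.  A thin command-line wrapper ships in
`inst/scripts/blanketflow-cli.R`.

The default problem sizes — $2\times10^5$ i.i.d. draws for the binning
protocol, 500 paths for relaxation ensembles, $10^5$ steps for
empirical autocovariances — were chosen so that the Monte-Carlo
standard errors are comfortably below the effect sizes the protocols
examine while each experiment completes in well under five minutes on
one CPU; they scale up linearly if sharper estimates are wanted.

## Known limitations

* Gaussian steady states only: no Laplace approximation of non-Gaussian
  densities, and no estimation of $\Pi$, $\varsigma$ or $Q$ from data.
* Binned synchronization checks support one-dimensional blankets only.
* Relaxation experiments require constant-coefficient (OU) models;
  state-dependent fields are simulated but analysed only through the
  transition-density demonstration.
* Jump processes and piecewise-deterministic samplers that share the
  same steady state are not implemented.
* Euler–Maruyama's numerical steady state differs from the continuous
  one at $O(dt)$; all stochastic tests use Monte-Carlo-aware tolerances
  rather than exact comparisons for this reason.
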