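---
title: "Methods: Bayesian kinetic-model inference in kinfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian kinetic-model inference in kinfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model, the numerical machinery and the design
choices behind `kinfer`, in the spirit of a methods section: what is
computed, under which assumptions, with which tunable constants, and where
the limits are.

## The process model

A network is a stoichiometric matrix $S$ (metabolites $\times$ reactions)
plus mechanism and regulation annotations.  Metabolites are either
*balanced* (state variables forced to steady state) or *boundary*
(fixed per-condition concentrations, treated as unknown parameters with
priors).  The steady-state condition is

$$ S_{bal}\, v(E, C, \theta) = 0, $$

which assumes (i) a pseudo-steady state — intracellular turnover is fast
relative to the duration of the experiment — and (ii) negligible dilution by
growth, so no $\mu C$ term appears on the right-hand side.  Each
enzyme-catalyzed flux factorizes as

$$ v = E \cdot k_{cat} \cdot \mathrm{rev} \cdot \mathrm{sat} \cdot
      \mathrm{allo} \cdot \mathrm{phos}. $$

*Reversibility.* $\mathrm{rev} = 1 - Q/K_{eq}$ with
$K_{eq} = \exp(-\Delta_r G^\circ / RT)$ and
$\Delta_r G^\circ = S^\top \Delta_f G^\circ$.  Only the forward $k_{cat}$ is
a parameter; the reverse rate enters exclusively through this factor, so the
Haldane relationship — and with it thermodynamic consistency, including an
exactly zero net flux at equilibrium — holds by construction rather than by
constraint.  Irreversible mechanisms fix the factor at 1.

*Saturation.* The **common modular** variant of the modular rate law:
with $x_i = C_i/K_{m,i}$,
$$ \mathrm{sat} = \frac{\prod_{sub} x_i^{|s_i|}}
   {\prod_{sub}(1+x_i)^{|s_i|} + \prod_{prod}(1+x_j)^{|s_j|} - 1
    + \sum_k C_k/K_{i,k}}. $$
The product binding polynomial is omitted for irreversible mechanisms
(declared competitive inhibitors, including products, still enter the
denominator).  Competitive inhibition is linear and non-cooperative
($C/K_i$).  The literature defines several modular variants; the common
variant was chosen because it is the standard default and needs no extra
parameters.

*Allostery.* The generalized Monod–Wyman–Changeux two-state model: the
free-enzyme ratio $r = 1/D$ couples active-site occupancy to the
tense/relaxed equilibrium, giving
$1 / (1 + L\,(r\,(1+\sum C/K_{inh})/(1+\sum C/K_{act}))^n)$ with transfer
constant $L$ and subunit number $n$.

*Phosphorylation.* Coupled kinase/phosphatase regulation contributes
$(1 + p/d)^{-n}$, with dimensionless per-condition rate weights $p$ (sum of
kinase weights) and $d$ (sum of phosphatase weights, defaulting to 1 when no
phosphatase is declared).  This concrete functional form is a
deliberately simple MWC-inspired stand-in: it is 1 without kinase activity,
strictly decreasing in $p$, and cooperative through $n$.  Allostery and
phosphorylation are kept as two separate multiplicative factors, so the
six-way decomposition multiplies back to the flux exactly; an
implementation that merges them would change the decomposition report but
not the flux.

*Drains and knockouts.*  A drain's flux equals a per-condition sign-free
parameter (exchange with unmodeled pathways; no thermodynamics, factor
fields reported as 1).  A knocked-out enzyme has $E = 0$ exactly, so its
flux is exactly zero, not merely small.

Units are fixed by convention, not inferred: concentrations mM, fluxes
mM/s, energies kJ/mol, temperature K (default 298.15), with
$R = 0.008314\ \mathrm{kJ\,mol^{-1}K^{-1}}$.

## Statistical model

Every scalar unknown carries a prior: log-normal for
positivity-constrained parameters ($k_{cat}$, $K_m$, $K_i$, $L$,
dissociation constants, enzyme and boundary concentrations, phosphorylation
weights), normal for sign-free ones (drain fluxes), and one multivariate
normal for the formation-energy vector, whose covariance lets correlated
thermodynamic information be expressed.  Per-condition unknowns (enzyme
concentrations, boundary concentrations, drain fluxes, phosphorylation
weights) are parameters, not fixed inputs.

Measurements are conditionally independent given the state:
concentration and enzyme records are log-normal with known sd around the
log of the modeled value (constant coefficient of variation, no mass on
negative concentrations); flux records are normal with known sd around the
steady-state flux.  Measurement sds are fixed, not estimated.  Boundary
metabolite and enzyme measurements compare directly to the corresponding
parameters; balanced-metabolite and flux measurements compare to solved
steady-state quantities.  Flux measurements should only be entered for a
network's free fluxes; `validate_free_fluxes()` computes
$f = \#\mathrm{reactions} - \mathrm{rank}(S_{bal})$ with exact rational
arithmetic and warns (never errors) about over-complete or linearly
dependent flux measurement sets.

Sampling runs on an unconstrained vector: positive parameters are
log-transformed (the exp-transform Jacobian is part of the target density).

## Steady-state solving

`solve_steady_state()` is a hybrid: the kinetics ODE is first evolved in
log-concentration coordinates (positivity is structural) with an adaptive
Rosenbrock 2(3) pair — linearly implicit and L-stable, appropriate for the
stiff dynamics of saturated pathways — and the evolved state seeds a damped
Newton iteration on $S_{bal} v = 0$.  On Newton failure the evolution time
doubles, up to `max_retries` times.  Non-convergence is a structured result
(`converged = FALSE`, best residual), which the sampler maps to a rejected
proposal; it is never an R error, because proposal rejection is an ordinary
event in tail regions of the posterior.

Defaults (all exposed in `solver_config()` / the `[solver]` section):
`t_evolve` 30 s, ODE `rel_tol` 1e-9 / `abs_tol` 1e-12, Newton tolerance
1e-8 mM/s on the infinity norm of the net production rates, 50 Newton
iterations, 4 retries.  `t_evolve` is a fixture-scale choice (benchmark
relaxation times are well under a second).

Gradients use the implicit function theorem at the fixed point,
$dC^*/d\theta = -(\partial f/\partial C)^{-1} \partial f/\partial\theta$ —
exact at the solution and far cheaper than differentiating through ODE
steps.  All Jacobians of the rate law are batched central differences
evaluated in compiled code (log-concentration step $10^{-6}$; parameter
steps $10^{-6}$ on the unconstrained scale for positive parameters); with
$f = O(1)$ this yields roughly 10 significant digits, comfortably inside
the 1e-4/1e-5 relative agreement the test suite demands against
finite-differencing the entire solve.  The likelihood gradient itself is
assembled adjointly (one linear solve per condition), so its cost does not
scale with the parameter count of the perturbation set.

Numerical guards worth knowing: the thermodynamic exponent in the
reversibility factor is capped at 500 so that an absurd proposal produces a
huge-but-finite negative factor instead of `Inf`/`NaN` contagion; Newton
steps are capped at 4 natural-log units with step-halving line search;
inside the sampler, steady states are warm-started from the previous
leapfrog point and fall back to the full hybrid scheme when Newton leaves
the basin.

## Posterior computation

`sample_posterior()` implements multinomial no-U-turn sampling with
Stan-style adaptation: dual averaging of the step size toward a target
acceptance statistic (default 0.8; $\gamma = 0.05$, $t_0 = 10$,
$\kappa = 0.75$), a diagonal metric estimated in expanding warmup windows
(75-iteration initial buffer, 25-iteration base window doubling, 50-iteration
terminal buffer), trajectory doubling capped at `max_tree_depth` (default
10), and divergence flagged when the Hamiltonian error exceeds 1000.
Initialization draws unconstrained coordinates uniformly within $\pm 2$ of
the prior locations, re-drawing (up to 100 times) until the joint density is
finite; a model whose every initialization fails raises a structured error
suggesting wider initial concentration guesses.  Identical seed and
configuration reproduce draws bitwise; chains are advanced sequentially from
one seeded RNG stream.

`laplace_approximation()` finds the MAP on the unconstrained scale (BFGS
with the analytic-adjoint gradient), takes the covariance as the inverse
negative Hessian (central differences of the gradient, step $10^{-4}$), and
back-transforms multivariate-normal draws.  Draws that land on steady-state
failures are dropped and counted, mirroring the practical fragility of
mode-centred approximations for these posteriors.  A non-positive-definite
Hessian is an error that reports the eigenvalues.

Diagnostics follow the improved definitions: rank-normalized split
$\hat R$ (maximum of bulk and folded variants), bulk ESS on rank-normalized
split chains, tail ESS as the minimum ESS of the 5%/95% indicator
functions, with Geyer's initial positive monotone sequence for the
autocorrelation sums.  A single chain is handled by splitting into four
segments, with a warning.  `ks_two_sample()` computes the classical
two-sample Kolmogorov–Smirnov $D$ from the empirical CDF definition and
delegates the p-value to `stats::ks.test`; `compare_draws()` applies it to
the total log-density draws and every marginal, which is the operational
test for "is the Laplace approximation good enough here".

## Derived quantities

Per draw, the package recomputes steady states, fluxes and the six-way
factor decomposition (one batched compiled evaluation per condition).
`regulatory_log_ratios()` reports per-factor log-ratios between two
conditions; exclusions are structural, not numeric: $k_{cat}$ is shared
across conditions (ratio identically zero), irreversible mechanisms have no
reversibility ratio, drains expose only the flux.  The included factor
log-ratios sum to the flux log-ratio exactly, per draw.  The probability of
a factor acting in each direction is the fraction of posterior mass on each
side of zero.

`control_coefficients()` differentiates the steady state with respect to
reaction *activities* — enzyme concentrations for catalyzed reactions and
the drain flux parameters for drains.  Because every activity enters its
rate linearly, scaling all activities together scales all fluxes and leaves
the steady state fixed, so the summation theorems hold in generalized form
(flux-control rows sum to 1, concentration-control rows to 0); the test
suite enforces them at 1e-6.  Control coefficients can be computed per draw
(`control_coefficient_draws()`, thinned, since each draw costs a sensitivity
solve) rather than only at a point estimate, matching the treatment of all
other derived quantities.  Residual reports use the posterior median as the
point estimate, which is robust to the skew of log-normal scales.

## The synthetic-data module

The generator is the package's stated experimental world, not a tuning
knob.  Measurement noise defaults are log-scale sd 0.1 for concentration
and enzyme records (about 10% error, a mildly optimistic but standard
reading of quantitative metabolomics/proteomics) and flux sd equal to 10%
of the simulated value, floored at 1e-6 mM/s so a near-zero flux never
produces a degenerate record.  Only a linearly independent set of free
fluxes is measured, selected greedily with exact rational rank tests, so
the simulated studies never double-count flux information.  Ground truth is
drawn from the priors; `draw_true_parameters(offset=)` can push selected
parameters away from their prior locations (in units of prior sd) to
emulate in-vitro/in-vivo disagreement.  Train/validation splitting assigns
the conditions with the most extreme total flux magnitude to validation, so
held-out prediction probes extrapolation rather than interpolation.

Three fixtures form a ladder:

* `linear_chain_2` — a drain feeding one irreversible Michaelis–Menten
  step; the steady state has the closed form
  $M^* = d K_m / (E k_{cat} - d)$, anchoring solver, sensitivity and
  control-coefficient tests analytically.
* `allosteric_cycle_3` — three reactions exercising reversibility,
  saturation, competitive inhibition, allosteric activation and inhibition,
  and an irreversible step; four conditions differing in their boundary
  substrate level (prior locations 1, 2.5, 0.4, 1.5 mM) to create the flux
  contrast that regulatory decomposition and train/validation splitting
  need.  This is the benchmark the acceptance script refits.
* `methionine_like_5` — five balanced metabolites in a cycle with entry,
  two exits, one 2:1 stoichiometry, allosteric feedback, a
  phosphorylated/dephosphorylated enzyme and a cycle-closure knockout
  condition.  Enzyme prior locations size the entry reaction as the
  bottleneck (0.005 mM versus 0.02–0.03 mM downstream) so that steady
  states exist robustly across prior draws even under the knockout and the
  stoichiometric amplification — a deliberate design requirement, since a
  fixture that frequently has no steady state cannot serve as a test bed.

What a green test on these fixtures does **not** establish: behavior at
genome scale; identifiability when measurements are sparse or conditions
few (marginal kinetic parameters generally stay prior-dominated — the
information is in the correlation structure); correlated measurement
errors; isotope-labeling likelihoods; multiple steady states (the solver
finds the basin of its initial guess and does not search for others).

## Deliberately difficult test fixtures

Two tiny models are built to *fail* specific approximations.  A
linear-Gaussian fixture (a drain flux with a normal prior and one normal
flux measurement) has an exactly Gaussian posterior, so the Laplace
approximation must agree with MCMC there.  A curved fixture measures one
irreversible Michaelis–Menten flux tightly (2%) under wide ($\sigma = 1.5$)
priors on $\ln k_{cat}$ and $\ln K_m$: the likelihood constrains
$\ln k_{cat} - \ln(1 + e^{\ln K_m - \ln C})$, a softplus ridge that no
Gaussian matches, so the Kolmogorov–Smirnov comparison of log-density draws
must reject.  Both directions are asserted.

## Known limitations

* Rate-law derivatives are high-accuracy finite differences, not symbolic;
  pathological parameter scales (far outside the priors of any sensible
  model) could degrade them.
* The NUTS implementation uses the basic extreme-point U-turn criterion
  (plus the combined-momentum check) rather than Stan's additional
  cross-subtree checks; this affects efficiency slightly, not correctness.
* The diagonal metric handles the benchmark posteriors; strongly banana-
  shaped high-dimensional targets would profit from a dense or Riemannian
  metric that is not implemented.
* One conformational modifier set per enzyme: multiple independent
  allosteric sites are summed inside one MWC factor, not modeled as
  separate transitions.
* TOML support covers the documented input subset (tables, arrays of
  tables, inline tables, arrays, scalars), not the full specification
  (no dates, no multi-line strings).
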