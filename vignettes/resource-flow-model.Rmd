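---
title: "An energy-budget model of eco-evolutionary dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An energy-budget model of eco-evolutionary dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`ecoflow` simulates evolution as a consequence of energy flow rather than of
an imposed fitness function. Individuals carry an internal energy budget
$\epsilon_\alpha$; they acquire energy from two sources — a basal
environmental resource that regenerates at rate $\lambda$ per lattice site
per step, and payoffs $\pi_\alpha$ from a game played with the co-occupants
of their site — and they dissipate energy at a metabolic rate $\eta$:

$$\epsilon_\alpha(t) = \epsilon_\alpha(t-1) + \kappa_\alpha(t) +
\pi_\alpha(t) - \eta.$$

An individual whose energy is exhausted dies; one whose energy exceeds the
division threshold $d$ splits in two, sharing its energy equally with an
offspring that inherits its strategy, flipped with mutation probability
$\nu$. Selection is therefore *emergent*: types that turn energy into
divisions faster outgrow the rest.

The game is a public goods game: cooperators invest a cost $c$ per step into
a common pot, the pot is multiplied by an enhancement factor $r > 1$ and
shared equally by everyone on the site, defectors included. A lone
cooperator keeps its own multiplied investment (net $c(r-1)$); a site's
total net production is $(r-1) c k_C$. The game sits behind a minimal
interface (`pgg_payoffs()`: group strategies in, payoffs out), so other
interactions can be substituted without touching the engine.

## Update cycle

Each step applies five stages in a fixed order, to all individuals
synchronously:

1. **Gather & play** — each occupied site's entire standing basal stock is
   split equally among its occupants; each site plays one round of the game;
   energy is credited.
2. **Reproduce** — every individual with $\epsilon > d$ divides once
   (strictly greater; a single binary fission per step even if
   $\epsilon/2 > d$, the excess resolving next step). Offspring start on the
   parent's site.
3. **Move** — each individual (newborns included) relocates with
   probability $q$: to a uniformly chosen Moore neighbour on the lattice
   topology (periodic boundaries), or to a uniformly chosen site — the
   current one included — in the mixed topology.
4. **Metabolize & cull** — everyone pays $\eta$; individuals strictly below
   zero die. A fully extinct population is rescued by one immigrant with a
   uniform random strategy.
5. **Regenerate** — every site's stock increases by $\lambda$.

Unoccupied sites accumulate stock without cap. This choice makes the mean
per-capita basal intake in a well-mixed population exactly $\lambda/\rho$
(all inflow is eventually consumed), which is what the equilibrium theory
assumes; the package's instrumented runs confirm it to three decimal places.

## Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `lambda` | basal regeneration per site | 0.6 | energy / site / step |
| `eta` | metabolic rate | 0.4 | energy / individual / step |
| `d` | division threshold | 2 | energy |
| `r` | enhancement factor | — | dimensionless, $> 1$ |
| `cost` | cooperator investment | 0.1 | energy / step |
| `nu` | mutation probability per birth | $10^{-4}$ | — |
| `q` | movement probability | 1 | — |
| `L` | lattice side | 100 | sites |

The defaults are the reference conditions used throughout the package's
figures and tests ($\lambda = 0.6$, $\eta = 0.4$, $d = 2$, $c = 0.1$,
founders all defectors, 100 of them, each with energy $d/2$). The cost
should be small relative to $d$; the regime $c \ll d$ is where the
energy-budget corrections discussed below stay small.

# Equilibrium theory (perfect mixing)

Two principles pin down the stationary state of the well-mixed model
($q = 1$): **resource conservation** — production balances consumption,

$$(r-1)\,c\,\rho_C + \lambda = \eta\,(\rho_C + \rho_D),$$

and **payoff equality** — coexisting types acquire equal total per-capita
resources. With uniform mixing the number of co-players is Poisson
distributed, and averaging the game over that mixture gives closed forms
which the package evaluates through the shared kernel
$g(\rho) = (\rho - 1 + e^{-\rho})/\rho^2$:

$$\bar\pi_C = c(r-1) - r c \rho_D\, g(\rho), \qquad
  \bar\pi_D = r c \rho_C\, g(\rho).$$

These are algebraically identical to the sum-over-Poisson forms (the
package's tests verify both the re-arrangement and agreement with
million-draw Monte Carlo); the kernel form is numerically stable, and a
series expansion of $g$ below $\rho = 10^{-4}$ removes the $0/0$ at small
densities, making the lone-cooperator limit $\bar\pi_C \to c(r-1)$ exact.

Solving the two principles yields three branches (`eq_densities()`):
defectors only at $\rho_D = \lambda/\eta$; coexistence with total density
$\rho = r + W_0(-r e^{-r})$ (a function of $r$ alone) split by the
conservation law; and full cooperation at
$\rho_C = \lambda/(\eta - (r-1)c)$. Cooperation invades iff

$$r > r^* = \frac{\lambda/\eta}{1 - e^{-\lambda/\eta}},$$

a function of the inflow-to-dissipation ratio only; in the $\lambda \to 0$
limit the persistence condition becomes $r > 1 + \eta/c$ (each cooperator's
surplus must cover its own metabolism). $W_0$ is evaluated with
`pracma::lambertWp`, its argument clamped to $\ge -1/e$ against rounding;
branch selection treats $|\rho^{II}| < 10^{-12}$ as the boundary.

# The mean-field flow

The dynamical mean field grows each type at its per-capita net gain
$F_s = \bar\pi_s + \lambda/\rho - \eta$, mixed by mutation:
$\dot\rho_C = (1-\nu) F_C + \nu F_D$ and symmetrically for $\rho_D$. Its
fixed points are exactly the equilibrium branches; note that because a
fixed point of the mixed flow requires $F_C = F_D = 0$, the coexistence
point is exactly $\nu$-independent, while for $\nu > 0$ single-strategy
states survive only as *projected* equilibria of the clamped flow.

Numerical choices, none of which the theory dictates:

* **Integrator**: `deSolve::ode` with `lsoda` (adaptive, stiff-capable),
  `rtol = 1e-8`, `atol = 1e-10`. Non-negativity is enforced by a
  *continuous* projection — derivatives are evaluated at the clamped state
  and marginally negative components feel a restoring pull — because a hard
  derivative freeze makes the right-hand side discontinuous and stalls the
  stiffness detector.
* **Jacobian**: central differences with step $10^{-6}$ (configurable), on
  the analytic continuation of the payoff forms so boundary points can be
  differenced.
* **Fixed points**: Newton iteration seeded from the closed-form branches.
* **Onset of fluctuations**: the coexistence point undergoes a Hopf-type
  loss of stability as $r$ grows; `mf_fluctuation_onset()` bisects the
  leading eigenvalue's real part in $r$ to $10^{-4}$. At the reference
  conditions the crossing sits near $r_c \approx 9.2$, with complex
  eigenvalues on both sides of it and sustained bounded oscillations above.
  Phase classification (`mf_phase_diagram()`) is mean-field based;
  `classify_phase_sim()` provides the simulation-based cross-check.

# Observables

`summarize_run()` takes arithmetic time averages after a burn-in. Per-type
payoff and basal means average over the individuals alive at the gather
stage; birth and death rates divide per-step counts by that stage's type
population (births are attributed to the *parent's* strategy). Oscillation
is flagged when the coefficient of variation of $\rho_C$ over the window
exceeds 0.15 — calibrated so that stable coexistence runs at small $r$ pass
as quiet — and cooperation is called "present" in phase scans when the
time-averaged cooperator fraction exceeds $m_{\min} = 0.05$ (mutation alone
maintains a much smaller fraction). Both cutoffs are arguments, not
constants. Lifespan distributions use unit-age bins; the exponential tail
rate is a least-squares slope on log counts over the upper half of the
occupied bins (bins with $\ge 5$ deaths, $\ge 30$ deaths in total, else the
fit is flagged off).

# What the simulator does and does not emulate

The engine *is* the data generator for all tests: there is no external
data. Its defaults reproduce the study conditions of the reference figures
(all-defector founders, 100 individuals, $T$ of a few thousand steps,
averages after equilibration). Test problem sizes are scaled to
$L = 50$, $T = 5000$, burn-in 2000 (and $T = 1500$ for the
near-zero-$\lambda$ boom-bust runs, whose populations transiently reach
$10^6$ individuals); these were chosen as the smallest sizes at which the
stationary averages are insensitive to doubling either dimension, except as
noted below.

Passing tests therefore show internal consistency of model, theory and
mean field — they do not show that any *empirical* system behaves this way.
Two model-intrinsic caveats surfaced by the package's own instrumentation
are worth knowing:

* **Finite-$d$ corrections.** The continuum theory is free of the division
  threshold $d$, but the agent model is not: dying agents export a residual
  energy of order $\eta/2$ each, shifting the effective dissipation by
  $\sim$1–2% at the reference turnover rates. The total and majority
  densities land within a few percent of the Lambert-W branch, but the
  *minority* component amplifies the shift (at $r = 2.5$, $d = 2$ the
  defector density sits $\sim$10% above branch II, independent of $L$ and
  strongly $d$-dependent). This is a property of the model, not a numerical
  artefact.
* **Near-zero regeneration.** For $\lambda$ close to zero with
  $(r-1)c > \eta$ the model alternates violent booms (fed by stock
  accumulated across empty sites during busts) and near-extinctions; time
  averages remain well-defined but individual trajectories are extreme.

# Known limitations

No closed-form theory is attempted for viscous populations ($q < 1$):
limited dispersal builds assortment that the Poisson mixture cannot see,
and all viscous predictions are simulation-only. There is no spatial
(travelling-wave) mean-field theory; lattice waves are available only as
snapshot grids. Lifespans of zero steps (birth and death in the same step)
are possible in principle for extreme parameter choices, though not in the
$d \gg \eta$ regime used throughout. The extinction-rescue immigrant makes
the all-defector absorbing state technically non-absorbing at
$\lambda \approx 0$; immigration events are flagged in the output so
windows containing them can be excluded if desired.
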