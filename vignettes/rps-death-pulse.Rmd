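---
title: "Pulse perturbations in a cyclic three-species ecosystem"
author: "rpspulse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulse perturbations in a cyclic three-species ecosystem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`rpspulse` simulates a rock–paper–scissors ecosystem of three species $A$,
$B$, $C$ in the May–Leonard formulation: total abundance is not conserved,
predation opens a vacancy and reproduction fills one, so vacancies carry a
density $\rho_v$ of their own and the bookkeeping obeys

$$\rho_a + \rho_b + \rho_c + \rho_v = 1 .$$

Three event types drive the dynamics, with $A$ preying on $B$, $B$ on $C$,
$C$ on $A$:

* predation: $X + \mathrm{prey}(X) \to X + V$ with rate $p$,
* reproduction: $X + V \to 2X$ with rate $r$,
* spontaneous death: $X \to V$ with rate $d$.

The perturbation of interest is a *death pulse*: the death rate of one
species (by default $A$) is raised by $\Delta d$ on the closed time window
$[\mathrm{onset}, \mathrm{onset} + \tau]$ and returns to $d$ afterwards
(`effective_death_rate()`, `pulse_spec()`). The package asks what becomes
of the ecosystem long after such a transient insult: does coexistence
recover, or does a single species take over — and which one?

All reference experiments use the symmetric rate set $p = 0.2$, $r = 0.4$,
$d = 0.1$, which supports coexistence in the unperturbed system.

## Two engines

### Lattice Monte-Carlo

`run_lattice()` works on an $L \times L$ square lattice with periodic
boundaries whose sites hold one individual or are vacant. One elementary
event picks an occupied site uniformly (rejection sampling over sites),
tests **death first** with the pulse-adjusted probability, and otherwise
lets the occupant act on one uniformly chosen von Neumann neighbour:
reproduce into a vacancy with probability $r$, or convert a cyclic-prey
neighbour to vacancy with probability $p$ (the predator does not move).
One time unit is $N = L^2$ elementary events (one sweep on average), and
the pulse clock runs in sweep units. Extinction on the lattice is an exact
zero count — the absorbing states of the finite chain.

The update rule is verified against an exhaustive enumeration of the
single-event transition distribution on a $2\times2$ lattice (where the two
vertical directions reach the same site, as do the two horizontal ones),
and by conservation and cyclic-relabelling tests.

### Discrete-time stochastic rate equations

`run_sde()` integrates the mean-field rate equations with explicit Euler
steps of size `dt` (default $10^{-3}$):

$$\dot\rho_a = \rho_a\!\left[\tilde r\,\rho_v - p\rho_c - (d + d'(t))\right],
\qquad
\dot\rho_b = \rho_b\!\left[\tilde r\,\rho_v - p\rho_a - d\right],
\qquad
\dot\rho_c = \rho_c\!\left[\tilde r\,\rho_v - p\rho_b - d\right],$$

with $d'(t) = \Delta d$ inside the pulse window. The reproduction rate
$\tilde r$ is redrawn **independently per species per step**: Gaussian
$r + 0.05\,\mathcal N(0,1)$ by default, a uniform variate of full width
0.2, or a multiplicative lognormal factor with median 1 (`noise_spec()`).
The noise is a random per-step parameter, deliberately *not* scaled by
$\sqrt{dt}$: the model is a discrete-time system, so its statistics depend
on `dt`, which is therefore recorded in every output. The lognormal shape
parameter equals the `scale` argument; this parameterisation is our choice,
as only the noise family is prescribed.

A species whose density falls below the extinction threshold
$\varepsilon = 10^{-6}$ is set to exactly zero and cannot return; this
prevents numerically undead densities of $10^{-300}$ from steering the
dynamics. Runs stop when at most one species remains, or at the horizon
`t_max`.

## Fixed point, stability, and what the noiseless flow does

For symmetric rates the interior (coexistence) fixed point solves
$r(1 - 3\rho) - p\rho - d = 0$:

$$\rho^* = \frac{r - d}{3r + p} = \frac{0.3}{1.4} \approx 0.2143,
\qquad \rho_v^* = 1 - 3\rho^* .$$

`interior_fixed_point()` returns this value, and the noiseless engine
started there is stationary to machine precision. The linearisation at
$\rho^*$ has one strongly stable direction (eigenvalue $-0.3$) and an
unstable spiral pair with $\mathrm{Re}\,\lambda = +0.0214$: a *symmetric*
initial state such as $(0.3, 0.3, 0.3)$ flows straight into the fixed
point along the symmetric manifold, while any asymmetric perturbation
spirals outward towards the heteroclinic boundary and ends in a
single-species absorbing state. Both behaviours are real; which one a
noiseless run shows depends only on whether its start is exactly
symmetric.

## The early-pulse decay law

Started at the fixed point, the background growth term
$r\rho_v - p\rho_c - d$ vanishes, so at pulse onset the pulsed species
obeys $\dot\rho_a \approx -\Delta d\,\rho_a$, a Malthusian decay
$\rho_a(t) = \rho^*\,e^{-\Delta d\,t}$ (`predicted_density()`).
`fit_decay_rate()` estimates the rate by ordinary least squares on
$(t, \ln\rho_a)$, without smoothing, for both engines.

The law is exact only at $t = 0$: as $A$ thins out, vacancies accumulate
and feed back through $r\rho_v$. Numerically the relative deviation of the
log-drop grows about linearly in $t$ — roughly 1% at $t = 0.2$ and 3.6% at
$t = 1$ — so the default fit window of one time unit recovers $\Delta d$
to about 4%, and shorter windows do monotonically better. Fits over the
whole pulse are reported with their (larger) residual rather than
corrected.

## Outcomes, the pulse plane, and what reproduces

`classify_outcome()` labels a final state by which species sit above
$\varepsilon$: `coexistence`, a single-survivor state, or `all_extinct`.
Two edge decisions are ours and worth stating:

* **Two species at the horizon** count as `coexistence`. The label set has
  no two-species value, and such states are transient; diversity has not
  collapsed to one species, so we do not crown a survivor early.
* **Undecided runs exist for a structural reason.** Once one species dies,
  a rare run can reach a state with a tiny invader under a resident near
  its one-species equilibrium $\rho = 1 - d/r$. There the invader's mean
  log-growth is exactly $r\,(d/r) - d = 0$: a quasi-neutral random walk
  whose exit time at realistic noise amplitudes exceeds $10^7$ time units.
  No finite horizon resolves these runs, so ensemble statistics
  (`run_sde_ensemble()`, `survival_map()`) report survivor shares among
  decided runs; by the three-fold symmetry this estimates the same
  distribution as an idealised fully resolved ensemble. At the default
  horizon of 20000 time units roughly a fifth of no-pulse runs remain
  undecided.

No-pulse ensembles give each species one third of the wins for Gaussian,
uniform and lognormal noise alike (chi-square tested). On the lattice the
unpulsed densities oscillate around $\approx 0.21$–$0.22$, consistent with
$\rho^* = 0.2143$.

`survival_map()` tallies outcomes over a $(\Delta d, \tau)$ grid; seeds
derive per cell and run as `derive_seed(base, i, j, k)`, so any cell is
recomputable in isolation. On the lattice the map reproduces the reference
structure: coexistence at small pulses, and $B$ — the species *eaten by*
the pulsed one — taking over with probability near 1 once $\Delta d \cdot
\tau$ is a few units. The affected species' own counter-intuitive survival
patch appears in the rate-equation engine at small pulses.

The rate-equation plane, however, is banded rather than monotone. With the
weak per-step noise the post-pulse state is nearly deterministic, and the
winner is selected by the phase of the spiral at pulse end: $B$ wins in a
band near $\Delta d \cdot \tau \approx 0.2$, while at strong scaled pulses
$C$'s crash bottoms out near $10^{-3}$ — far above $\varepsilon$ — so $C$
survives, the recovering $A$ eliminates $B$, and the final state is
$A$-only or $C$-only. Broad $B$-dominance at large scaled pulses would
require the pulsed species to die first, which at one tenth of the lattice
pulse heights is impossible under $\varepsilon = 10^{-6}$; equivalently,
the engines' pulse scales then agree only up to a factor we measure at
about 20–25 rather than 10. We keep the threshold fixed and report this
divergence rather than tuning $\varepsilon$ until the maps match; the
corresponding acceptance checks are expected to fail and say so.

## Numerical and design choices

* **Random numbers.** One generator family everywhere: xoshiro256++
  seeded via splitmix64, with a 128-strip ziggurat normal sampler
  (statistically verified in the tests). Every run takes an explicit
  integer seed; child seeds come from `derive_seed()`, a documented
  splitmix64 mix that is stable across platforms. No global RNG state is
  consumed except where tests use R's own generator for test statistics.
* **Engines in C++.** Both inner loops are Rcpp; a no-pulse rate-equation
  step costs ~30 ns, a lattice sweep of $200^2$ sites ~2 ms. The exported
  `sde_step()`/`mc_elementary_update()` are the same arithmetic at R level
  and the noiseless engine is tested to replay `sde_step()` bit for bit.
* **Defaults.** `dt = 0.001`; $\varepsilon = 10^{-6}$; rate-equation runs
  start at $(0.3, 0.3, 0.3)$, lattice runs at the fixed point with random
  arrangement (optional burn-in available); pulse onset 0 on the lattice
  and 50 in rate-equation pulse experiments, so the noisy state has
  settled near the fixed point when the pulse lands; classification
  horizon 5000 by default, 20000 for survivor-share ensembles.
* **Problem sizes in the shipped checks.** Survivor shares: 1000 runs in
  the acceptance script, 300–600 in the test suite; lattice density:
  $100^2$–$200^2$ sites averaged over 1500 sweeps after a 100-sweep
  transient; phase maps: coarse grids with 12–25 runs per cell. These are
  the package's reporting choices; all are configurable.

## What the simulations do and do not emulate

The engines generate the model's own study conditions — symmetric rates,
one pulsed species, spatially unstructured (rate equations) or
nearest-neighbour (lattice) interactions. They do not emulate demographic
structure, mobility beyond nearest-neighbour predation/reproduction,
mutation, multiple or recurring disturbances, or asymmetric rate sets
(the fixed-point analysis is symmetric-only by scope). Passing tests
therefore support conclusions about this idealised ecosystem, not about
any field system.

## Known limitations

* Explicit Euler with per-step parameter noise means statistics depend on
  `dt`; there is no Itô/Stratonovich limit intended, and no higher-order
  integrator is provided.
* The quasi-neutral trap described above makes "run until one species
  remains" an unattainable protocol for a minority of runs; all shipped
  statistics define themselves over decided runs instead.
* Lattice rates double as per-attempt probabilities and must lie in
  $[0, 1]$.
* The single-species lattice density sits a few percent below the
  mean-field value $(r - d)/r$ because occupied sites cluster; the
  mean-field number is a guide, not a test oracle.
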