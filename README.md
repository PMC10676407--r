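# rpspulse

Tools for asking what a transient catastrophe does to a balanced
ecosystem. `rpspulse` simulates a three-species rock–paper–scissors
community in the May–Leonard formulation — $A$ preys on $B$, $B$ on $C$,
$C$ on $A$; predation opens vacancies, reproduction fills them — in which
one species suffers a finite-duration elevation of its death rate
("death pulse"): epidemics, heatwaves and similar events that raise
mortality of selected species for a while and then subside.

With site fractions $\rho_a + \rho_b + \rho_c + \rho_v = 1$ and symmetric
rates (predation $p$, reproduction $r$, death $d$), the mean-field
dynamics are

$$\dot\rho_a = \rho_a\left[\tilde r \rho_v - p\rho_c - (d + d'(t))\right],
\quad
\dot\rho_b = \rho_b\left[\tilde r \rho_v - p\rho_a - d\right],
\quad
\dot\rho_c = \rho_c\left[\tilde r \rho_v - p\rho_b - d\right],$$

where $d'(t) = \Delta d$ for $\mathrm{onset} \le t \le \mathrm{onset} +
\tau$ and $\tilde r$ carries per-step reproduction noise. The package
provides:

* a **lattice Monte-Carlo engine** (`run_lattice()`): $L \times L$
  periodic lattice, von Neumann neighbourhoods, death-checked-first event
  ordering, one time unit = $L^2$ elementary events;
* a **discrete-time stochastic rate-equation engine** (`run_sde()`),
  explicit Euler with Gaussian / uniform / lognormal reproduction-rate
  noise, and a noiseless deterministic mode;
* **outcome classification** (`classify_outcome()`): coexistence,
  single-survivor states, total extinction;
* **survival-probability maps** over the $(\Delta d, \tau)$ plane
  (`survival_map()`) and a cross-engine pulse-scale comparison
  (`compare_engines()`);
* the **early-pulse Malthusian decay law**
  $\rho_a(t) \approx \rho_a^0 e^{-\Delta d\, t}$: closed-form prediction
  (`predicted_density()`) and log-linear rate estimation
  (`fit_decay_rate()`).

It is aimed at theoretical ecologists and statistical physicists studying
cyclic dominance, disturbance–diversity relationships and extinction
dynamics.

## Worked example

Start the deterministic rate equations at the coexistence fixed point
$\rho^* = (r-d)/(3r+p)$, apply a pulse of height $\Delta d = 0.2$ for
$\tau = 15$ time units, and recover the decay rate of the affected
species from the first time unit:

```r
library(rpspulse)

rates <- rate_set_symmetric(p = 0.2, r = 0.4, d = 0.1)
fp <- interior_fixed_point(rates)
fp
#> <densities> a = 0.214286, b = 0.214286, c = 0.214286, vacant = 0.357143

cfg <- simulation_config("sde", init = fp, noise = noise_spec("none"),
                         pulse = pulse_spec(delta_d = 0.2, tau = 15),
                         t_max = 16, record_stride = 10L, seed = 1)
res <- run_sde(cfg)
fit_decay_rate(res$trajectory, window = c(0, 1), species = "a")
#> <decay_fit> rate = 0.192715 over [0, 1] (101 points)
#>   exp(intercept) = 0.214042, RMS log-residual = 0.000497
```

The fitted rate 0.193 sits within 4% of $\Delta d = 0.2$ (the law is
exact only at pulse onset; vacancies feed back as the species thins out),
and the intercept recovers the fixed-point density 0.21.

The same pulse on the lattice ends the story differently — after the
pulse kills $A$, $B$ eats its own prey $C$ unopposed and inherits the
lattice:

```r
cfg_mc <- simulation_config("lattice", L = 100, t_max = 400,
                            pulse = pulse_spec(delta_d = 0.2, tau = 55),
                            seed = 7)
run_lattice(cfg_mc)$outcome
#> <outcome> only_B
#>   extinctions: A at t = 19, C at t = 161
```

`survival_map()` repeats such runs over a grid of pulse heights and
durations and tallies the five outcome probabilities per cell.

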