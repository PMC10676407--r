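#' Noise on the reproduction rate
#'
#' Per-step random perturbation of the reproduction rate in the
#' rate-equation engine. `gaussian` adds `scale * N(0,1)`; `uniform` adds a
#' uniform variate on `[-scale/2, +scale/2]` (`scale` is the full width);
#' `lognormal` multiplies by a lognormal variate with median 1 and shape
#' parameter `scale`; `none` leaves the rate exact.
#'
#' @param kind one of `"none"`, `"gaussian"`, `"uniform"`, `"lognormal"`.
#' @param scale noise amplitude (>= 0); ignored for `kind = "none"`.
#' @return An object of class `noise_spec`.
#' @export
#' @examples
#' noise_spec("gaussian", 0.05)
noise_spec <- function(kind = c("none", "gaussian", "uniform", "lognormal"),
                       scale = 0) {
  kind <- match.arg(kind)
  if (!is.finite(scale) || scale < 0) stop("scale must be >= 0", call. = FALSE)
  if (kind == "none") scale <- 0
  structure(list(kind = kind, scale = scale), class = "noise_spec")
}

noise_kind_code <- function(spec) {
  match(spec$kind, c("none", "gaussian", "uniform", "lognormal")) - 1L
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("<noise_spec> %s (scale = %g)\n", x$kind, x$scale))
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles everything one run needs: the engine, the interaction rates, the
#' death pulse, initial densities, numerical settings and the seed. Defaults
#' follow the reference study conditions: symmetric rates
#' `p = 0.2, r = 0.4, d = 0.1`; lattice runs start from the interior fixed
#' point on a 200 x 200 grid; rate-equation runs start from
#' `(0.3, 0.3, 0.3)` with step size `dt = 0.001` and Gaussian
#' reproduction-rate noise of amplitude 0.05.
#'
#' @param engine `"lattice"` (Monte-Carlo on a 2-D periodic lattice) or
#'   `"sde"` (discrete-time stochastic rate equations).
#' @param rates a [rate_set()]; lattice rates must be <= 1 (they act as
#'   per-attempt probabilities).
#' @param pulse a [pulse_spec()].
#' @param L lattice side length (lattice engine), >= 2.
#' @param init initial [densities()]; default: interior fixed point for the
#'   lattice, `(0.3, 0.3, 0.3)` for the rate equations.
#' @param dt Euler step size (sde engine), > 0.
#' @param t_max classification horizon in time units; must exceed
#'   `onset + tau`.
#' @param epsilon extinction threshold for continuous densities (> 0); on
#'   the lattice extinction is an exact zero count.
#' @param noise a [noise_spec()] (sde engine only).
#' @param seed integer seed for the run's generator.
#' @param record_stride record every `record_stride`-th Euler step (sde);
#'   lattice trajectories are always recorded once per time unit.
#' @param burn_in pulse-free lattice sweeps executed before the clock starts.
#' @return An object of class `simulation_config`.
#' @export
#' @examples
#' simulation_config("sde", t_max = 100)
simulation_config <- function(engine = c("sde", "lattice"),
                              rates = rate_set_symmetric(0.2, 0.4, 0.1),
                              pulse = pulse_spec(0, 0),
                              L = 200,
                              init = NULL,
                              dt = 0.001,
                              t_max = 5000,
                              epsilon = 1e-6,
                              noise = noise_spec("gaussian", 0.05),
                              seed = 1L,
                              record_stride = 100L,
                              burn_in = 0L) {
  engine <- match.arg(engine)
  stopifnot(inherits(rates, "rate_set"), inherits(pulse, "pulse_spec"),
            inherits(noise, "noise_spec"))
  problems <- character()
  if (!is.numeric(L) || L < 2 || L != round(L)) {
    problems <- c(problems, "L must be an integer >= 2")
  }
  if (!is.finite(dt) || dt <= 0) problems <- c(problems, "dt must be > 0")
  if (!is.finite(t_max) || t_max <= pulse$onset + pulse$tau) {
    problems <- c(problems, "t_max must exceed onset + tau")
  }
  if (!is.finite(epsilon) || epsilon <= 0) {
    problems <- c(problems, "epsilon must be > 0")
  }
  if (engine == "lattice" &&
      any(unlist(rates) > 1)) {
    problems <- c(problems,
                  "lattice rates act as probabilities and must be <= 1")
  }
  if (!is.finite(record_stride) || record_stride < 1) {
    problems <- c(problems, "record_stride must be >= 1")
  }
  if (!is.finite(burn_in) || burn_in < 0) {
    problems <- c(problems, "burn_in must be >= 0")
  }
  if (length(problems)) {
    stop(paste0("invalid configuration:\n  - ",
                paste(problems, collapse = "\n  - ")), call. = FALSE)
  }
  if (is.null(init)) {
    init <- if (engine == "lattice") {
      interior_fixed_point(rates)
    } else {
      densities(0.3, 0.3, 0.3)
    }
  }
  stopifnot(inherits(init, "densities"))
  structure(list(engine = engine, rates = rates, pulse = pulse,
                 L = as.integer(L), init = init, dt = dt, t_max = t_max,
                 epsilon = epsilon, noise = noise, seed = as.integer(seed),
                 record_stride = as.integer(record_stride),
                 burn_in = as.integer(burn_in)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> engine = %s, t_max = %g, seed = %d\n",
              x$engine, x$t_max, x$seed))
  print(x$rates)
  print(x$pulse)
  if (x$engine == "lattice") {
    cat(sprintf("  L = %d, burn_in = %d sweeps\n", x$L, x$burn_in))
  } else {
    cat(sprintf("  dt = %g, epsilon = %g, record_stride = %d\n",
                x$dt, x$epsilon, x$record_stride))
    print(x$noise)
  }
  print(x$init)
  invisible(x)
}

# flat echo of a config for embedding into output artifacts
config_echo <- function(config) {
  list(engine = config$engine,
       p = config$rates$p_a, r = config$rates$r_a, d = config$rates$d_a,
       rates = unclass(config$rates),
       delta_d = config$pulse$delta_d, tau = config$pulse$tau,
       onset = config$pulse$onset, target = config$pulse$target,
       L = config$L, init = as.numeric(config$init), dt = config$dt,
       t_max = config$t_max, epsilon = config$epsilon,
       noise.kind = config$noise$kind, noise.scale = config$noise$scale,
       seed = config$seed, record_stride = config$record_stride,
       burn_in = config$burn_in)
}

#' Derive a reproducible child seed
#'
#' Stable cross-platform mixing (splitmix64-based) of a base seed with up to
#' three indices, used for per-cell and per-run seeds in sweeps so any cell
#' can be recomputed in isolation.
#'
#' @param base_seed base integer seed.
#' @param i,j,k non-negative integer indices (e.g. pulse-height index, pulse
#'   duration index, run index).
#' @return An integer-valued double in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, 1, 2, 3)
derive_seed <- function(base_seed, i = 0, j = 0, k = 0) {
  mix_seed_cpp(as.double(base_seed), as.double(i), as.double(j), as.double(k))
}
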