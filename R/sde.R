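#' Draw per-step effective reproduction rates
#'
#' Applies the reproduction-rate noise of a [noise_spec()] to the base rate
#' `r`: one independent draw per requested value, as the rate-equation
#' engine does per species per step. A negative effective rate can occur for
#' large amplitudes and is allowed (a warning is emitted), matching the
#' engine's behaviour; realistic amplitudes keep the rate positive.
#'
#' @param spec a [noise_spec()].
#' @param r base reproduction rate.
#' @param n number of independent draws.
#' @param seed integer seed for the draw stream.
#' @return Numeric vector of `n` effective rates.
#' @export
#' @examples
#' noise_draw(noise_spec("gaussian", 0.05), r = 0.4, n = 5, seed = 1)
noise_draw <- function(spec, r, n = 1, seed = 1) {
  stopifnot(inherits(spec, "noise_spec"))
  out <- noise_draw_cpp(noise_kind_code(spec), spec$scale, r, as.integer(n),
                        as.double(seed))
  if (any(out < 0)) {
    warning("negative effective reproduction rate drawn; ",
            "consider a smaller noise scale", call. = FALSE)
  }
  out
}

#' One explicit Euler step of the stochastic rate equations
#'
#' Advances the densities by one step of the discrete-time system
#' `drho_a/dt = rho_a (r~ rho_v - p rho_c - (d + d'(t)))` (and cyclic
#' analogues for B and C), where `r~` is an independent noise draw per
#' species and `d'(t) = delta_d` inside the pulse window of the target
#' species. Updated species densities below `epsilon` are set to exactly 0
#' and the vacancy fraction is recomputed.
#'
#' @param dens current [densities()].
#' @param rates a symmetric [rate_set()].
#' @param pulse a [pulse_spec()].
#' @param t current time.
#' @param dt step size.
#' @param noise a [noise_spec()].
#' @param seed seed for this step's noise draws (ignored for
#'   `kind = "none"`).
#' @param epsilon clamping threshold: updated densities below it become 0.
#' @return The updated [densities()].
#' @export
#' @examples
#' fp <- interior_fixed_point(rate_set_symmetric(0.2, 0.4, 0.1))
#' sde_step(fp, rate_set_symmetric(0.2, 0.4, 0.1), pulse_spec(0, 0),
#'          t = 0, dt = 0.001, noise = noise_spec("none"))
sde_step <- function(dens, rates, pulse, t, dt, noise = noise_spec("none"),
                     seed = 1, epsilon = 0) {
  stopifnot(inherits(dens, "densities"), inherits(rates, "rate_set"),
            inherits(pulse, "pulse_spec"), dt > 0)
  r <- rates$r_a; p <- rates$p_a; d <- rates$d_a
  re <- noise_draw_cpp(noise_kind_code(noise), noise$scale, r, 3L,
                       as.double(seed))
  dprime <- if (t >= pulse$onset && t <= pulse$onset + pulse$tau) {
    pulse$delta_d
  } else {
    0
  }
  dd <- c(0, 0, 0)
  dd[target_index(pulse)] <- dprime
  rho <- as.numeric(dens)[1:3]
  rv <- 1 - rho[1] - rho[2] - rho[3]
  prey_dens <- c(rho[3], rho[1], rho[2]) # pressure on a, b, c
  deriv <- rho * (re * rv - p * prey_dens - (d + dd))
  rho <- rho + dt * deriv
  rho[rho < epsilon | rho < 0] <- 0
  densities(rho[1], rho[2], rho[3])
}

#' Run the discrete-time stochastic rate equations
#'
#' Integrates the three coupled equations with explicit Euler steps from the
#' configured initial densities until at most one species remains above the
#' extinction threshold or `t_max` is reached, recording densities every
#' `record_stride` steps. Once a species crosses the threshold it is set to
#' exactly 0 and cannot return.
#'
#' @param config a [simulation_config()] with `engine = "sde"`.
#' @return An object of class `sde_run_result`: list with elements
#'   `trajectory` (data frame `t, rho_a, rho_b, rho_c, rho_v`), `outcome`
#'   ([classify_outcome()] of the final state), `final` (final densities),
#'   `t_end`, `resolved` (`TRUE` if a single-survivor/extinct state was
#'   reached before `t_max`), `seed` and `config` (flat echo).
#' @export
#' @examples
#' cfg <- simulation_config("sde", noise = noise_spec("none"), t_max = 50)
#' res <- run_sde(cfg)
#' res$outcome
run_sde <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$engine != "sde") stop("config engine must be 'sde'", call. = FALSE)
  if (!is_symmetric(config$rates)) {
    stop("the rate-equation engine implements symmetric rates only",
         call. = FALSE)
  }
  raw <- sde_run_cpp(as.numeric(config$init)[1:3],
                     config$rates$p_a, config$rates$r_a, config$rates$d_a,
                     config$pulse$delta_d, config$pulse$tau,
                     config$pulse$onset, target_index(config$pulse),
                     config$dt, config$t_max, config$epsilon,
                     noise_kind_code(config$noise), config$noise$scale,
                     as.double(config$seed), config$record_stride,
                     record = TRUE)
  traj <- data.frame(t = raw$t, rho_a = raw$rho_a, rho_b = raw$rho_b,
                     rho_c = raw$rho_c,
                     rho_v = 1 - raw$rho_a - raw$rho_b - raw$rho_c)
  ext <- setNames(raw$extinction_times, SPECIES)
  outcome <- classify_outcome(raw$rho, config$epsilon, ext)
  structure(list(trajectory = traj, outcome = outcome,
                 final = raw$rho, t_end = raw$t_end, resolved = raw$resolved,
                 seed = config$seed, config = config_echo(config)),
            class = "sde_run_result")
}

#' @export
print.sde_run_result <- function(x, ...) {
  cat(sprintf("<sde_run_result> %s at t = %g (%s), %d samples\n",
              as.character(x$outcome$label), x$t_end,
              if (x$resolved) "resolved" else "horizon reached",
              nrow(x$trajectory)))
  invisible(x)
}

#' Run an ensemble of stochastic rate-equation simulations
#'
#' Repeats [run_sde()] over `n_runs` independent seeds derived from
#' `base_seed` (via [derive_seed()]), without storing trajectories, and
#' tallies the classified outcome of each run.
#'
#' @param config a [simulation_config()] with `engine = "sde"`.
#' @param n_runs number of independent runs.
#' @param base_seed base seed; run `k` uses `derive_seed(base_seed, 0, 0, k)`.
#' @return A data frame with one row per run: `run`, `seed`, `label`,
#'   `t_end`, `resolved`, `rho_a`, `rho_b`, `rho_c`, and per-species
#'   extinction times `ext_a`, `ext_b`, `ext_c`.
#' @export
#' @examples
#' cfg <- simulation_config("sde", t_max = 200)
#' tab <- run_sde_ensemble(cfg, n_runs = 5, base_seed = 1)
#' table(tab$label)
run_sde_ensemble <- function(config, n_runs, base_seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"), n_runs >= 1)
  if (config$engine != "sde") stop("config engine must be 'sde'", call. = FALSE)
  seeds <- vapply(seq_len(n_runs) - 1L,
                  function(k) derive_seed(base_seed, 0, 0, k), numeric(1))
  raw <- sde_ensemble_cpp(as.numeric(config$init)[1:3],
                          config$rates$p_a, config$rates$r_a,
                          config$rates$d_a,
                          config$pulse$delta_d, config$pulse$tau,
                          config$pulse$onset, target_index(config$pulse),
                          config$dt, config$t_max, config$epsilon,
                          noise_kind_code(config$noise), config$noise$scale,
                          seeds)
  labels <- vapply(seq_len(n_runs), function(k) {
    as.character(classify_outcome(raw$rho[k, ], config$epsilon)$label)
  }, character(1))
  data.frame(run = seq_len(n_runs), seed = seeds,
             label = factor(labels, levels = OUTCOME_LABELS),
             t_end = raw$t_end, resolved = raw$resolved,
             rho_a = raw$rho[, 1], rho_b = raw$rho[, 2], rho_c = raw$rho[, 3],
             ext_a = raw$extinction_times[, 1],
             ext_b = raw$extinction_times[, 2],
             ext_c = raw$extinction_times[, 3])
}
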