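#' Initialise a random lattice
#'
#' Assigns each site of an `L x L` periodic lattice independently to species
#' A, B, C or vacancy with the given probabilities.
#'
#' @param L lattice side length (>= 2).
#' @param init a [densities()] giving the per-site occupation probabilities.
#' @param seed integer seed.
#' @return An object of class `lattice_state`: list with `grid` (integer
#'   matrix, 0 = vacant, 1 = A, 2 = B, 3 = C), `counts` (named tally
#'   `vacant, a, b, c`) and `t = 0`.
#' @export
#' @examples
#' st <- init_lattice(10, densities(0.3, 0.3, 0.3), seed = 1)
#' st$counts
init_lattice <- function(L, init, seed = 1) {
  stopifnot(L >= 2, L == round(L), inherits(init, "densities"))
  probs <- as.numeric(init)[c(4, 1, 2, 3)] # vacant, a, b, c
  # inverse-CDF assignment driven by the package generator, so lattice
  # initialisation shares the engines' seed discipline
  u <- unif_cpp(as.integer(L * L), as.double(seed))
  cum <- cumsum(probs)
  cells <- findInterval(u, cum)
  grid <- matrix(as.integer(cells), nrow = L, ncol = L)
  new_lattice_state(grid, t = 0)
}

new_lattice_state <- function(grid, t = 0) {
  counts <- tabulate(as.integer(grid) + 1L, nbins = 4L)
  structure(list(grid = grid,
                 counts = setNames(counts, c("vacant", "a", "b", "c")),
                 t = t),
            class = "lattice_state")
}

#' @export
print.lattice_state <- function(x, ...) {
  L <- nrow(x$grid)
  cat(sprintf("<lattice_state> %d x %d at t = %g: A = %d, B = %d, C = %d, vacant = %d\n",
              L, L, x$t, x$counts[["a"]], x$counts[["b"]], x$counts[["c"]],
              x$counts[["vacant"]]))
  invisible(x)
}

#' Densities of a lattice state
#'
#' @param state a `lattice_state`.
#' @return The [densities()] implied by the site counts.
#' @export
lattice_densities <- function(state) {
  stopifnot(inherits(state, "lattice_state"))
  n <- length(state$grid)
  densities(state$counts[["a"]] / n, state$counts[["b"]] / n,
            state$counts[["c"]] / n)
}

#' Elementary Monte-Carlo update(s)
#'
#' Performs `n_updates` elementary events on the lattice at fixed time `t`:
#' pick an occupied site uniformly at random; with the (pulse-adjusted)
#' death probability of its species the occupant dies; otherwise one of its
#' four von Neumann neighbours (periodic wrap) is chosen uniformly and the
#' occupant reproduces into a vacancy with probability `r`, or converts a
#' cyclic-prey neighbour to vacancy with probability `p` (the predator does
#' not move). Non-prey or same-species neighbours leave the lattice
#' unchanged.
#'
#' @param state a `lattice_state` with at least one occupied site.
#' @param rates a [rate_set()] with all entries <= 1.
#' @param pulse a [pulse_spec()]; the death probability of the target
#'   species is evaluated at `state$t` via [effective_death_rate()].
#' @param n_updates number of elementary events.
#' @param seed integer seed.
#' @return The updated `lattice_state` (time unchanged: a single event does
#'   not advance the sweep clock).
#' @export
#' @examples
#' st <- init_lattice(4, densities(0.3, 0.3, 0.3), seed = 2)
#' mc_elementary_update(st, rate_set_symmetric(0.2, 0.4, 0.1),
#'                      pulse_spec(0, 0), seed = 7)
mc_elementary_update <- function(state, rates, pulse = pulse_spec(0, 0),
                                 n_updates = 1, seed = 1) {
  stopifnot(inherits(state, "lattice_state"), inherits(rates, "rate_set"),
            inherits(pulse, "pulse_spec"))
  if (any(unlist(rates) > 1)) {
    stop("lattice rates act as probabilities and must be <= 1", call. = FALSE)
  }
  if (sum(state$counts[c("a", "b", "c")]) == 0) {
    stop("fully vacant lattice: no update possible", call. = FALSE)
  }
  d_eff <- c(rates$d_a, rates$d_b, rates$d_c)
  ti <- target_index(pulse)
  d_eff[ti] <- effective_death_rate(state$t, d_eff[ti], pulse)
  if (!(rates$p_a == rates$p_b && rates$p_b == rates$p_c &&
        rates$r_a == rates$r_b && rates$r_b == rates$r_c)) {
    stop("the lattice engine implements symmetric predation/reproduction",
         call. = FALSE)
  }
  grid <- lattice_update_cpp(state$grid, rates$p_a, rates$r_a, d_eff,
                             as.integer(n_updates), as.double(seed))
  new_lattice_state(grid, t = state$t)
}

#' Run the lattice Monte-Carlo engine
#'
#' Advances the lattice in sweeps of `N = L^2` elementary events per time
#' unit, with the death pulse applied to the target species on the closed
#' window `[onset, onset + tau]` of the sweep clock. Densities are recorded
#' once per time unit. The run stops early once at most one species remains
#' and its fate cannot change (a lone species whose reproduction rate
#' exceeds its death rate persists; otherwise the run continues to `t_max`
#' to distinguish total extinction).
#'
#' @param config a [simulation_config()] with `engine = "lattice"`. An
#'   optional `burn_in` number of pulse-free sweeps precedes `t = 0`.
#' @param early_stop stop once the outcome can no longer change (default);
#'   set `FALSE` to keep sweeping a single-species lattice to `t_max`, e.g.
#'   to study its stationary density.
#' @return An object of class `mc_run_result`: list with `trajectory`
#'   (data frame `t, rho_a, rho_b, rho_c, rho_v`), `outcome`, `final_state`
#'   (`lattice_state`), `t_end`, `stopped_early`, `seed`, `config`.
#' @export
#' @examples
#' cfg <- simulation_config("lattice", L = 30, t_max = 20, seed = 3)
#' run_lattice(cfg)$outcome
run_lattice <- function(config, early_stop = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$engine != "lattice") {
    stop("config engine must be 'lattice'", call. = FALSE)
  }
  if (!is_symmetric(config$rates)) {
    stop("the lattice engine implements symmetric rates only", call. = FALSE)
  }
  init_state <- init_lattice(config$L, config$init,
                             seed = derive_seed(config$seed, 1, 0, 0))
  raw <- lattice_run_cpp(init_state$grid,
                         config$rates$p_a, config$rates$r_a, config$rates$d_a,
                         config$pulse$delta_d, config$pulse$tau,
                         config$pulse$onset, target_index(config$pulse),
                         as.integer(config$t_max), config$burn_in,
                         as.double(derive_seed(config$seed, 2, 0, 0)),
                         isTRUE(early_stop))
  traj <- data.frame(t = raw$t, rho_a = raw$rho_a, rho_b = raw$rho_b,
                     rho_c = raw$rho_c, rho_v = raw$rho_v)
  n <- config$L^2
  # on the lattice extinction is an exact zero count: any occupied site counts
  ext <- setNames(raw$extinction_times, SPECIES)
  outcome <- classify_outcome(raw$counts[2:4] / n, epsilon = 0.5 / n,
                              extinction_times = ext)
  structure(list(trajectory = traj, outcome = outcome,
                 final_state = new_lattice_state(raw$grid, t = raw$t_end),
                 t_end = raw$t_end, stopped_early = raw$stopped_early,
                 seed = config$seed, config = config_echo(config)),
            class = "mc_run_result")
}

#' @export
print.mc_run_result <- function(x, ...) {
  cat(sprintf("<mc_run_result> %s at t = %g (%s)\n",
              as.character(x$outcome$label), x$t_end,
              if (x$stopped_early) "stopped early" else "horizon reached"))
  invisible(x)
}
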