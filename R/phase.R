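#' Define a (delta_d, tau) sweep grid
#'
#' @param delta_d strictly increasing pulse heights (>= 0).
#' @param tau strictly increasing pulse durations (>= 0).
#' @param n_runs independent runs per grid cell (>= 1).
#' @param base_config a [simulation_config()] supplying engine, rates,
#'   initial densities and numerical settings; its pulse height/duration are
#'   overridden cell by cell (onset and target are kept).
#' @return An object of class `sweep_grid`.
#' @export
#' @examples
#' sweep_grid(c(0, 0.1, 0.2), c(10, 30, 50), n_runs = 10,
#'            base_config = simulation_config("sde", t_max = 500))
sweep_grid <- function(delta_d, tau, n_runs, base_config) {
  stopifnot(inherits(base_config, "simulation_config"))
  if (length(delta_d) == 0 || any(delta_d < 0) ||
      any(diff(delta_d) <= 0) && length(delta_d) > 1) {
    stop("delta_d values must be non-empty, >= 0, strictly increasing",
         call. = FALSE)
  }
  if (length(tau) == 0 || any(tau < 0) ||
      (length(tau) > 1 && any(diff(tau) <= 0))) {
    stop("tau values must be non-empty, >= 0, strictly increasing",
         call. = FALSE)
  }
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  if (max(tau) + base_config$pulse$onset >= base_config$t_max) {
    stop("t_max of the base config must exceed onset + max(tau)",
         call. = FALSE)
  }
  structure(list(delta_d = delta_d, tau = tau, n_runs = as.integer(n_runs),
                 base_config = base_config),
            class = "sweep_grid")
}

cell_config <- function(grid, dd, tv, seed) {
  cfg <- grid$base_config
  simulation_config(engine = cfg$engine, rates = cfg$rates,
                    pulse = pulse_spec(dd, tv, cfg$pulse$onset,
                                       cfg$pulse$target),
                    L = cfg$L, init = cfg$init, dt = cfg$dt,
                    t_max = cfg$t_max, epsilon = cfg$epsilon,
                    noise = cfg$noise, seed = seed,
                    record_stride = cfg$record_stride, burn_in = cfg$burn_in)
}

#' Survival-probability map over the pulse plane
#'
#' For every cell of a [sweep_grid()] runs `n_runs` independent simulations
#' and tallies the classified outcomes into relative frequencies. Run `k` of
#' cell `(i, j)` uses seed `derive_seed(base_seed, i, j, k)`, so any cell can
#' be recomputed in isolation and the result is independent of execution
#' order.
#'
#' @param grid a [sweep_grid()].
#' @param base_seed base seed for the sweep.
#' @return An object of class `survival_map`: list with `cells` (long-format
#'   data frame `delta_d, tau, outcome, probability, n_runs`), `delta_d`,
#'   `tau`, `n_runs`, `engine`, `base_seed` and `config` (flat echo).
#' @export
#' @examples
#' cfg <- simulation_config("sde", t_max = 300)
#' sm <- survival_map(sweep_grid(c(0, 0.05), c(20, 50), 5, cfg),
#'                    base_seed = 1)
#' head(sm$cells)
survival_map <- function(grid, base_seed = 1) {
  stopifnot(inherits(grid, "sweep_grid"))
  engine <- grid$base_config$engine
  rows <- vector("list", length(grid$delta_d) * length(grid$tau))
  idx <- 0
  for (i in seq_along(grid$delta_d)) {
    for (j in seq_along(grid$tau)) {
      labels <- character(grid$n_runs)
      for (k in seq_len(grid$n_runs)) {
        seed <- derive_seed(base_seed, i, j, k)
        cfg <- cell_config(grid, grid$delta_d[i], grid$tau[j], seed)
        res <- if (engine == "lattice") run_lattice(cfg) else run_sde(cfg)
        labels[k] <- as.character(res$outcome$label)
      }
      tab <- table(factor(labels, levels = OUTCOME_LABELS))
      idx <- idx + 1
      rows[[idx]] <- data.frame(delta_d = grid$delta_d[i], tau = grid$tau[j],
                                outcome = OUTCOME_LABELS,
                                probability = as.numeric(tab) / grid$n_runs,
                                n_runs = grid$n_runs)
    }
  }
  structure(list(cells = do.call(rbind, rows), delta_d = grid$delta_d,
                 tau = grid$tau, n_runs = grid$n_runs, engine = engine,
                 base_seed = base_seed,
                 config = config_echo(grid$base_config)),
            class = "survival_map")
}

#' @export
print.survival_map <- function(x, ...) {
  cat(sprintf("<survival_map> %s engine, %d x %d cells, %d runs/cell\n",
              x$engine, length(x$delta_d), length(x$tau), x$n_runs))
  dom <- cell_probability(x, "only_B")
  cat(sprintf("  P(only_B) range: %.2f - %.2f\n", min(dom$probability),
              max(dom$probability)))
  invisible(x)
}

#' Extract one outcome's probabilities from a survival map
#'
#' @param map a [survival_map()].
#' @param outcome one of the five outcome labels.
#' @return Data frame `delta_d, tau, probability, n_runs`.
#' @export
cell_probability <- function(map, outcome) {
  stopifnot(inherits(map, "survival_map"), outcome %in% OUTCOME_LABELS)
  out <- map$cells[map$cells$outcome == outcome,
                   c("delta_d", "tau", "probability", "n_runs")]
  rownames(out) <- NULL
  out
}

# first delta_d at which prob crosses 0.5, linearly interpolated; NA if never
dd50 <- function(delta_d, prob) {
  above <- which(prob >= 0.5)
  if (length(above) == 0) return(NA_real_)
  i <- above[1]
  if (i == 1) return(delta_d[1])
  d0 <- delta_d[i - 1]; d1 <- delta_d[i]
  p0 <- prob[i - 1]; p1 <- prob[i]
  d0 + (0.5 - p0) / (p1 - p0) * (d1 - d0)
}

#' Compare the pulse scale of the two engines
#'
#' For each shared pulse duration, locates the pulse height at which the
#' probability of the B-only outcome first reaches 0.5 in each map (linear
#' interpolation between grid points) and reports the per-duration ratio
#' `dd50_mc / dd50_sde` and its median. Rows where either map never crosses
#' 0.5 are reported as `NA`. The function reports; it makes no pass/fail
#' judgement.
#'
#' @param map_mc [survival_map()] from the lattice engine.
#' @param map_sde [survival_map()] from the rate-equation engine; must share
#'   `map_mc`'s tau grid.
#' @return An object of class `engine_scaling`: list with `per_tau`
#'   (data frame `tau, dd50_mc, dd50_sde, ratio`) and `median_ratio`.
#' @export
compare_engines <- function(map_mc, map_sde) {
  stopifnot(inherits(map_mc, "survival_map"), inherits(map_sde, "survival_map"))
  if (!isTRUE(all.equal(map_mc$tau, map_sde$tau))) {
    stop("the two maps must share the tau grid", call. = FALSE)
  }
  pb_mc <- cell_probability(map_mc, "only_B")
  pb_sde <- cell_probability(map_sde, "only_B")
  per_tau <- do.call(rbind, lapply(map_mc$tau, function(tv) {
    mc <- pb_mc[pb_mc$tau == tv, ]
    sde <- pb_sde[pb_sde$tau == tv, ]
    mc50 <- dd50(mc$delta_d, mc$probability)
    sde50 <- dd50(sde$delta_d, sde$probability)
    ratio <- if (is.na(mc50) || is.na(sde50) || sde50 == 0) {
      NA_real_
    } else {
      mc50 / sde50
    }
    data.frame(tau = tv, dd50_mc = mc50, dd50_sde = sde50, ratio = ratio)
  }))
  structure(list(per_tau = per_tau,
                 median_ratio = median(per_tau$ratio, na.rm = TRUE)),
            class = "engine_scaling")
}

#' @export
print.engine_scaling <- function(x, ...) {
  cat("<engine_scaling> pulse-height scale between engines\n")
  print(x$per_tau, row.names = FALSE)
  cat(sprintf("  median dd50 ratio (MC / SDE): %.3g\n", x$median_ratio))
  invisible(x)
}
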