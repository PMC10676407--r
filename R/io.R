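#' Write a density trajectory as CSV
#'
#' Writes the header `t,rho_a,rho_b,rho_c,rho_v` and one row per sample at
#' full double precision (`%.17g`), so the byte output is deterministic for
#' a fixed trajectory and round-trips exactly.
#'
#' @param traj data frame with columns `t, rho_a, rho_b, rho_c, rho_v`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  cols <- c("t", "rho_a", "rho_b", "rho_c", "rho_v")
  stopifnot(is.data.frame(traj), all(cols %in% names(traj)))
  con <- tryCatch(file(path, "wb"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e),
         call. = FALSE)
  })
  on.exit(close(con))
  lines <- paste(cols, collapse = ",")
  if (nrow(traj) > 0) {
    body <- do.call(paste, c(lapply(cols, function(cc) {
      sprintf("%.17g", traj[[cc]])
    }), sep = ","))
    lines <- c(lines, body)
  }
  writeLines(lines, con)
  invisible(path)
}

#' Read a density trajectory written by [write_trajectory()]
#'
#' @param path CSV file path.
#' @return Data frame with columns `t, rho_a, rho_b, rho_c, rho_v`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  out <- read.csv(path)
  cols <- c("t", "rho_a", "rho_b", "rho_c", "rho_v")
  if (!all(cols %in% names(out))) {
    stop("not a trajectory file (expected columns ",
         paste(cols, collapse = ", "), ")", call. = FALSE)
  }
  out[cols]
}

CONFIG_KEYS <- c("engine", "L", "p", "r", "d", "delta_d", "tau", "onset",
                 "target", "dt", "t_max", "epsilon", "noise.kind",
                 "noise.scale", "seed", "n_runs", "record_stride", "burn_in")

#' Load a simulation configuration from file
#'
#' Reads a flat key-value configuration (JSON or YAML, by file extension),
#' validates it exhaustively, fills defaults and returns a
#' [simulation_config()]. Recognised keys: `engine, L, p, r, d, delta_d,
#' tau, onset, target, dt, t_max, epsilon, noise.kind, noise.scale, seed,
#' n_runs, record_stride, burn_in` (in YAML, `noise` may be a nested map).
#' Unknown keys are an error, with a suggestion for likely typos; all schema
#' violations are reported together.
#'
#' @param path configuration file path (`.json`, `.yaml` or `.yml`).
#' @return A [simulation_config()]; the requested ensemble size (key
#'   `n_runs`, default 1) is attached as attribute `n_runs`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format '.", ext, "' (use .json or .yaml)",
         call. = FALSE)
  }
  if (!is.list(raw)) stop("config must be a key-value mapping", call. = FALSE)
  # flatten a nested noise block into dotted keys
  if (!is.null(raw$noise) && is.list(raw$noise)) {
    for (k in names(raw$noise)) raw[[paste0("noise.", k)]] <- raw$noise[[k]]
    raw$noise <- NULL
  }
  problems <- character()
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  for (key in unknown) {
    dist <- adist(key, CONFIG_KEYS)
    hint <- if (min(dist) <= 3) {
      paste0(" (did you mean '", CONFIG_KEYS[which.min(dist)], "'?)")
    } else {
      ""
    }
    problems <- c(problems, paste0("unknown key '", key, "'", hint))
  }
  num_keys <- setdiff(CONFIG_KEYS, c("engine", "noise.kind", "target"))
  for (key in intersect(names(raw), num_keys)) {
    if (!is.numeric(raw[[key]]) || length(raw[[key]]) != 1 ||
        !is.finite(raw[[key]])) {
      problems <- c(problems, paste0("key '", key,
                                     "' must be a single finite number"))
    } else if (raw[[key]] < 0) {
      problems <- c(problems, paste0("key '", key, "' must be >= 0"))
    }
  }
  if (!is.null(raw$engine) &&
      !identical(raw$engine, "sde") && !identical(raw$engine, "lattice")) {
    problems <- c(problems, "key 'engine' must be 'sde' or 'lattice'")
  }
  if (!is.null(raw$noise.kind) &&
      !raw$noise.kind %in% c("none", "gaussian", "uniform", "lognormal")) {
    problems <- c(problems,
                  "key 'noise.kind' must be one of none, gaussian, uniform, lognormal")
  }
  if (length(problems)) {
    stop(paste0("invalid config '", path, "':\n  - ",
                paste(problems, collapse = "\n  - ")), call. = FALSE)
  }
  engine <- raw$engine %||% "sde"
  pick <- function(key, default) if (is.null(raw[[key]])) default else raw[[key]]
  noise <- noise_spec(pick("noise.kind", "gaussian"), pick("noise.scale", 0.05))
  cfg <- simulation_config(
    engine = engine,
    rates = rate_set_symmetric(pick("p", 0.2), pick("r", 0.4), pick("d", 0.1)),
    pulse = pulse_spec(pick("delta_d", 0), pick("tau", 0), pick("onset", 0),
                       pick("target", "A")),
    L = pick("L", 200), dt = pick("dt", 0.001), t_max = pick("t_max", 5000),
    epsilon = pick("epsilon", 1e-6), noise = noise, seed = pick("seed", 1),
    record_stride = pick("record_stride", 100),
    burn_in = pick("burn_in", 0))
  attr(cfg, "n_runs") <- as.integer(pick("n_runs", 1))
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run summary as JSON
#'
#' Serialises the classified outcome, extinction times, seed and the full
#' resolved configuration of a run result so the run can be reproduced
#' exactly.
#'
#' @param result an `sde_run_result` or `mc_run_result`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_outcome_json <- function(result, path) {
  stopifnot(inherits(result, c("sde_run_result", "mc_run_result")))
  payload <- list(outcome = as.character(result$outcome$label),
                  extinction_times = as.list(result$outcome$extinction_times),
                  t_end = result$t_end, seed = result$seed,
                  config = result$config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a survival map as JSON and long-format CSV
#'
#' @param map a [survival_map()].
#' @param path_json JSON output path (nested per-cell records plus config
#'   echo); skipped if `NULL`.
#' @param path_csv CSV output path (columns
#'   `delta_d,tau,outcome,probability,n_runs`); skipped if `NULL`.
#' @return Invisibly, the paths written.
#' @export
write_survival_map <- function(map, path_json = NULL, path_csv = NULL) {
  stopifnot(inherits(map, "survival_map"))
  if (!is.null(path_json)) {
    payload <- list(engine = map$engine, base_seed = map$base_seed,
                    delta_d = map$delta_d, tau = map$tau, n_runs = map$n_runs,
                    config = map$config, cells = map$cells)
    jsonlite::write_json(payload, path_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  if (!is.null(path_csv)) {
    utils::write.csv(map$cells, path_csv, row.names = FALSE, quote = FALSE)
  }
  invisible(c(json = path_json, csv = path_csv))
}
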