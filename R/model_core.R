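#' Per-species interaction rates
#'
#' Predation (`p_*`), reproduction (`r_*`) and death (`d_*`) rates for the
#' three cyclically interacting species. For the lattice engine these act as
#' per-attempt probabilities and must lie in \[0, 1\]; for the rate-equation
#' engine they are rates per unit time.
#'
#' @param p_a,p_b,p_c predation rates (A eats B, B eats C, C eats A).
#' @param r_a,r_b,r_c reproduction rates into vacant neighbouring sites.
#' @param d_a,d_b,d_c spontaneous death rates.
#' @return An object of class `rate_set`.
#' @seealso [rate_set_symmetric()] for the common equal-rates case.
#' @export
#' @examples
#' rate_set_symmetric(p = 0.2, r = 0.4, d = 0.1)
rate_set <- function(p_a, p_b, p_c, r_a, r_b, r_c, d_a, d_b, d_c) {
  x <- c(p_a = p_a, p_b = p_b, p_c = p_c,
         r_a = r_a, r_b = r_b, r_c = r_c,
         d_a = d_a, d_b = d_b, d_c = d_c)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("all rates must be finite and >= 0", call. = FALSE)
  }
  structure(as.list(x), class = "rate_set")
}

#' @rdname rate_set
#' @param p,r,d common predation, reproduction and death rate shared by all
#'   three species.
#' @export
rate_set_symmetric <- function(p, r, d) {
  rate_set(p, p, p, r, r, r, d, d, d)
}

is_symmetric <- function(rates) {
  with(rates, p_a == p_b && p_b == p_c && r_a == r_b && r_b == r_c &&
         d_a == d_b && d_b == d_c)
}

#' @export
print.rate_set <- function(x, ...) {
  cat("<rate_set>\n")
  cat(sprintf("  predation    p = (%g, %g, %g)\n", x$p_a, x$p_b, x$p_c))
  cat(sprintf("  reproduction r = (%g, %g, %g)\n", x$r_a, x$r_b, x$r_c))
  cat(sprintf("  death        d = (%g, %g, %g)\n", x$d_a, x$d_b, x$d_c))
  invisible(x)
}

#' Death-rate pulse specification
#'
#' A transient additive increase of one species' death rate: the rate becomes
#' `d + delta_d` on the closed interval `[onset, onset + tau]` and returns to
#' `d` outside it.
#'
#' @param delta_d pulse height, same units as the death rate (>= 0).
#' @param tau pulse duration in simulation time units (>= 0).
#' @param onset pulse start time (>= 0).
#' @param target species receiving the pulse, one of `"A"`, `"B"`, `"C"`.
#' @return An object of class `pulse_spec`.
#' @export
#' @examples
#' pulse_spec(delta_d = 0.2, tau = 15)
pulse_spec <- function(delta_d = 0, tau = 0, onset = 0, target = "A") {
  target <- match.arg(toupper(target), c("A", "B", "C"))
  if (!is.finite(delta_d) || delta_d < 0) stop("delta_d must be >= 0", call. = FALSE)
  if (!is.finite(tau) || tau < 0) stop("tau must be >= 0", call. = FALSE)
  if (!is.finite(onset) || onset < 0) stop("onset must be >= 0", call. = FALSE)
  structure(list(delta_d = delta_d, tau = tau, onset = onset, target = target),
            class = "pulse_spec")
}

#' @export
print.pulse_spec <- function(x, ...) {
  cat(sprintf("<pulse_spec> delta_d = %g on species %s for t in [%g, %g]\n",
              x$delta_d, x$target, x$onset, x$onset + x$tau))
  invisible(x)
}

target_index <- function(pulse) match(pulse$target, c("A", "B", "C"))

#' Species and vacancy densities
#'
#' Site fractions of the three species and of vacancies, obeying the
#' May-Leonard conservation rule `rho_a + rho_b + rho_c + rho_v = 1`.
#'
#' @param rho_a,rho_b,rho_c species site fractions in \[0, 1\].
#' @param rho_v vacancy fraction; computed as `1 - rho_a - rho_b - rho_c`
#'   when omitted.
#' @param tol tolerance on the conservation-rule check.
#' @return A named numeric vector of class `densities`.
#' @export
#' @examples
#' densities(0.3, 0.3, 0.3)
densities <- function(rho_a, rho_b, rho_c, rho_v = NULL, tol = 1e-8) {
  if (is.null(rho_v)) rho_v <- 1 - rho_a - rho_b - rho_c
  x <- c(rho_a = rho_a, rho_b = rho_b, rho_c = rho_c, rho_v = rho_v)
  if (any(!is.finite(x))) stop("densities must be finite", call. = FALSE)
  if (any(x < -tol) || any(x > 1 + tol)) {
    stop("densities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(x) - 1) > tol) {
    stop("densities must satisfy rho_a + rho_b + rho_c + rho_v = 1",
         call. = FALSE)
  }
  structure(pmin(pmax(x, 0), 1), class = "densities")
}

#' @export
print.densities <- function(x, ...) {
  cat(sprintf("<densities> a = %.6g, b = %.6g, c = %.6g, vacant = %.6g\n",
              x[["rho_a"]], x[["rho_b"]], x[["rho_c"]], x[["rho_v"]]))
  invisible(x)
}

#' Pulse-adjusted death rate
#'
#' Evaluates the time-dependent death rate of the pulsed species:
#' `base_d + delta_d` on the closed interval `[onset, onset + tau]`,
#' `base_d` elsewhere.
#'
#' @param t time(s), >= 0; vectorised.
#' @param base_d baseline death rate.
#' @param pulse a [pulse_spec()].
#' @return Numeric vector of death rates, one per element of `t`.
#' @export
#' @examples
#' effective_death_rate(c(5, 20), 0.1, pulse_spec(0.2, tau = 15))
effective_death_rate <- function(t, base_d, pulse) {
  stopifnot(inherits(pulse, "pulse_spec"))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be >= 0", call. = FALSE)
  base_d + pulse$delta_d * (t >= pulse$onset & t <= pulse$onset + pulse$tau)
}

#' Interior coexistence fixed point of the symmetric rate equations
#'
#' For equal rates the deterministic flow has a symmetric interior fixed
#' point at which every per-capita growth term `r*rho_v - p*rho_prey - d`
#' vanishes; solving `r(1 - 3*rho) - p*rho - d = 0` gives
#' `rho* = (r - d) / (3r + p)` for each species. When `d >= r` there is no
#' positive interior solution and all species densities are returned as zero.
#'
#' @param rates a symmetric [rate_set()].
#' @return A [densities()] object with equal species fractions.
#' @export
#' @examples
#' interior_fixed_point(rate_set_symmetric(0.2, 0.4, 0.1))
interior_fixed_point <- function(rates) {
  stopifnot(inherits(rates, "rate_set"))
  if (!is_symmetric(rates)) {
    stop("interior_fixed_point() requires symmetric rates", call. = FALSE)
  }
  p <- rates$p_a; r <- rates$r_a; d <- rates$d_a
  if (r <= 0 || 3 * r + p <= 0) {
    stop("requires r > 0 and 3r + p > 0", call. = FALSE)
  }
  rho <- if (d >= r) 0 else (r - d) / (3 * r + p)
  densities(rho, rho, rho)
}

#' Classify the long-time fate of a run
#'
#' A species with final density below `epsilon` counts as extinct. All three
#' alive is coexistence; exactly one alive is a single-survivor state; none
#' alive is total extinction. Exactly two alive at the horizon (a transient,
#' rare state: two-species compositions resolve dynamically) is counted as
#' coexistence, since diversity has not collapsed to a single species.
#'
#' @param final final [densities()] (or a numeric vector
#'   `(rho_a, rho_b, rho_c)` or `(rho_a, rho_b, rho_c, rho_v)`).
#' @param epsilon extinction threshold (> 0).
#' @param extinction_times optional named numeric vector of per-species
#'   extinction times (`NA` for surviving species), echoed in the result.
#' @return An object of class `outcome` with elements `label` (one of
#'   `"coexistence"`, `"only_A"`, `"only_B"`, `"only_C"`, `"all_extinct"`)
#'   and `extinction_times`.
#' @export
#' @examples
#' classify_outcome(densities(0.5, 0, 0, 0.5))
classify_outcome <- function(final, epsilon = 1e-6,
                             extinction_times = c(a = NA_real_, b = NA_real_,
                                                  c = NA_real_)) {
  if (!is.finite(epsilon) || epsilon <= 0) {
    stop("epsilon must be > 0", call. = FALSE)
  }
  rho <- as.numeric(final)[1:3]
  alive <- rho >= epsilon
  label <- if (sum(alive) >= 2) {
    "coexistence"
  } else if (sum(alive) == 1) {
    paste0("only_", c("A", "B", "C")[alive])
  } else {
    "all_extinct"
  }
  structure(list(label = factor(label, levels = OUTCOME_LABELS),
                 extinction_times = extinction_times),
            class = "outcome")
}

#' @export
print.outcome <- function(x, ...) {
  cat(sprintf("<outcome> %s\n", as.character(x$label)))
  et <- x$extinction_times
  gone <- !is.na(et)
  if (any(gone)) {
    cat("  extinctions:",
        paste(sprintf("%s at t = %g", toupper(names(et)[gone]), et[gone]),
              collapse = ", "), "\n")
  }
  invisible(x)
}
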