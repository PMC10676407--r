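#' Malthusian decay prediction for the pulsed species
#'
#' During the early part of the pulse, a run started at the interior fixed
#' point has all background growth terms cancelled, so the pulsed species
#' obeys `drho/dt = -delta_d * rho` and decays as
#' `rho(t) = rho0 * exp(-delta_d * t)`.
#'
#' @param rho0 density at pulse onset, in (0, 1].
#' @param delta_d pulse height (>= 0).
#' @param t time(s) since pulse onset (>= 0); vectorised.
#' @return Predicted density at each `t`.
#' @export
#' @examples
#' predicted_density(0.21, delta_d = 0.2, t = c(0, 10))
predicted_density <- function(rho0, delta_d, t) {
  stopifnot(rho0 > 0, rho0 <= 1, delta_d >= 0, all(t >= 0))
  rho0 * exp(-delta_d * t)
}

#' Fit an exponential decay rate to a density trajectory
#'
#' Ordinary least squares of `ln rho` against `t` inside the window; the
#' negated slope is the decay rate. No smoothing is applied, also for the
#' noisier per-time-unit lattice samples.
#'
#' @param trajectory data frame with a `t` column and density columns
#'   `rho_a`, `rho_b`, `rho_c` (as produced by the run functions).
#' @param window numeric `c(t_start, t_end)`, `t_end > t_start`.
#' @param species which species to fit: `"a"`, `"b"` or `"c"`.
#' @return An object of class `decay_fit`: list with `rate` (per-time decay
#'   constant), `intercept` (log density at `t = 0`), `window`, `residual`
#'   (root-mean-square of the log-density residuals) and `n_points`.
#' @export
#' @examples
#' tr <- data.frame(t = 0:5, rho_a = 0.21 * exp(-0.2 * (0:5)),
#'                  rho_b = 0.2, rho_c = 0.2)
#' fit_decay_rate(tr, window = c(0, 5))
fit_decay_rate <- function(trajectory, window, species = "a") {
  species <- match.arg(tolower(species), SPECIES)
  col <- paste0("rho_", species)
  stopifnot(is.data.frame(trajectory), all(c("t", col) %in% names(trajectory)),
            length(window) == 2, window[2] > window[1])
  sel <- trajectory$t >= window[1] & trajectory$t <= window[2]
  tt <- trajectory$t[sel]
  rho <- trajectory[[col]][sel]
  if (length(tt) < 3) {
    stop("need at least 3 samples inside the window", call. = FALSE)
  }
  if (any(rho <= 0)) {
    stop("species ", species, " has non-positive density inside the window; ",
         "the log-linear fit is undefined", call. = FALSE)
  }
  fit <- lm(log(rho) ~ tt)
  structure(list(rate = -unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 window = window,
                 residual = sqrt(mean(resid(fit)^2)),
                 n_points = length(tt)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> rate = %.6g over [%g, %g] (%d points)\n",
              x$rate, x$window[1], x$window[2], x$n_points))
  cat(sprintf("  exp(intercept) = %.6g, RMS log-residual = %.3g\n",
              exp(x$intercept), x$residual))
  invisible(x)
}
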