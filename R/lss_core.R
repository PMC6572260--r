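#' Gradient program
#'
#' Describes one reversed-phase separation as a single linear ramp of the
#' strong-solvent volume fraction from `phi0` to `phi0 + delta_phi` over
#' `t_gradient` minutes, preceded by the instrument dwell delay and followed
#' by a plateau at the final composition. All times are in minutes; solvent
#' fractions are dimensionless volume fractions in \[0, 1\].
#'
#' @param phi0 Strong-solvent fraction at the start of the gradient.
#' @param delta_phi Gradient span, so the ramp ends at `phi0 + delta_phi`.
#' @param t_gradient Ramp duration tG (min).
#' @param t_dead Column dead (hold-up) time t0 (min): transit time of an
#'   unretained compound.
#' @param t_dwell Dwell time tD (min): delay between the solvent mixer and
#'   the column head. See [dwell_time_from_volume()] to convert a dwell
#'   volume.
#' @return An object of class `gradient_program`.
#' @examples
#' g <- gradient_program(phi0 = 0.02, delta_phi = 0.98, t_gradient = 14,
#'                       t_dead = 0.8, t_dwell = 0.75)
#' @export
gradient_program <- function(phi0, delta_phi, t_gradient, t_dead, t_dwell) {
  stopifnot(is.numeric(phi0), is.numeric(delta_phi), is.numeric(t_gradient),
            is.numeric(t_dead), is.numeric(t_dwell))
  if (phi0 < 0) stop_lssrt("phi0 must be >= 0", "domain")
  if (delta_phi <= 0) stop_lssrt("delta_phi must be > 0", "domain")
  if (phi0 + delta_phi > 1 + 1e-12)
    stop_lssrt("phi0 + delta_phi must not exceed 1", "domain")
  if (t_gradient <= 0) stop_lssrt("t_gradient must be > 0", "domain")
  if (t_dead <= 0) stop_lssrt("t_dead must be > 0", "domain")
  if (t_dwell < 0) stop_lssrt("t_dwell must be >= 0", "domain")
  structure(list(phi0 = phi0, delta_phi = delta_phi, t_gradient = t_gradient,
                 t_dead = t_dead, t_dwell = t_dwell),
            class = "gradient_program")
}

#' @export
print.gradient_program <- function(x, ...) {
  cat(sprintf(
    "Gradient program: phi %.3f -> %.3f over %g min (t0 = %g min, tD = %g min)\n",
    x$phi0, x$phi0 + x$delta_phi, x$t_gradient, x$t_dead, x$t_dwell))
  invisible(x)
}

#' Per-compound LSS retention parameters
#'
#' The linear solvent strength (LSS) model describes the retention factor of
#' an analyte as k = kw * exp(-S * phi), where phi is the strong-solvent
#' volume fraction. `ln_kw` is the natural logarithm of kw, the retention
#' factor extrapolated to pure weak solvent, and `S` is the solvent-strength
#' slope. Both are stored in natural-log units: a library tabulated in
#' base-10 (log10 kw, S10) converts by multiplying both values by `log(10)`.
#'
#' @param ln_kw Natural log of the retention factor in pure weak solvent.
#' @param S Solvent-strength slope (per unit phi), natural-log units. Must
#'   be non-negative; `S = 0` gives the isocratic limit.
#' @param provenance Either `"experimental"` (measured from standards under
#'   two gradients) or `"qsrr"` (predicted in silico from molecular
#'   descriptors). Governs the retention-time tolerance used at annotation.
#' @return An object of class `lss_params`.
#' @examples
#' lss_params(ln_kw = 8, S = 25)
#' @export
lss_params <- function(ln_kw, S, provenance = c("experimental", "qsrr")) {
  stopifnot(is.numeric(ln_kw), length(ln_kw) == 1L,
            is.numeric(S), length(S) == 1L)
  if (S < 0) stop_lssrt("S must be non-negative", "domain")
  provenance <- match.arg(provenance)
  structure(list(ln_kw = ln_kw, S = S, provenance = provenance),
            class = "lss_params")
}

#' @export
print.lss_params <- function(x, ...) {
  cat(sprintf("LSS parameters: ln kw = %g, S = %g (%s)\n",
              x$ln_kw, x$S, x$provenance))
  invisible(x)
}

#' Retention factor at a fixed mobile-phase composition
#'
#' Evaluates the LSS law k = exp(ln_kw - S * phi).
#'
#' @param params An [lss_params()] object.
#' @param phi Strong-solvent volume fraction, in \[0, 1\]. Vectorised.
#' @return Retention factor(s), strictly positive and decreasing in `phi`.
#' @examples
#' retention_factor(lss_params(8, 25), phi = 0.02)
#' @export
retention_factor <- function(params, phi) {
  stopifnot(inherits(params, "lss_params"), is.numeric(phi))
  if (any(phi < 0 | phi > 1))
    stop_lssrt("phi must lie in [0, 1]", "domain")
  exp(params$ln_kw - params$S * phi)
}

#' Intrinsic gradient steepness
#'
#' b = delta_phi * S * t0 / tG, the compound-specific dimensionless
#' steepness of a gradient program. Large b means the composition sweeps
#' quickly past the analyte relative to its unretained transit time.
#'
#' @param params An [lss_params()] object.
#' @param gradient A [gradient_program()].
#' @return The steepness b (>= 0; zero only when S = 0).
#' @examples
#' g <- gradient_program(0.02, 0.98, 14, 0.8, 0.75)
#' gradient_steepness(lss_params(8, 25), g)  # 0.98 * 25 * 0.8 / 14 = 1.4
#' @export
gradient_steepness <- function(params, gradient) {
  stopifnot(inherits(params, "lss_params"), inherits(gradient, "gradient_program"))
  gradient$delta_phi * params$S * gradient$t_dead / gradient$t_gradient
}

# Initial retention factor at the starting composition, k0 = exp(ln_kw - S*phi0).
k0_initial <- function(params, gradient) {
  exp(params$ln_kw - params$S * gradient$phi0)
}

#' Predicted gradient retention time
#'
#' Closed-form LSS retention time under a single-ramp gradient with dwell
#' delay. Three elution regimes are distinguished:
#'
#' * Pre-gradient (isocratic) elution, when `t_dead * k0 <= t_dwell`: the
#'   analyte leaves the column before the gradient front reaches it, so
#'   tR = t0 * (1 + k0).
#' * Elution during the ramp: tR = t0 * \[1 + tD/t0 +
#'   (1/b) * log(1 + b * (k0 - tD/t0))\], with the analytic b -> 0 limit
#'   t0 * (1 + k0) used for vanishing steepness.
#' * Elution after the ramp has ended at the analyte position (the closed
#'   form would place elution beyond the final-composition plateau): the
#'   migration integral is evaluated numerically via [migrate_oracle()],
#'   which models the plateau explicitly.
#'
#' Here k0 = exp(ln_kw - S * phi0) is the retention factor at the starting
#' composition and b the [gradient_steepness()].
#'
#' @param params An [lss_params()] object.
#' @param gradient A [gradient_program()].
#' @return Predicted retention time in minutes (always >= `t_dead`).
#' @examples
#' g <- gradient_program(0.02, 0.98, 14, 0.8, 0.75)
#' retention_time(lss_params(8, 25), g)
#' @export
retention_time <- function(params, gradient) {
  stopifnot(inherits(params, "lss_params"), inherits(gradient, "gradient_program"))
  t0 <- gradient$t_dead
  tD <- gradient$t_dwell
  k0 <- k0_initial(params, gradient)
  b <- gradient_steepness(params, gradient)

  # Regime (a): elutes isocratically before the delayed gradient catches up.
  if (t0 * k0 <= tD) return(t0 * (1 + k0))

  if (b < 1e-12) {
    tr <- t0 * (1 + k0)
  } else {
    arg <- 1 + b * (k0 - tD / t0)
    if (arg <= 0)
      stop_lssrt(sprintf(
        "log argument 1 + b*(k0 - tD/t0) = %g is non-positive (b = %g, k0 = %g); inconsistent parameters",
        arg, b, k0), "numerical")
    tr <- t0 * (1 + tD / t0 + log(arg) / b)
  }

  # Regime (c): the closed form is only valid while elution happens on the
  # ramp; the mobile-phase composition at the outlet at time tr corresponds
  # to mixer time tr - tD - t0, which must not exceed tG.
  if (tr - tD - t0 > gradient$t_gradient + 1e-9)
    tr <- migrate_oracle(params, gradient)
  max(tr, t0)
}

# Strong-solvent fraction experienced at column position z (fraction of L)
# at time t: the mixer composition a dwell delay plus the transit time to z
# earlier, clamped to the ramp limits.
phi_at <- function(gradient, t, z) {
  s <- t - gradient$t_dwell - z * gradient$t_dead
  frac <- min(max(s / gradient$t_gradient, 0), 1)
  gradient$phi0 + gradient$delta_phi * frac
}

#' Numerical migration oracle for gradient retention
#'
#' Integrates the analyte migration equation dz/dt = u0 / (1 + k(phi(t, z)))
#' directly, with the delayed gradient composition phi(t, z) clamped to
#' \[phi0, phi0 + delta_phi\], using a fixed-step fourth-order Runge-Kutta
#' scheme. Serves as the independent reference for [retention_time()] and
#' handles elution on the final-composition plateau, which the closed form
#' does not model.
#'
#' @param params An [lss_params()] object.
#' @param gradient A [gradient_program()].
#' @param dt Integration step in minutes; must be small relative to
#'   `t_dead`.
#' @param t_max Maximum time horizon (min) before the integration aborts.
#' @return Retention time in minutes: the time at which the analyte position
#'   reaches the column outlet, located by linear interpolation within the
#'   final step.
#' @examples
#' g <- gradient_program(0.02, 0.98, 14, 0.8, 0.75)
#' migrate_oracle(lss_params(8, 25), g)
#' @export
migrate_oracle <- function(params, gradient, dt = 1e-3, t_max = 1e4) {
  stopifnot(inherits(params, "lss_params"), inherits(gradient, "gradient_program"))
  if (dt <= 0) stop_lssrt("dt must be > 0", "domain")
  t0g <- gradient$t_dead
  tDg <- gradient$t_dwell
  tG <- gradient$t_gradient
  phi0 <- gradient$phi0
  dphi <- gradient$delta_phi
  u0 <- 1 / t0g  # column-lengths per minute
  ln_kw <- params$ln_kw
  S <- params$S
  vel <- function(t, z) {
    frac <- (t - tDg - z * t0g) / tG
    if (frac < 0) frac <- 0 else if (frac > 1) frac <- 1
    u0 / (1 + exp(ln_kw - S * (phi0 + dphi * frac)))
  }
  t <- 0
  z <- 0
  while (t < t_max) {
    k1 <- vel(t, z)
    k2 <- vel(t + dt / 2, z + dt * k1 / 2)
    k3 <- vel(t + dt / 2, z + dt * k2 / 2)
    k4 <- vel(t + dt, z + dt * k3)
    z_new <- z + dt * (k1 + 2 * k2 + 2 * k3 + k4) / 6
    if (z_new >= 1) {
      # linear interpolation to the crossing inside the last step
      return(t + dt * (1 - z) / (z_new - z))
    }
    z <- z_new
    t <- t + dt
  }
  stop_lssrt(sprintf("analyte did not elute within t_max = %g min", t_max),
             "numerical")
}

#' Convert a dwell volume to a dwell time
#'
#' Instrument documentation usually reports the dwell volume (mL) between
#' the solvent mixer and the column head; the retention model consumes a
#' dwell time. tD = dwell volume / flow rate.
#'
#' @param volume_ml Dwell volume in mL.
#' @param flow_ml_min Flow rate in mL/min.
#' @return Dwell time in minutes.
#' @examples
#' dwell_time_from_volume(0.375, 0.5)
#' @export
dwell_time_from_volume <- function(volume_ml, flow_ml_min) {
  stopifnot(is.numeric(volume_ml), is.numeric(flow_ml_min))
  if (any(volume_ml < 0)) stop_lssrt("dwell volume must be >= 0", "domain")
  if (any(flow_ml_min <= 0)) stop_lssrt("flow rate must be > 0", "domain")
  volume_ml / flow_ml_min
}

# Classed error helper: class is one of "domain", "format", "numerical",
# "usage"; mapped to exit codes by the command-line wrapper.
stop_lssrt <- function(message, class) {
  stop(structure(class = c(paste0("lssrt_", class, "_error"), "error", "condition"),
                 list(message = message, call = sys.call(-1))))
}
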