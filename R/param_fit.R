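#' Recover LSS parameters from two retention times under two gradients
#'
#' The pair (ln kw, S) is identified by the two equations
#' t1 = tR(g1; ln kw, S) and t2 = tR(g2; ln kw, S). For a trial value of S
#' the first equation is inverted in closed form for the initial retention
#' factor, k0 = (exp(b1 * (t1/t0 - 1 - tD/t0)) - 1) / b1 + tD/t0, giving
#' ln kw = log(k0) + S * phi0; the residual t2 - tR(g2) is then a
#' one-dimensional function of S solved by bracketed root-finding. The two
#' gradients must differ enough in intrinsic steepness for the system to be
#' well conditioned; see [check_steepness_ratio()].
#'
#' @param g1,g2 [gradient_program()] objects describing the two runs. They
#'   must yield distinct steepness, i.e. differ in `delta_phi * t_dead /
#'   t_gradient` or in `phi0`.
#' @param t1,t2 Observed retention times (min) under `g1` and `g2`; each
#'   must exceed the corresponding dead time.
#' @param s_bracket Initial search interval for S; expanded geometrically
#'   (down to 1e-3 and up to 1e4) if no sign change is found inside it.
#' @param tol Solver tolerance (min) on the reproduction of the observed
#'   times by the fitted parameters.
#' @return An [lss_params()] object with `provenance = "experimental"`.
#' @examples
#' g1 <- gradient_program(0.02, 0.98, 7, 0.8, 0.75)
#' g2 <- gradient_program(0.02, 0.98, 21, 0.8, 0.75)
#' p <- lss_params(6.9, 20)
#' fit_lss(g1, retention_time(p, g1), g2, retention_time(p, g2))
#' @export
fit_lss <- function(g1, t1, g2, t2, s_bracket = c(1, 100), tol = 1e-8) {
  stopifnot(inherits(g1, "gradient_program"), inherits(g2, "gradient_program"),
            is.numeric(t1), is.numeric(t2))
  if (identical(unclass(g1), unclass(g2)))
    stop_lssrt("the two gradient programs are identical: system is underdetermined",
               "domain")
  if (t1 <= g1$t_dead || t2 <= g2$t_dead)
    stop_lssrt("observed retention times must exceed the dead time", "domain")

  residual <- function(S) {
    p <- params_from_t1(S, g1, t1)
    if (is.null(p)) return(NA_real_)
    t2 - retention_time(p, g2)
  }

  bracket <- find_bracket(residual, s_bracket)
  if (is.null(bracket))
    stop_lssrt("no S bracket with a sign change was found; observations may be inconsistent with the LSS model",
               "numerical")
  root <- stats::uniroot(residual, interval = bracket, tol = 1e-12)
  fit <- params_from_t1(root$root, g1, t1)
  fit$provenance <- "experimental"

  err1 <- abs(retention_time(fit, g1) - t1)
  err2 <- abs(retention_time(fit, g2) - t2)
  if (max(err1, err2) > max(tol, 1e3 * .Machine$double.eps * max(t1, t2)))
    stop_lssrt(sprintf("fitted parameters reproduce the observations only to %.2e min (tolerance %.0e)",
                       max(err1, err2), tol), "numerical")
  fit
}

# Closed-form inversion of the ramp-regime retention formula for the first
# gradient: given S and t1, recover k0 and hence ln_kw. Returns NULL when
# the trial S puts k0 outside its physical range.
params_from_t1 <- function(S, g1, t1) {
  t0 <- g1$t_dead
  tD <- g1$t_dwell
  b1 <- g1$delta_phi * S * t0 / g1$t_gradient
  k0 <- if (b1 < 1e-12) {
    t1 / t0 - 1
  } else {
    expm1(b1 * (t1 / t0 - 1 - tD / t0)) / b1 + tD / t0
  }
  if (!is.finite(k0) || k0 <= 0) return(NULL)
  lss_params(ln_kw = log(k0) + S * g1$phi0, S = S, provenance = "experimental")
}

# Scan a geometric grid for a sign change of f, expanding beyond the
# initial interval if necessary.
find_bracket <- function(f, interval, lower_limit = 1e-3, upper_limit = 1e4) {
  lo <- max(interval[1], lower_limit)
  hi <- min(interval[2], upper_limit)
  repeat {
    s_grid <- exp(seq(log(lo), log(hi), length.out = 60))
    vals <- vapply(s_grid, f, numeric(1))
    ok <- which(is.finite(vals))
    if (length(ok) >= 2) {
      sg <- sign(vals[ok])
      flip <- which(sg[-1] * sg[-length(sg)] <= 0)
      if (length(flip) > 0) {
        i <- ok[flip[1]]
        j <- ok[flip[1] + 1]
        return(c(s_grid[i], s_grid[j]))
      }
    }
    if (lo <= lower_limit && hi >= upper_limit) return(NULL)
    lo <- max(lo / 10, lower_limit)
    hi <- min(hi * 10, upper_limit)
  }
}

#' Check the intrinsic steepness ratio of a gradient pair
#'
#' For reliable two-gradient parameter estimation the two runs should
#' differ in intrinsic steepness by a factor of 3 or more. The ratio
#' max(b1, b2) / min(b1, b2) is evaluated at a reference slope `S_ref`
#' (it does not depend on S when only the gradient geometry differs).
#'
#' @param g1,g2 [gradient_program()] objects.
#' @param S_ref Reference solvent-strength slope at which to evaluate the
#'   steepness.
#' @return A list with elements `ratio` (>= 1) and `warn` (TRUE when the
#'   ratio is below 3, i.e. the pair is poorly conditioned for fitting).
#' @examples
#' g1 <- gradient_program(0.02, 0.98, 7, 0.8, 0.75)
#' g2 <- gradient_program(0.02, 0.98, 21, 0.8, 0.75)
#' check_steepness_ratio(g1, g2)
#' @export
check_steepness_ratio <- function(g1, g2, S_ref = 25) {
  stopifnot(inherits(g1, "gradient_program"), inherits(g2, "gradient_program"))
  p <- lss_params(0, S_ref)
  b1 <- gradient_steepness(p, g1)
  b2 <- gradient_steepness(p, g2)
  ratio <- max(b1, b2) / min(b1, b2)
  list(ratio = ratio, warn = ratio < 3)
}
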