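#' Fit a global affine retention-time calibration
#'
#' Small inaccuracies in the instrumental parameters (dead time, dwell
#' time, steepness) shift all predicted retention times by a common affine
#' map to first order: tR_pred = alpha * tR_obs + beta, with alpha and beta
#' independent of the compound. This fits (alpha, beta) by ordinary least
#' squares of the predictions on the observations for a set of calibrant
#' compounds of known identity, so that the systematic instrument error can
#' later be removed from every prediction with [apply_calibration()].
#'
#' Only compounds whose LSS parameters were measured experimentally should
#' serve as calibrants; calibrating with in-silico (QSRR) predictions
#' propagates their error into the whole library.
#'
#' @param pred Numeric vector of predicted retention times (min).
#' @param obs Numeric vector of observed retention times (min) for the same
#'   compounds, same length, at least 2, not all identical.
#' @return An object of class `rt_calibration`: list with `alpha` (slope),
#'   `beta` (intercept, min), `n_calibrants`, and `residuals`
#'   (pred - alpha*obs - beta, min). A non-positive fitted slope triggers a
#'   warning, as it has no physical interpretation.
#' @examples
#' fit_affine(pred = c(2.1, 5.2, 9.3), obs = c(2.0, 5.0, 9.0))
#' @export
fit_affine <- function(pred, obs) {
  stopifnot(is.numeric(pred), is.numeric(obs))
  if (length(pred) != length(obs))
    stop_lssrt("pred and obs must have equal length", "domain")
  if (length(obs) < 2)
    stop_lssrt("at least 2 calibrants are required", "domain")
  if (stats::var(obs) == 0)
    stop_lssrt("observed calibrant times are all identical: affine fit is degenerate",
               "domain")
  fit <- stats::lm.fit(cbind(intercept = 1, slope = obs), pred)
  alpha <- unname(fit$coefficients["slope"])
  beta <- unname(fit$coefficients["intercept"])
  if (alpha <= 0)
    warning("fitted calibration slope is not positive; check the calibrant assignments")
  structure(list(alpha = alpha, beta = beta,
                 n_calibrants = length(obs),
                 residuals = unname(fit$residuals)),
            class = "rt_calibration")
}

#' @export
print.rt_calibration <- function(x, ...) {
  cat(sprintf("Retention-time calibration: pred = %.5f * obs + %.5f min (n = %d, RMS residual %.4f min)\n",
              x$alpha, x$beta, x$n_calibrants, sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Apply an affine calibration to predicted retention times
#'
#' Inverts the fitted map: the calibrated prediction is
#' (t_pred - beta) / alpha, i.e. the observation the instrument would be
#' expected to produce for that prediction.
#'
#' @param t_pred Predicted retention time(s) in minutes. Vectorised.
#' @param fit An [fit_affine()] result (or `NULL`, in which case `t_pred`
#'   is returned unchanged).
#' @return Calibrated retention time(s) in minutes.
#' @examples
#' cal <- fit_affine(c(2.1, 5.2, 9.3), c(2.0, 5.0, 9.0))
#' apply_calibration(6.0, cal)
#' @export
apply_calibration <- function(t_pred, fit) {
  if (is.null(fit)) return(t_pred)
  stopifnot(inherits(fit, "rt_calibration"), is.numeric(t_pred))
  if (fit$alpha == 0) stop_lssrt("calibration slope is zero", "numerical")
  (t_pred - fit$beta) / fit$alpha
}

#' Relative perturbation of the instrumental parameters
#'
#' Describes a small multiplicative error on the dead time, dwell time and
#' intrinsic steepness of a gradient program, as used to emulate the
#' mismatch between nominal and effective instrument geometry. Magnitudes
#' above 0.2 are rejected: the affine-calibration theory is a first-order
#' linearisation and is only exercised in the small-perturbation regime.
#'
#' @param rel_dt0 Relative change of the dead time t0.
#' @param rel_dtD Relative change of the dwell time tD.
#' @param rel_db Relative change of the intrinsic steepness b, realised by
#'   scaling the ramp duration tG by 1/(1 + rel_db) since b is proportional
#'   to 1/tG.
#' @return An object of class `perturbation_spec`.
#' @seealso [perturb_gradient()]
#' @examples
#' perturbation_spec(0.03, 0.03, 0.03)
#' @export
perturbation_spec <- function(rel_dt0 = 0, rel_dtD = 0, rel_db = 0) {
  vals <- c(rel_dt0 = rel_dt0, rel_dtD = rel_dtD, rel_db = rel_db)
  stopifnot(is.numeric(vals))
  if (any(abs(vals) > 0.2))
    stop_lssrt("perturbations must satisfy |rel| <= 0.2 (first-order regime)",
               "domain")
  structure(as.list(vals), class = "perturbation_spec")
}
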