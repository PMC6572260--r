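# Monoisotopic masses (Da) used to build the default adduct registry.
PROTON_MASS <- 1.007276467     # CODATA proton (H+ ion)
H2O_MASS <- 18.010564684       # monoisotopic H2O
NA_MASS <- 22.989769282        # monoisotopic Na atom
ELECTRON_MASS <- 0.000548580   # CODATA electron

#' Default positive-mode adduct registry
#'
#' The five adducts routinely used for steroid ESI+ peak picking:
#' \[M+H\]+, \[M-H2O+H\]+, \[M-2H2O+H\]+, \[M-3H2O+H\]+ and \[M+Na\]+.
#' The `mass_shift` convention is chosen so that the neutral monoisotopic
#' mass is recovered as `charge * mz + mass_shift`; for example
#' -1.007276 Da for \[M+H\]+ and +17.003288 Da for \[M-H2O+H\]+.
#'
#' @return A data.frame with columns `name`, `mass_shift` (Da) and
#'   `charge`.
#' @examples
#' default_adducts()
#' @export
default_adducts <- function() {
  data.frame(
    name = c("[M+H]+", "[M-H2O+H]+", "[M-2H2O+H]+", "[M-3H2O+H]+", "[M+Na]+"),
    mass_shift = c(-PROTON_MASS,
                   H2O_MASS - PROTON_MASS,
                   2 * H2O_MASS - PROTON_MASS,
                   3 * H2O_MASS - PROTON_MASS,
                   -(NA_MASS - ELECTRON_MASS)),
    charge = c(1L, 1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Annotation tolerance configuration
#'
#' Mass matching uses a relative (ppm) tolerance; retention-time matching
#' uses one of two relative tolerances depending on the provenance of the
#' LSS parameters behind the prediction: a tight one for experimentally
#' measured parameters and a loose one for in-silico (QSRR) parameters,
#' whose predictions carry substantially larger errors.
#'
#' @param mass_ppm Relative mass tolerance in ppm (default 5).
#' @param rt_experimental Relative retention-time tolerance for
#'   experimentally parameterised compounds (default 0.005, i.e. 0.5\%).
#' @param rt_qsrr Relative retention-time tolerance for QSRR-parameterised
#'   compounds (default 0.05, i.e. 5\%). Expected to be at least as large
#'   as `rt_experimental`; a warning is raised otherwise.
#' @return An object of class `tolerance_config` with fields `tol_mass`
#'   (dimensionless), `tol_rt_experimental` and `tol_rt_qsrr`.
#' @examples
#' tolerance_config(mass_ppm = 5, rt_experimental = 0.005, rt_qsrr = 0.05)
#' @export
tolerance_config <- function(mass_ppm = 5, rt_experimental = 0.005,
                             rt_qsrr = 0.05) {
  stopifnot(is.numeric(mass_ppm), is.numeric(rt_experimental),
            is.numeric(rt_qsrr))
  if (mass_ppm <= 0 || rt_experimental <= 0 || rt_qsrr <= 0)
    stop_lssrt("all tolerances must be strictly positive", "domain")
  if (rt_experimental > rt_qsrr)
    warning("rt_experimental tolerance exceeds rt_qsrr; the provenance levels are usually ordered the other way")
  structure(list(tol_mass = mass_ppm * 1e-6,
                 tol_rt_experimental = rt_experimental,
                 tol_rt_qsrr = rt_qsrr),
            class = "tolerance_config")
}

#' Predict retention times for every compound in a library
#'
#' @param library A compound library as returned by [read_library()] or
#'   [gen_library()].
#' @param gradient A [gradient_program()].
#' @param calibration Optional [fit_affine()] result applied to the raw
#'   predictions.
#' @return A data.frame with columns `compound_id` and `predicted_rt` (min),
#'   one row per library compound in library order.
#' @export
predict_library_rt <- function(library, gradient, calibration = NULL) {
  library <- as_compound_library(library)
  n <- nrow(library)
  rt <- numeric(n)
  for (i in seq_len(n)) {
    p <- lss_params(library$ln_kw[i], library$S[i], library$provenance[i])
    rt[i] <- retention_time(p, gradient)
  }
  data.frame(compound_id = library$compound_id,
             predicted_rt = apply_calibration(rt, calibration),
             stringsAsFactors = FALSE)
}

#' Annotate LC-MS features by exact mass and predicted retention time
#'
#' For every combination of feature, adduct and library compound, a match
#' is reported when both
#' `|charge * mz + mass_shift - mass| / mass < tol_mass` and
#' `|rt_obs - rt_pred| / rt_pred < tol_rt`, where `rt_pred` is the
#' (optionally calibrated) LSS prediction for the compound and `tol_rt` is
#' the tolerance level matching the compound's parameter provenance. Both
#' inequalities are strict; boundary hits are excluded. Matches within a
#' feature are sorted by the combined normalised error
#' `sqrt(rel_mass_error^2 + rel_rt_error^2)`, ties broken by compound id.
#'
#' Annotation levels follow the provenance of the LSS parameters: `"2+"`
#' when they were experimentally measured, `"2"` when QSRR-predicted.
#'
#' @param features A data.frame with columns `mz` (Th) and `rt` (min),
#'   optionally `known_identity`; see [read_features()].
#' @param library A compound library; see [read_library()].
#' @param gradient A [gradient_program()].
#' @param tolerances A [tolerance_config()].
#' @param adducts An adduct registry data.frame; see [default_adducts()].
#' @param calibration Optional [fit_affine()] result.
#' @return An object of class `feature_annotation`: a list with `features`
#'   (the input, with a `feature` index column), `matches` (a data.frame
#'   with one row per (feature, compound, adduct) match: `feature`,
#'   `compound_id`, `name`, `adduct`, `level`, `predicted_rt`,
#'   `rel_mass_error`, `rel_rt_error`), and the `tolerances` used.
#'   Features with no match simply have no rows in `matches`.
#' @examples
#' g <- gradient_program(0.02, 0.98, 14, 0.8, 0.75)
#' scen <- synthetic_scenario(seed = 1, n_compounds = 10)
#' lib <- gen_library(scen)
#' feats <- gen_features(lib, scen)
#' ann <- annotate_features(feats, lib, g)
#' @export
annotate_features <- function(features, library, gradient,
                              tolerances = tolerance_config(),
                              adducts = default_adducts(),
                              calibration = NULL) {
  library <- as_compound_library(library)
  stopifnot(is.data.frame(features), inherits(tolerances, "tolerance_config"),
            is.data.frame(adducts))
  if (nrow(library) == 0)
    stop_lssrt("compound library is empty", "domain")
  if (nrow(adducts) == 0)
    stop_lssrt("adduct registry is empty", "domain")
  check_feature_frame(features)

  pred <- predict_library_rt(library, gradient, calibration)$predicted_rt
  tol_rt <- ifelse(library$provenance == "experimental",
                   tolerances$tol_rt_experimental, tolerances$tol_rt_qsrr)
  level <- ifelse(library$provenance == "experimental", "2+", "2")

  out <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    mz <- features$mz[i]
    rt <- features$rt[i]
    rel_rt <- (rt - pred) / pred
    rt_ok <- abs(rel_rt) < tol_rt
    rows <- list()
    for (j in seq_len(nrow(adducts))) {
      neutral <- adducts$charge[j] * mz + adducts$mass_shift[j]
      rel_m <- (neutral - library$monoisotopic_mass) / library$monoisotopic_mass
      hit <- which(abs(rel_m) < tolerances$tol_mass & rt_ok)
      if (length(hit) > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          feature = i,
          compound_id = library$compound_id[hit],
          name = library$name[hit],
          adduct = adducts$name[j],
          level = level[hit],
          predicted_rt = pred[hit],
          rel_mass_error = rel_m[hit],
          rel_rt_error = rel_rt[hit],
          stringsAsFactors = FALSE)
    }
    if (length(rows) > 0) {
      m <- do.call(rbind, rows)
      score <- sqrt(m$rel_mass_error^2 + m$rel_rt_error^2)
      m <- m[order(score, m$compound_id), , drop = FALSE]
      out[[i]] <- m
    }
  }
  matches <- do.call(rbind, c(out, list(empty_match_frame())))
  rownames(matches) <- NULL
  feats <- features
  feats$feature <- seq_len(nrow(features))
  structure(list(features = feats, matches = matches, tolerances = tolerances),
            class = "feature_annotation")
}

empty_match_frame <- function() {
  data.frame(feature = integer(0), compound_id = character(0),
             name = character(0), adduct = character(0), level = character(0),
             predicted_rt = numeric(0), rel_mass_error = numeric(0),
             rel_rt_error = numeric(0), stringsAsFactors = FALSE)
}

check_feature_frame <- function(features) {
  if (!all(c("mz", "rt") %in% names(features)))
    stop_lssrt("feature table must have columns mz and rt", "format")
  if (nrow(features) > 0 && (!is.numeric(features$mz) || !is.numeric(features$rt)))
    stop_lssrt("mz and rt must be numeric", "format")
  if (nrow(features) > 0 && any(features$mz <= 0))
    stop_lssrt("mz must be positive", "domain")
  invisible(features)
}

#' @export
print.feature_annotation <- function(x, ...) {
  n_ann <- length(unique(x$matches$feature))
  cat(sprintf("Feature annotation: %d features, %d annotated, %d matches\n",
              nrow(x$features), n_ann, nrow(x$matches)))
  invisible(x)
}

#' Annotation success rate
#'
#' The fraction of standards that were annotated with their actual
#' identity: features carrying a known identity whose match list contains
#' that identity, divided by the number of distinct known identities
#' present in the library.
#'
#' @param annotation A [annotate_features()] result whose features carry a
#'   `known_identity` column.
#' @param library The compound library used for the annotation (defines the
#'   denominator: standards absent from the library cannot be recovered and
#'   are not counted).
#' @return A fraction in \[0, 1\].
#' @export
success_rate <- function(annotation, library) {
  stopifnot(inherits(annotation, "feature_annotation"))
  library <- as_compound_library(library)
  feats <- annotation$features
  if (is.null(feats$known_identity))
    stop_lssrt("features carry no known_identity column", "domain")
  truth <- feats[!is.na(feats$known_identity), , drop = FALSE]
  denom <- length(intersect(unique(truth$known_identity), library$compound_id))
  if (denom == 0)
    stop_lssrt("no known identities are present in the library: success rate undefined",
               "domain")
  m <- annotation$matches
  correct <- vapply(seq_len(nrow(truth)), function(i) {
    any(m$feature == truth$feature[i] & m$compound_id == truth$known_identity[i])
  }, logical(1))
  # a standard counts once even if several of its adduct features were matched
  n_found <- length(unique(truth$known_identity[correct]))
  n_found / denom
}

#' Annotation misattribution rate
#'
#' The fraction of returned annotations whose proposed identity differs
#' from the true identity of the feature, among features of known identity.
#'
#' @param annotation A [annotate_features()] result whose features carry a
#'   `known_identity` column.
#' @return A fraction in \[0, 1\].
#' @export
misattribution_rate <- function(annotation) {
  stopifnot(inherits(annotation, "feature_annotation"))
  feats <- annotation$features
  if (is.null(feats$known_identity))
    stop_lssrt("features carry no known_identity column", "domain")
  truth <- feats$known_identity[annotation$matches$feature]
  counted <- !is.na(truth)
  if (sum(counted) == 0)
    stop_lssrt("no annotations over features of known identity: misattribution rate undefined",
               "domain")
  mean(annotation$matches$compound_id[counted] != truth[counted])
}

#' Sweep annotation rates over a retention-time tolerance grid
#'
#' Re-annotates the same features at a series of retention-time tolerances
#' (applied to both provenance levels; the mass tolerance is held fixed)
#' and reports the success and misattribution rates at each, in the manner
#' of a receiver-operating-characteristic sweep. The success rate is
#' necessarily non-decreasing in the tolerance; the misattribution rate
#' need not be monotone.
#'
#' @param features,library,gradient,adducts,calibration As in
#'   [annotate_features()].
#' @param tol_grid Strictly increasing vector of relative retention-time
#'   tolerances (e.g. `c(0.005, 0.01, 0.05, 0.10, 0.15)`).
#' @param mass_ppm Fixed mass tolerance in ppm.
#' @return A data.frame with one row per grid point: `tol_rt`, `n_matches`,
#'   `n_annotated_features`, `success_rate`, `misattribution_rate` (NA when
#'   undefined at that tolerance).
#' @export
tolerance_sweep <- function(features, library, gradient, tol_grid,
                            adducts = default_adducts(), mass_ppm = 5,
                            calibration = NULL) {
  if (length(tol_grid) == 0 || any(diff(tol_grid) <= 0))
    stop_lssrt("tol_grid must be non-empty and strictly increasing", "domain")
  library <- as_compound_library(library)
  rows <- lapply(tol_grid, function(tol) {
    ann <- annotate_features(features, library, gradient,
                             tolerance_config(mass_ppm, tol, tol),
                             adducts, calibration)
    mis <- tryCatch(misattribution_rate(ann), error = function(e) NA_real_)
    suc <- tryCatch(success_rate(ann, library), error = function(e) NA_real_)
    data.frame(tol_rt = tol, n_matches = nrow(ann$matches),
               n_annotated_features = length(unique(ann$matches$feature)),
               success_rate = suc, misattribution_rate = mis)
  })
  out <- do.call(rbind, rows)
  suc <- out$success_rate[!is.na(out$success_rate)]
  stopifnot(!is.unsorted(suc))  # success is monotone in tolerance by construction
  out
}

#' Annotation multiplicity statistics
#'
#' Summarises the number of annotations per annotated feature (features
#' with no annotation are excluded). Percentiles are interpolated from a
#' gamma distribution fitted to the per-feature counts by maximum
#' likelihood with method-of-moments initialisation; the gamma family
#' covers most non-negative count-like distributions while remaining
#' analytically tractable. When all counts are equal, that value is
#' returned for the mean and every percentile.
#'
#' @param annotation A [annotate_features()] result, or a numeric vector of
#'   positive per-feature annotation counts.
#' @param probs Percentile levels to interpolate (default 50/75/90\%).
#' @return A list with `n_annotated`, `mean`, `shape`, `rate` (NA in the
#'   degenerate all-equal case) and `percentiles` (named vector).
#' @export
multiplicity_stats <- function(annotation, probs = c(0.50, 0.75, 0.90)) {
  counts <- if (inherits(annotation, "feature_annotation")) {
    as.numeric(table(annotation$matches$feature))
  } else {
    as.numeric(annotation)
  }
  if (length(counts) == 0)
    stop_lssrt("no annotated features: multiplicity undefined", "domain")
  if (any(counts <= 0))
    stop_lssrt("annotation counts must be positive", "domain")
  pct_names <- paste0("p", round(100 * probs))
  if (stats::var(counts) == 0) {
    pct <- stats::setNames(rep(counts[1], length(probs)), pct_names)
    return(list(n_annotated = length(counts), mean = counts[1],
                shape = NA_real_, rate = NA_real_, percentiles = pct))
  }
  # method-of-moments start for the gamma MLE
  m <- mean(counts)
  v <- stats::var(counts)
  start <- list(shape = m^2 / v, rate = m / v)
  fit <- suppressWarnings(
    MASS::fitdistr(counts, "gamma", start = start, lower = c(1e-8, 1e-8)))
  shape <- unname(fit$estimate["shape"])
  rate <- unname(fit$estimate["rate"])
  pct <- stats::setNames(stats::qgamma(probs, shape = shape, rate = rate),
                         pct_names)
  list(n_annotated = length(counts), mean = m, shape = shape, rate = rate,
       percentiles = pct)
}
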