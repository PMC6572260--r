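# Shared fixtures and independent reference implementations used across the
# suite. The references here are deliberately naive (vectorised closed forms,
# exhaustive loops) and never call the code paths they are used to check.

`%||%` <- function(x, y) if (is.null(x)) y else x

std_gradient <- function() {
  gradient_program(phi0 = 0.02, delta_phi = 0.98, t_gradient = 14,
                   t_dead = 0.8, t_dwell = 0.75)
}

# Vectorised closed-form retention time over parameter vectors (pre-gradient
# and ramp regimes only; callers must stay off the final plateau). Written
# directly from the gradient-elution integral, independently of
# retention_time()'s scalar branching.
tr_closed_vec <- function(ln_kw, S, g) {
  k0 <- exp(ln_kw - S * g$phi0)
  b <- g$delta_phi * S * g$t_dead / g$t_gradient
  iso <- g$t_dead * (1 + k0)
  ramp <- g$t_dead * (1 + g$t_dwell / g$t_dead +
                        log1p(b * (k0 - g$t_dwell / g$t_dead)) / b)
  ifelse(g$t_dead * k0 <= g$t_dwell | b < 1e-12, iso, ramp)
}

# Exhaustive triple-loop annotation reference: every (feature, adduct,
# compound) combination is tested against the two strict-inequality
# criteria. Returns an unsorted data.frame of (feature, compound_id, adduct).
brute_annotate <- function(features, library, gradient, tolerances,
                           adducts, calibration = NULL) {
  pred <- numeric(nrow(library))
  for (k in seq_len(nrow(library))) {
    p <- lss_params(library$ln_kw[k], library$S[k], library$provenance[k])
    pred[k] <- retention_time(p, gradient)
  }
  pred <- apply_calibration(pred, calibration)
  rows <- list()
  for (i in seq_len(nrow(features))) {
    for (j in seq_len(nrow(adducts))) {
      for (k in seq_len(nrow(library))) {
        neutral <- adducts$charge[j] * features$mz[i] + adducts$mass_shift[j]
        mass <- library$monoisotopic_mass[k]
        tol_rt <- if (library$provenance[k] == "experimental")
          tolerances$tol_rt_experimental else tolerances$tol_rt_qsrr
        if (abs(neutral - mass) / mass < tolerances$tol_mass &&
            abs(features$rt[i] - pred[k]) / pred[k] < tol_rt) {
          rows[[length(rows) + 1L]] <- data.frame(
            feature = i, compound_id = library$compound_id[k],
            adduct = adducts$name[j], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(feature = integer(0), compound_id = character(0),
                      adduct = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# Canonical sorted key set for match-set equality comparisons.
match_keys <- function(df) {
  sort(paste(df$feature, df$compound_id, df$adduct, sep = "|"))
}

# A small hand-built library with well-separated masses and retention.
toy_library <- function(n = 6, provenance = "experimental") {
  lib <- data.frame(
    compound_id = sprintf("T%02d", seq_len(n)),
    name = sprintf("toy %02d", seq_len(n)),
    monoisotopic_mass = seq(280, by = 15, length.out = n),
    ln_kw = seq(6, 9.5, length.out = n),
    S = seq(18, 34, length.out = n),
    provenance = provenance,
    stringsAsFactors = FALSE)
  class(lib) <- c("compound_library", "data.frame")
  lib
}

# Exact [M+H]+ features (no noise) for a library under a gradient.
exact_features <- function(library, gradient) {
  pred <- predict_library_rt(library, gradient)$predicted_rt
  shift <- default_adducts()$mass_shift[1]  # [M+H]+
  data.frame(mz = library$monoisotopic_mass - shift,
             rt = pred, known_identity = library$compound_id,
             stringsAsFactors = FALSE)
}
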