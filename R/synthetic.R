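#' Synthetic study scenario
#'
#' Bundles every knob of the synthetic-data generator: a steroid-like
#' compound library (LSS parameters and monoisotopic masses), the gradient
#' program under which "observed" features are produced, an optional
#' instrument perturbation, retention-time noise, decoy features, and the
#' adducts under which compounds are observed. Defaults emulate a typical
#' C18 steroid separation: ln kw in \[5, 11\] and S in \[15, 40\] (so the
#' initial retention k0 at phi0 = 0.02 is large, >> 100), masses in a
#' 250-500 Da window, and a 2\% -> 100\% acetonitrile ramp over 14 min with
#' t0 = 0.8 min and tD = 0.75 min.
#'
#' A fixed fraction of compounds is placed in isomer clusters (identical
#' exact mass, distinct LSS parameters) of size 2-3, since distinguishing
#' isomers by retention is precisely what the retention model is for.
#'
#' @param seed Integer seed; the generator is fully deterministic given it
#'   (R's default Mersenne-Twister PRNG).
#' @param n_compounds Library size.
#' @param ln_kw_range,S_range Uniform sampling ranges of the LSS
#'   parameters.
#' @param mass_range Monoisotopic mass window (Da).
#' @param gradient A [gradient_program()].
#' @param perturbation A [perturbation_spec()] describing the instrument
#'   mismatch to emulate.
#' @param rt_noise_sd Gaussian noise sd (min) added to observed retention
#'   times.
#' @param n_decoys Number of decoy features guaranteed (by construction)
#'   not to match any library compound.
#' @param adducts Adduct registry rows under which each compound is
#'   observed; defaults to \[M+H\]+ only, giving one feature per compound.
#' @param isomer_fraction Fraction of compounds grouped into shared-mass
#'   isomer clusters (default 0.2).
#' @param qsrr_fraction Fraction of compounds flagged with `qsrr`
#'   provenance (default 0; the rest are `experimental`).
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed,
                               n_compounds = 70,
                               ln_kw_range = c(5, 11),
                               S_range = c(15, 40),
                               mass_range = c(250, 500),
                               gradient = gradient_program(0.02, 0.98, 14, 0.8, 0.75),
                               perturbation = perturbation_spec(),
                               rt_noise_sd = 0,
                               n_decoys = 0,
                               adducts = default_adducts()[1, , drop = FALSE],
                               isomer_fraction = 0.2,
                               qsrr_fraction = 0) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            inherits(gradient, "gradient_program"),
            inherits(perturbation, "perturbation_spec"))
  if (rt_noise_sd < 0) stop_lssrt("rt_noise_sd must be >= 0", "domain")
  if (diff(ln_kw_range) <= 0 || diff(S_range) <= 0 || diff(mass_range) <= 0)
    stop_lssrt("parameter ranges must be non-degenerate", "domain")
  if (isomer_fraction < 0 || isomer_fraction > 1 ||
      qsrr_fraction < 0 || qsrr_fraction > 1)
    stop_lssrt("fractions must lie in [0, 1]", "domain")
  structure(list(seed = as.integer(seed), n_compounds = n_compounds,
                 ln_kw_range = ln_kw_range, S_range = S_range,
                 mass_range = mass_range, gradient = gradient,
                 perturbation = perturbation, rt_noise_sd = rt_noise_sd,
                 n_decoys = n_decoys, adducts = adducts,
                 isomer_fraction = isomer_fraction,
                 qsrr_fraction = qsrr_fraction),
            class = "synthetic_scenario")
}

#' Generate a synthetic compound library
#'
#' Draws `n_compounds` compounds with ln kw and S uniform over the scenario
#' ranges and masses uniform over the mass window, then overwrites the
#' masses within isomer clusters so that clustered compounds share an exact
#' mass while keeping their individual LSS parameters. Deterministic for a
#' fixed scenario seed.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A `compound_library` data.frame with an extra `isomer_cluster`
#'   column (NA outside clusters).
#' @export
gen_library <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  n <- scenario$n_compounds
  if (n == 0) {
    lib <- data.frame(compound_id = character(0), name = character(0),
                      monoisotopic_mass = numeric(0), ln_kw = numeric(0),
                      S = numeric(0), provenance = character(0),
                      isomer_cluster = integer(0), stringsAsFactors = FALSE)
    class(lib) <- c("compound_library", "data.frame")
    return(lib)
  }
  with_seed(scenario$seed, {
    ln_kw <- stats::runif(n, scenario$ln_kw_range[1], scenario$ln_kw_range[2])
    S <- stats::runif(n, scenario$S_range[1], scenario$S_range[2])
    mass <- stats::runif(n, scenario$mass_range[1], scenario$mass_range[2])
    provenance <- rep("experimental", n)
    n_qsrr <- round(scenario$qsrr_fraction * n)
    if (n_qsrr > 0) provenance[sample.int(n, n_qsrr)] <- "qsrr"

    cluster <- rep(NA_integer_, n)
    n_iso <- round(scenario$isomer_fraction * n)
    if (n_iso >= 2) {
      members <- sample.int(n, n_iso)
      cl_id <- 0L
      i <- 1L
      while (i <= n_iso - 1L) {
        size <- min(sample(2:3, 1), n_iso - i + 1L)
        if (size < 2) break
        cl_id <- cl_id + 1L
        idx <- members[i:(i + size - 1L)]
        cluster[idx] <- cl_id
        mass[idx] <- mass[idx[1]]  # shared exact mass within the cluster
        i <- i + size
      }
    }
    lib <- data.frame(
      compound_id = sprintf("CPD%03d", seq_len(n)),
      name = sprintf("synthetic steroid %03d", seq_len(n)),
      monoisotopic_mass = mass, ln_kw = ln_kw, S = S,
      provenance = provenance, isomer_cluster = cluster,
      stringsAsFactors = FALSE)
    class(lib) <- c("compound_library", "data.frame")
    lib
  })
}

#' Generate synthetic LC-MS features with ground truth
#'
#' Produces one feature per (compound, scenario adduct): m/z is the ion
#' m/z, `(mass - mass_shift) / charge`, and rt is the true
#' [retention_time()] under the scenario gradient plus Gaussian noise of sd
#' `rt_noise_sd`. `n_decoys` additional features carry m/z values placed
#' beyond the largest library ion m/z by construction (at least 5\% above
#' it), so they cannot match any compound even at several times the usual
#' mass tolerance; their identity is NA.
#'
#' @param library A compound library, normally from [gen_library()].
#' @param scenario The [synthetic_scenario()] (its seed, offset by 1, keeps
#'   feature noise independent of the library draw).
#' @return A feature data.frame with columns `mz`, `rt`, `known_identity`,
#'   `adduct`.
#' @export
gen_features <- function(library, scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  library <- as_compound_library(library)
  adducts <- scenario$adducts
  g <- scenario$gradient
  rt_true <- predict_library_rt(library, g)$predicted_rt
  rows <- list()
  for (j in seq_len(nrow(adducts))) {
    rows[[j]] <- data.frame(
      mz = (library$monoisotopic_mass - adducts$mass_shift[j]) / adducts$charge[j],
      rt = rt_true,
      known_identity = library$compound_id,
      adduct = adducts$name[j],
      stringsAsFactors = FALSE)
  }
  feats <- do.call(rbind, rows)
  with_seed(scenario$seed + 1L, {
    if (scenario$rt_noise_sd > 0 && nrow(feats) > 0)
      feats$rt <- feats$rt + stats::rnorm(nrow(feats), 0, scenario$rt_noise_sd)
    if (scenario$n_decoys > 0) {
      max_mz <- if (nrow(feats) > 0) max(feats$mz) else scenario$mass_range[2]
      decoy_mz <- max_mz * (1.05 + cumsum(stats::runif(scenario$n_decoys, 0.01, 0.05)))
      decoy_rt <- stats::runif(scenario$n_decoys, g$t_dead,
                               g$t_dead + g$t_dwell + g$t_gradient)
      feats <- rbind(feats, data.frame(
        mz = decoy_mz, rt = decoy_rt,
        known_identity = NA_character_, adduct = NA_character_,
        stringsAsFactors = FALSE))
    }
    feats
  })
}

#' Apply a relative perturbation to a gradient program
#'
#' Scales the dead time by `1 + rel_dt0`, the dwell time by `1 + rel_dtD`,
#' and the ramp duration by `1 / (1 + rel_db)` (the intrinsic steepness is
#' proportional to `t_dead / t_gradient`, so shortening the ramp raises b).
#'
#' @param gradient A [gradient_program()].
#' @param perturbation A [perturbation_spec()].
#' @return A perturbed [gradient_program()]; invariant violations raise an
#'   error.
#' @export
perturb_gradient <- function(gradient, perturbation) {
  stopifnot(inherits(gradient, "gradient_program"),
            inherits(perturbation, "perturbation_spec"))
  gradient_program(
    phi0 = gradient$phi0,
    delta_phi = gradient$delta_phi,
    t_gradient = gradient$t_gradient / (1 + perturbation$rel_db),
    t_dead = gradient$t_dead * (1 + perturbation$rel_dt0),
    t_dwell = gradient$t_dwell * (1 + perturbation$rel_dtD))
}

# Run code under a temporary RNG state so generators are deterministic
# without clobbering the caller's random stream.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
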