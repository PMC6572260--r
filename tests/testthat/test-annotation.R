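test_that("default adduct registry matches independent isotope masses", {
  # independent values: proton = 1.00727646688 Da; monoisotopic H2O from
  # 2 * 1.00782503207 (1H) + 15.99491461956 (16O); 23Na = 22.9897692809,
  # minus one electron (0.00054857991) for the cation
  ad <- default_adducts()
  expect_setequal(ad$name, c("[M+H]+", "[M-H2O+H]+", "[M-2H2O+H]+",
                             "[M-3H2O+H]+", "[M+Na]+"))
  h2o <- 2 * 1.00782503207 + 15.99491461956
  shift <- setNames(ad$mass_shift, ad$name)
  expect_equal(shift[["[M+H]+"]], -1.00727646688, tolerance = 1e-5)
  expect_equal(shift[["[M-H2O+H]+"]], h2o - 1.00727646688, tolerance = 1e-5)
  expect_equal(shift[["[M-2H2O+H]+"]], 2 * h2o - 1.00727646688, tolerance = 1e-5)
  expect_equal(shift[["[M-3H2O+H]+"]], 3 * h2o - 1.00727646688, tolerance = 1e-5)
  expect_equal(shift[["[M+Na]+"]], -(22.9897692809 - 0.00054857991),
               tolerance = 1e-5)
  expect_true(all(ad$charge >= 1))
})

test_that("an exact protonated feature yields exactly one match at its level", {
  g <- std_gradient()
  lib <- toy_library(3)
  feats <- exact_features(lib, g)[2, , drop = FALSE]
  ann <- annotate_features(feats, lib, g)
  expect_equal(nrow(ann$matches), 1L)
  expect_equal(ann$matches$compound_id, "T02")
  expect_equal(ann$matches$adduct, "[M+H]+")
  expect_equal(ann$matches$level, "2+")
  expect_equal(ann$matches$rel_mass_error, 0)
  expect_equal(ann$matches$rel_rt_error, 0)

  lib$provenance <- "qsrr"
  ann2 <- annotate_features(feats, lib, g)
  expect_equal(ann2$matches$level, "2")
})

test_that("empty feature lists annotate to an empty result", {
  g <- std_gradient()
  lib <- toy_library(3)
  ann <- annotate_features(data.frame(mz = numeric(0), rt = numeric(0)), lib, g)
  expect_equal(nrow(ann$matches), 0L)
  expect_equal(nrow(ann$features), 0L)
})

test_that("annotation equals the exhaustive triple-loop reference", {
  g <- std_gradient()
  scen <- synthetic_scenario(seed = 101, n_compounds = 50, rt_noise_sd = 0.05,
                             n_decoys = 100, adducts = default_adducts(),
                             qsrr_fraction = 0.4)
  lib <- gen_library(scen)
  feats <- gen_features(lib, scen)  # 50 compounds x 5 adducts + 100 decoys
  expect_equal(nrow(feats), 350L)
  tol <- tolerance_config(mass_ppm = 20, rt_experimental = 0.02, rt_qsrr = 0.08)
  ann <- annotate_features(feats, lib, g, tol, default_adducts())
  ref <- brute_annotate(feats, lib, g, tol, default_adducts())
  expect_gt(nrow(ref), 0)
  expect_identical(match_keys(ann$matches), match_keys(ref))
})

test_that("matches within a feature are sorted by combined normalised error", {
  g <- std_gradient()
  scen <- synthetic_scenario(seed = 101, n_compounds = 50, rt_noise_sd = 0.05,
                             adducts = default_adducts(), qsrr_fraction = 0.4)
  lib <- gen_library(scen)
  feats <- gen_features(lib, scen)
  ann <- annotate_features(feats, lib, g,
                           tolerance_config(20, 0.05, 0.10), default_adducts())
  for (f in unique(ann$matches$feature)) {
    m <- ann$matches[ann$matches$feature == f, ]
    score <- sqrt(m$rel_mass_error^2 + m$rel_rt_error^2)
    expect_true(!is.unsorted(score))
  }
})

test_that("success rate counts recovered identities over library standards", {
  g <- std_gradient()
  lib <- toy_library(10)
  feats <- exact_features(lib, g)
  # push two features far off in retention so their identity is lost
  feats$rt[c(4, 7)] <- feats$rt[c(4, 7)] * 1.5
  ann <- annotate_features(feats, lib, g)
  expect_equal(success_rate(ann, lib), 0.8)

  # all observed standards recovered: the denominator counts identities
  # actually observed and present in the library
  ann_full <- annotate_features(exact_features(lib, g)[1:5, ], lib, g)
  expect_equal(success_rate(ann_full, lib), 1.0)

  # vanishing tolerance finds nothing once features carry any error at all
  feats_eps <- exact_features(lib, g)
  feats_eps$mz <- feats_eps$mz * (1 + 1e-6)
  feats_eps$rt <- feats_eps$rt * 1.001
  ann_none <- annotate_features(feats_eps, lib, g,
                                tolerance_config(1e-3, 1e-9, 1e-9))
  expect_equal(success_rate(ann_none, lib), 0)
})

test_that("misattribution rate is the fraction of wrong annotations", {
  g <- std_gradient()
  lib <- toy_library(4)
  # two isomer pairs: identical masses, close but distinct retention
  lib$monoisotopic_mass[2] <- lib$monoisotopic_mass[1]
  lib$ln_kw[2] <- lib$ln_kw[1] + 0.05
  feats <- exact_features(lib, g)
  # generous RT tolerance: each isomer feature matches both partners
  ann <- annotate_features(feats, lib, g, tolerance_config(5, 0.5, 0.5))
  m <- ann$matches
  truth <- ann$features$known_identity[m$feature]
  expect_equal(misattribution_rate(ann), mean(m$compound_id != truth))
  expect_gt(misattribution_rate(ann), 0)

  # all matches correct when masses are unique and tolerance tight
  ann2 <- annotate_features(exact_features(toy_library(4), g),
                            toy_library(4), g)
  expect_equal(misattribution_rate(ann2), 0)

  # truth absent from the library: every match is a misattribution
  lib3 <- toy_library(3)
  feats3 <- exact_features(lib3, g)
  feats3$known_identity <- c("X1", "X2", "X3")
  ann3 <- annotate_features(feats3, lib3, g)
  expect_equal(misattribution_rate(ann3), 1)
})

test_that("rates error out when undefined", {
  g <- std_gradient()
  lib <- toy_library(3)
  feats <- exact_features(lib, g)
  feats$known_identity <- NULL
  ann <- annotate_features(feats, lib, g)
  expect_error(success_rate(ann, lib), "known_identity")
  expect_error(misattribution_rate(ann), "known_identity")

  feats2 <- exact_features(lib, g)
  feats2$known_identity <- c("X1", "X2", "X3")  # none in library
  ann2 <- annotate_features(feats2, lib, g)
  expect_error(success_rate(ann2, lib), "success rate undefined")
})

test_that("the tolerance sweep yields monotone success and consistent counts", {
  g <- std_gradient()
  scen <- synthetic_scenario(seed = 77, n_compounds = 40, rt_noise_sd = 0.03,
                             n_decoys = 20, isomer_fraction = 0.3)
  lib <- gen_library(scen)
  feats <- gen_features(lib, scen)
  grid <- c(0.005, 0.01, 0.05, 0.10, 0.15)
  sw <- tolerance_sweep(feats, lib, g, grid)
  expect_equal(nrow(sw), 5L)
  suc <- sw$success_rate[!is.na(sw$success_rate)]
  expect_true(!is.unsorted(suc))
  expect_true(!is.unsorted(sw$n_matches))
  expect_true(all(sw$success_rate >= 0 & sw$success_rate <= 1, na.rm = TRUE))
  expect_true(all(sw$misattribution_rate >= 0 & sw$misattribution_rate <= 1,
                  na.rm = TRUE))
  # per-tolerance counts agree with a brute-force recount
  for (tol in grid[c(2, 4)]) {
    ref <- brute_annotate(feats, lib, g, tolerance_config(5, tol, tol),
                          default_adducts()[1, , drop = FALSE])
    expect_equal(sw$n_matches[sw$tol_rt == tol], nrow(ref))
  }
  # an effectively unbounded RT tolerance reduces matching to mass alone
  sw_inf <- tolerance_sweep(feats, lib, g, c(0.005, 1e3))
  ref_inf <- brute_annotate(feats, lib, g, tolerance_config(5, 1e3, 1e3),
                            default_adducts()[1, , drop = FALSE])
  expect_equal(sw_inf$n_matches[2], nrow(ref_inf))
  expect_error(tolerance_sweep(feats, lib, g, c(0.1, 0.05)), "increasing")
})

test_that("decoy features receive no annotations at realistic tolerances", {
  g <- std_gradient()
  scen <- synthetic_scenario(seed = 31, n_compounds = 30, n_decoys = 50)
  lib <- gen_library(scen)
  feats <- gen_features(lib, scen)
  ann <- annotate_features(feats, lib, g, tolerance_config(5, 0.005, 0.05))
  decoy_rows <- which(is.na(feats$known_identity))
  expect_length(intersect(ann$matches$feature, decoy_rows), 0)
})

test_that("well-separated compounds annotate with unique identities at 0.5% tolerance", {
  g <- std_gradient()
  scen <- synthetic_scenario(seed = 53, n_compounds = 60, isomer_fraction = 0)
  lib <- gen_library(scen)
  pred <- predict_library_rt(lib, g)$predicted_rt
  tolm <- 5e-6
  # greedily keep compounds pairwise separated by >1% in predicted retention
  # or >2x the mass tolerance in mass
  keep <- integer(0)
  for (i in seq_len(nrow(lib))) {
    ok <- all(vapply(keep, function(j)
      abs(pred[i] - pred[j]) / pred[j] > 0.01 ||
        abs(lib$monoisotopic_mass[i] - lib$monoisotopic_mass[j]) /
          lib$monoisotopic_mass[j] > 2 * tolm, logical(1)))
    if (ok) keep <- c(keep, i)
  }
  lib2 <- lib[keep, ]
  class(lib2) <- c("compound_library", "data.frame")
  expect_gt(nrow(lib2), 10)
  ann <- annotate_features(exact_features(lib2, g), lib2, g,
                           tolerance_config(5, 0.005, 0.005),
                           adducts = default_adducts()[1, , drop = FALSE])
  mult <- multiplicity_stats(ann)
  expect_equal(mult$n_annotated, nrow(lib2))
  expect_equal(mult$mean, 1)
  expect_equal(unname(mult$percentiles), c(1, 1, 1))
})

test_that("multiplicity statistics recover gamma parameters and handle degeneracy", {
  # degenerate: every annotated feature has exactly one match
  m1 <- multiplicity_stats(rep(1, 25))
  expect_equal(m1$mean, 1)
  expect_equal(unname(m1$percentiles), c(1, 1, 1))
  expect_true(is.na(m1$shape))

  # parameter recovery at n = 1e4
  set.seed(19)
  counts <- rgamma(1e4, shape = 2, scale = 1.5)
  fit <- multiplicity_stats(counts)
  expect_lt(abs(fit$shape - 2) / 2, 0.05)
  expect_lt(abs(1 / fit$rate - 1.5) / 1.5, 0.05)
  # percentiles come from the fitted distribution
  expect_equal(unname(fit$percentiles),
               qgamma(c(0.5, 0.75, 0.9), shape = fit$shape, rate = fit$rate))
  expect_error(multiplicity_stats(numeric(0)), "multiplicity undefined")
})
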