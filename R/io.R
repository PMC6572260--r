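# Units throughout the file formats: minutes for all times, Da for masses,
# Th for m/z; ln_kw and S are dimensionless and in natural-log units.

REQUIRED_LIBRARY_COLS <- c("compound_id", "name", "monoisotopic_mass",
                           "ln_kw", "S", "provenance")

# Validate (and lightly coerce) a compound library data.frame.
as_compound_library <- function(x) {
  if (inherits(x, "compound_library")) return(x)
  if (!is.data.frame(x))
    stop_lssrt("a compound library must be a data.frame", "format")
  validate_library(x)
}

validate_library <- function(df, where = "library") {
  missing <- setdiff(REQUIRED_LIBRARY_COLS, names(df))
  if (length(missing) > 0)
    stop_lssrt(sprintf("%s is missing required column(s): %s", where,
                       paste(missing, collapse = ", ")), "format")
  df$compound_id <- as.character(df$compound_id)
  df$name <- as.character(df$name)
  for (col in c("monoisotopic_mass", "ln_kw", "S")) {
    if (!is.numeric(df[[col]])) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]))
      if (length(bad) > 0 || anyNA(v))
        stop_lssrt(sprintf("%s: non-numeric %s at row(s) %s", where, col,
                           paste(utils::head(bad, 5), collapse = ", ")), "format")
      df[[col]] <- v
    }
  }
  dup <- df$compound_id[duplicated(df$compound_id)]
  if (length(dup) > 0)
    stop_lssrt(sprintf("%s: duplicate compound_id: %s", where,
                       paste(unique(dup), collapse = ", ")), "format")
  bad_mass <- which(!is.finite(df$monoisotopic_mass) | df$monoisotopic_mass <= 0)
  if (length(bad_mass) > 0)
    stop_lssrt(sprintf("%s: non-positive monoisotopic_mass at row(s) %s", where,
                       paste(bad_mass, collapse = ", ")), "format")
  bad_s <- which(!is.finite(df$S) | df$S < 0)
  if (length(bad_s) > 0)
    stop_lssrt(sprintf("%s: negative or missing S at row(s) %s", where,
                       paste(bad_s, collapse = ", ")), "format")
  bad_prov <- which(!df$provenance %in% c("experimental", "qsrr"))
  if (length(bad_prov) > 0)
    stop_lssrt(sprintf("%s: provenance must be 'experimental' or 'qsrr' at row(s) %s",
                       where, paste(bad_prov, collapse = ", ")), "format")
  class(df) <- c("compound_library", "data.frame")
  df
}

#' Read a compound library from CSV
#'
#' Expects a header with at least `compound_id,name,monoisotopic_mass,
#' ln_kw,S,provenance`; any additional columns (e.g. `iupac`, `cas`,
#' `smiles`, `pathway`, `xrefs`) are carried through as metadata.
#' `provenance` must be `experimental` or `qsrr`. Rows violating the
#' invariants (duplicate ids, non-positive masses, negative S) are rejected
#' with row-numbered diagnostics.
#'
#' @param path Path to a CSV file (RFC-4180, UTF-8, dot decimal separator).
#' @return A `compound_library` data.frame.
#' @seealso [write_library()], [library_counts()]
#' @export
read_library <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, fileEncoding = "UTF-8")
  validate_library(df, where = basename(path))
}

#' Write a compound library to CSV
#'
#' @param library A `compound_library` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  library <- as_compound_library(library)
  utils::write.csv(library, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Per-provenance compound counts of a library
#'
#' @param library A `compound_library` data.frame.
#' @return A list with `total`, `experimental` and `qsrr` counts.
#' @export
library_counts <- function(library) {
  library <- as_compound_library(library)
  list(total = nrow(library),
       experimental = sum(library$provenance == "experimental"),
       qsrr = sum(library$provenance == "qsrr"))
}

#' Read an LC-MS feature list from CSV
#'
#' Expects header columns `mz,rt`; optional columns `identity` (mapped to
#' `known_identity`), `adduct` and `formula` are kept, any others are
#' ignored. File order is preserved. An empty file (header only) yields an
#' empty feature table.
#'
#' @param path Path to a CSV file.
#' @return A data.frame with columns `mz` (Th), `rt` (min) and optionally
#'   `known_identity`.
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, fileEncoding = "UTF-8")
  if (!all(c("mz", "rt") %in% names(df)))
    stop_lssrt(sprintf("%s must have columns mz and rt", basename(path)),
               "format")
  for (col in c("mz", "rt")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & nzchar(trimws(df[[col]])))
    if (length(bad) > 0)
      stop_lssrt(sprintf("%s: non-numeric %s at line(s) %s", basename(path),
                         col, paste(bad + 1L, collapse = ", ")), "format")
    if (nrow(df) > 0 && any(is.na(v)))
      stop_lssrt(sprintf("%s: missing %s at line(s) %s", basename(path), col,
                         paste(which(is.na(v)) + 1L, collapse = ", ")), "format")
    df[[col]] <- v
  }
  out <- df[, intersect(c("mz", "rt", "identity", "adduct", "formula"),
                        names(df)), drop = FALSE]
  if ("identity" %in% names(out)) {
    names(out)[names(out) == "identity"] <- "known_identity"
    out$known_identity <- ifelse(nzchar(trimws(as.character(out$known_identity))),
                                 as.character(out$known_identity), NA_character_)
  }
  if (nrow(out) > 0) check_feature_frame(out)
  out
}

#' Read a calibrant list from CSV
#'
#' Expects header columns `compound_id,observed_rt_min`.
#'
#' @param path Path to a CSV file.
#' @return A data.frame with columns `compound_id` and `observed_rt_min`.
#' @export
read_calibrants <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("compound_id", "observed_rt_min") %in% names(df)))
    stop_lssrt(sprintf("%s must have columns compound_id and observed_rt_min",
                       basename(path)), "format")
  df$compound_id <- as.character(df$compound_id)
  df$observed_rt_min <- as.numeric(df$observed_rt_min)
  if (nrow(df) > 0 && any(is.na(df$observed_rt_min)))
    stop_lssrt(sprintf("%s: non-numeric observed_rt_min", basename(path)),
               "format")
  df[, c("compound_id", "observed_rt_min")]
}

#' Read a run configuration file
#'
#' A flat YAML file with a `gradient` block (`phi0`, `delta_phi`,
#' `t_gradient_min`, `t_dead_min`, `t_dwell_min`) and an optional
#' `tolerances` block (`mass_ppm`, `rt_experimental`, `rt_qsrr`).
#'
#' @param path Path to a YAML config file.
#' @return A list with elements `gradient` (a [gradient_program()]) and
#'   `tolerances` (a [tolerance_config()], defaults applied for missing
#'   keys).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$gradient))
    stop_lssrt(sprintf("%s has no 'gradient' block", basename(path)), "format")
  g <- cfg$gradient
  need <- c("phi0", "delta_phi", "t_gradient_min", "t_dead_min", "t_dwell_min")
  missing <- setdiff(need, names(g))
  if (length(missing) > 0)
    stop_lssrt(sprintf("%s gradient block is missing: %s", basename(path),
                       paste(missing, collapse = ", ")), "format")
  gradient <- gradient_program(g$phi0, g$delta_phi, g$t_gradient_min,
                               g$t_dead_min, g$t_dwell_min)
  tl <- cfg$tolerances
  tolerances <- tolerance_config(
    mass_ppm = tl$mass_ppm %||% 5,
    rt_experimental = tl$rt_experimental %||% 0.005,
    rt_qsrr = tl$rt_qsrr %||% 0.05)
  list(gradient = gradient, tolerances = tolerances)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write annotations to JSON
#'
#' Emits one object per feature: `{"feature": {"mz": ..., "rt": ...},
#' "matches": [{"compound_id", "name", "adduct", "level",
#' "predicted_rt_min", "rel_mass_error_ppm", "rel_rt_error_pct"}, ...]}`.
#' The document is a JSON array with one element per feature, in feature
#' order; features with no match are emitted with an empty `matches` array,
#' and an empty annotation yields `[]`. Output is byte-stable for a fixed
#' input: keys are emitted in a fixed order and floating-point values are
#' rounded to 6 significant digits. This layout is schema version 1 of the
#' package's annotation export.
#'
#' @param annotation A [annotate_features()] result.
#' @param path Output path; the JSON document is also returned invisibly
#'   as a string when `path` is `NULL`.
#' @return The JSON string, invisibly.
#' @export
write_annotations <- function(annotation, path = NULL) {
  stopifnot(inherits(annotation, "feature_annotation"))
  feats <- annotation$features
  m <- annotation$matches
  per_feature <- lapply(seq_len(nrow(feats)), function(i) {
    mi <- m[m$feature == i, , drop = FALSE]
    matches <- lapply(seq_len(nrow(mi)), function(r) {
      list(compound_id = mi$compound_id[r],
           name = mi$name[r],
           adduct = mi$adduct[r],
           level = mi$level[r],
           predicted_rt_min = signif(mi$predicted_rt[r], 6),
           rel_mass_error_ppm = signif(mi$rel_mass_error[r] * 1e6, 6),
           rel_rt_error_pct = signif(mi$rel_rt_error[r] * 100, 6))
    })
    list(feature = list(mz = signif(feats$mz[i], 6), rt = signif(feats$rt[i], 6)),
         matches = matches)
  })
  json <- jsonlite::toJSON(per_feature, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(json, con)
  }
  invisible(as.character(json))
}
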