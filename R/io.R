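cohort_columns <- c("patient_id", "age", "sex", "diameter_mm", "height_mm",
                    "ciliary_body", "extraocular", "chr3_status",
                    "mam5_full", "mam5_nochr3", "mam5_nogenetics",
                    "stage", "endpoint")
score_columns <- c("mam5_full", "mam5_nochr3", "mam5_nogenetics")

#' Write / read a cohort CSV
#'
#' The cohort schema has one row per patient with the columns produced by
#' [generate_cohort()]. Scores are serialised with 17 significant digits so
#' a write-read round trip reproduces every double bit-exactly. The only
#' permitted "missing" value in an analysis cohort is the `chr3_status`
#' token `"unknown"`. `read_cohort()` validates the schema and reports the
#' first offending row and column.
#'
#' @param cohort A cohort data frame.
#' @param path File path.
#' @return `read_cohort()` returns a validated `um_cohort` data frame with
#'   attribute `provenance` set to the source filename;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- as.data.frame(cohort)[, cohort_columns]
  for (col in score_columns) out[[col]] <- sprintf("%.17g", out[[col]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(cohort_columns, names(raw))
  if (length(missing_cols)) {
    stop("cohort file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  raw <- raw[, cohort_columns]
  fail <- function(row, col, why) {
    stop(sprintf("invalid cohort row %d, column '%s': %s", row, col, why))
  }
  check_numeric <- function(col, lo = -Inf, hi = Inf) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.finite(v) | v < lo | v > hi)
    if (length(bad)) {
      fail(bad[1], col, sprintf("value '%s' not a number in [%g, %g]",
                                raw[[col]][bad[1]], lo, hi))
    }
    v
  }
  check_logical <- function(col) {
    v <- raw[[col]]
    map <- c("TRUE" = TRUE, "FALSE" = FALSE, "1" = TRUE, "0" = FALSE)
    bad <- which(!v %in% names(map))
    if (length(bad)) fail(bad[1], col, paste0("value '", v[bad[1]],
                                              "' not TRUE/FALSE"))
    unname(map[v])
  }
  dup <- which(duplicated(raw$patient_id))
  if (length(dup)) fail(dup[1], "patient_id", "duplicate identifier")
  out <- data.frame(patient_id = raw$patient_id, stringsAsFactors = FALSE)
  out$age <- check_numeric("age", 0, 120)
  bad_sex <- which(!raw$sex %in% c("F", "M"))
  if (length(bad_sex)) fail(bad_sex[1], "sex", "expected F or M")
  out$sex <- raw$sex
  out$diameter_mm <- check_numeric("diameter_mm", 0, 50)
  out$height_mm <- check_numeric("height_mm", 0, 30)
  out$ciliary_body <- check_logical("ciliary_body")
  out$extraocular <- check_logical("extraocular")
  bad_chr3 <- which(!raw$chr3_status %in% c("monosomy", "disomy", "unknown"))
  if (length(bad_chr3)) {
    fail(bad_chr3[1], "chr3_status", "expected monosomy/disomy/unknown")
  }
  out$chr3_status <- raw$chr3_status
  for (col in score_columns) out[[col]] <- check_numeric(col, 0, 1)
  bad_stage <- which(!raw$stage %in% stage_levels)
  if (length(bad_stage)) {
    fail(bad_stage[1], "stage",
         paste0("unknown stage label '", raw$stage[bad_stage[1]], "'"))
  }
  out$stage <- raw$stage
  out$endpoint <- check_logical("endpoint")
  attr(out, "provenance") <- path
  class(out) <- c("um_cohort", "data.frame")
  out
}

#' Apply the study eligibility criteria to a raw cohort extract
#'
#' Drops records that would be excluded from analysis: iris melanomas,
#' patients without at least 5 years of follow-up and no observed endpoint,
#' and records with missing data in any of age, sex, tumour dimensions
#' (diameter or height), ciliary body involvement or extraocular extension.
#' The raw extract may carry the optional flags `iris_melanoma` and
#' `followup_adequate`; when absent, the corresponding rules are vacuous.
#'
#' @param raw A data frame; covariate columns may contain `NA`.
#' @return List with `eligible` (the retained rows) and `exclusions` (a data
#'   frame with `row`, `patient_id`, `reason`, one entry per dropped
#'   record, first matching rule wins).
#' @export
eligibility_filter <- function(raw) {
  n <- nrow(raw)
  get_col <- function(nm, default) {
    if (nm %in% names(raw)) raw[[nm]] else rep(default, n)
  }
  reason <- rep(NA_character_, n)
  mark <- function(reason_vec, cond, why) {
    ifelse(is.na(reason_vec) & cond, why, reason_vec)
  }
  iris <- get_col("iris_melanoma", FALSE)
  fup <- get_col("followup_adequate", TRUE)
  endpoint <- get_col("endpoint", FALSE)
  reason <- mark(reason, !is.na(iris) & iris, "iris melanoma")
  reason <- mark(reason, !is.na(fup) & !fup & !(!is.na(endpoint) & endpoint),
                 "insufficient follow-up without observed endpoint")
  reason <- mark(reason, is.na(get_col("age", NA)), "missing age")
  reason <- mark(reason, is.na(get_col("sex", NA)), "missing sex")
  reason <- mark(reason, is.na(get_col("diameter_mm", NA)) |
                   is.na(get_col("height_mm", NA)),
                 "missing tumour dimensions")
  reason <- mark(reason, is.na(get_col("ciliary_body", NA)),
                 "missing ciliary body involvement")
  reason <- mark(reason, is.na(get_col("extraocular", NA)),
                 "missing extraocular extension")
  drop <- !is.na(reason)
  ids <- get_col("patient_id", NA_character_)
  list(
    eligible = raw[!drop, , drop = FALSE],
    exclusions = data.frame(row = which(drop),
                            patient_id = ids[drop],
                            reason = reason[drop],
                            stringsAsFactors = FALSE)
  )
}

#' Serialise / parse a generator configuration as YAML
#'
#' `write_cohort_config()` writes an [cohort_config()] object to a YAML
#' file; `read_cohort_config()` parses one back, rejecting unknown keys and
#' re-validating every invariant.
#'
#' @param config An `um_config`.
#' @param path File path.
#' @return `read_cohort_config()` returns an `um_config`;
#'   `write_cohort_config()` returns `path` invisibly.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "um_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(cohort_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(cohort_config, vals)
}
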