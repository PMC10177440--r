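#' @rdname stratify
#' @export
stage_levels <- c("I", "IIA", "IIB", "IIIA", "IIIB", "IIIC")

new_strategy <- function(kind, label, ...) {
  structure(c(list(kind = kind, label = label), list(...)),
            class = "um_strategy")
}

#' Stratification strategies
#'
#' A strategy maps each patient to a surveillance decision: high-risk
#' (enrol in periodic liver imaging) or low-risk. Four kinds are supported,
#' mirroring the prognostic systems compared for uveal melanoma:
#'
#' * `strategy_score_threshold()`: high-risk iff a continuous 5-year
#'   metastasis-risk score is at or above a single threshold (inclusive, as
#'   in "MAM >= 0.05").
#' * `strategy_dual_threshold()`: a chromosome-3-dependent decision rule --
#'   patients with a chromosome 3 result are thresholded on the
#'   full-information score, patients without on the score computed without
#'   chromosome 3, each with its own threshold.
#' * `strategy_stage_threshold()`: high-risk iff ordinal tumour stage is at
#'   or above a cut, under I < IIA < IIB < IIIA < IIIB < IIIC.
#' * `strategy_monosomy3()`: high-risk iff the tumour shows monosomy 3 or no
#'   chromosome 3 result is available (untested patients are also
#'   recommended surveillance); disomy 3 is low-risk.
#'
#' `stratify()` applies any strategy to a cohort and returns a decision
#' vector; `stratify_score_threshold()` and friends are direct forms.
#'
#' @param cohort A cohort data frame with columns `mam5_full`,
#'   `mam5_nochr3`, `mam5_nogenetics`, `stage`, `chr3_status`.
#' @param strategy An `um_strategy` object.
#' @param score_field Score column name, e.g. `"mam5_full"`.
#' @param threshold Probability threshold in \[0, 1\] (inclusive rule).
#' @param score_field_known,score_field_unknown Score columns used for
#'   patients with / without a chromosome 3 result.
#' @param t_known,t_unknown Thresholds for the two subgroups.
#' @param stage_cut Ordinal stage cut, one of I, IIA, IIB, IIIA, IIIB, IIIC.
#' @param label Display name for report tables.
#' @return `stratify()` and the `stratify_*()` functions return an object of
#'   class `um_decisions`: list with logical `high_risk` (one entry per
#'   patient, cohort order) and the strategy `label`.
#' @name stratify
NULL

#' @rdname stratify
#' @export
strategy_score_threshold <- function(score_field, threshold, label = NULL) {
  stopifnot(is.character(score_field), length(threshold) == 1)
  if (threshold < 0 || threshold > 1) stop("`threshold` must be in [0, 1]")
  if (is.null(label)) label <- sprintf("%s >= %g", score_field, threshold)
  new_strategy("score_threshold", label,
               score_field = score_field, threshold = threshold)
}

#' @rdname stratify
#' @export
strategy_dual_threshold <- function(t_known, t_unknown,
                                    score_field_known = "mam5_full",
                                    score_field_unknown = "mam5_nochr3",
                                    label = NULL) {
  if (any(c(t_known, t_unknown) < 0 | c(t_known, t_unknown) > 1)) {
    stop("thresholds must be in [0, 1]")
  }
  if (is.null(label)) {
    label <- sprintf("MAM >= %g / >= %g (known/unknown chr3)",
                     t_known, t_unknown)
  }
  new_strategy("dual_threshold", label,
               score_field_known = score_field_known,
               score_field_unknown = score_field_unknown,
               t_known = t_known, t_unknown = t_unknown)
}

#' @rdname stratify
#' @export
strategy_stage_threshold <- function(stage_cut, label = NULL) {
  stage_cut <- as.character(stage_cut)
  if (!stage_cut %in% stage_levels) {
    stop("unknown stage '", stage_cut, "'; expected one of ",
         paste(stage_levels, collapse = ", "))
  }
  if (is.null(label)) label <- sprintf("Stage >= %s", stage_cut)
  new_strategy("stage_threshold", label, stage_cut = stage_cut)
}

#' @rdname stratify
#' @export
strategy_monosomy3 <- function(label = "Monosomy 3") {
  new_strategy("monosomy3", label)
}

#' @export
print.um_strategy <- function(x, ...) {
  cat(sprintf("<um_strategy %s: %s>\n", x$kind, x$label))
  invisible(x)
}

#' @rdname stratify
#' @export
stratify <- function(cohort, strategy) {
  stopifnot(inherits(strategy, "um_strategy"))
  switch(strategy$kind,
    score_threshold = stratify_score_threshold(
      cohort, strategy$score_field, strategy$threshold, strategy$label),
    dual_threshold = stratify_dual_threshold(
      cohort, strategy$score_field_known, strategy$score_field_unknown,
      strategy$t_known, strategy$t_unknown, strategy$label),
    stage_threshold = stratify_stage_threshold(
      cohort, strategy$stage_cut, strategy$label),
    monosomy3 = stratify_monosomy3(cohort, strategy$label),
    stop("unknown strategy kind '", strategy$kind, "'")
  )
}

get_score <- function(cohort, score_field) {
  s <- cohort[[score_field]]
  if (is.null(s)) stop("cohort has no score column '", score_field, "'")
  if (anyNA(s)) stop("score column '", score_field, "' has missing values")
  s
}

new_decisions <- function(high_risk, label) {
  structure(list(high_risk = as.logical(high_risk), label = label),
            class = "um_decisions")
}

#' @rdname stratify
#' @export
stratify_score_threshold <- function(cohort, score_field, threshold,
                                     label = NULL) {
  if (is.null(label)) label <- sprintf("%s >= %g", score_field, threshold)
  s <- get_score(cohort, score_field)
  new_decisions(s >= threshold, label)
}

#' @rdname stratify
#' @export
stratify_dual_threshold <- function(cohort, score_field_known,
                                    score_field_unknown, t_known, t_unknown,
                                    label = NULL) {
  if (is.null(label)) {
    label <- sprintf("MAM >= %g / >= %g (known/unknown chr3)",
                     t_known, t_unknown)
  }
  known <- cohort$chr3_status != "unknown"
  sk <- get_score(cohort, score_field_known)
  su <- get_score(cohort, score_field_unknown)
  new_decisions(ifelse(known, sk >= t_known, su >= t_unknown), label)
}

#' @rdname stratify
#' @export
stratify_stage_threshold <- function(cohort, stage_cut, label = NULL) {
  stage_cut <- as.character(stage_cut)
  if (!stage_cut %in% stage_levels) stop("unknown stage '", stage_cut, "'")
  if (is.null(label)) label <- sprintf("Stage >= %s", stage_cut)
  st <- as.character(cohort$stage)
  bad <- setdiff(unique(st), stage_levels)
  if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  ord <- match(st, stage_levels)
  new_decisions(ord >= match(stage_cut, stage_levels), label)
}

#' @rdname stratify
#' @export
stratify_monosomy3 <- function(cohort, label = "Monosomy 3") {
  st <- as.character(cohort$chr3_status)
  bad <- setdiff(unique(st), c("monosomy", "disomy", "unknown"))
  if (length(bad)) {
    stop("unknown chr3_status value(s): ", paste(bad, collapse = ", "))
  }
  new_decisions(st %in% c("monosomy", "unknown"), label)
}

#' @export
print.um_decisions <- function(x, ...) {
  cat(sprintf("<um_decisions '%s': %d/%d high-risk>\n", x$label,
              sum(x$high_risk), length(x$high_risk)))
  invisible(x)
}
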