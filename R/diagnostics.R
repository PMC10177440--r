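#' Cross-tabulate surveillance decisions against the 5-year endpoint
#'
#' Counts true/false positives and negatives for a vector of high-risk
#' (surveillance) decisions against the observed endpoint (death from, or
#' detection of, metastasis within 5 years). A patient stratified high-risk
#' who reaches the endpoint is a true positive; one stratified high-risk who
#' does not is a false positive, and so on.
#'
#' @param decisions Logical vector (or a decision vector from [stratify()]):
#'   `TRUE` means high-risk, i.e. enrolled in surveillance.
#' @param endpoints Logical (or 0/1) vector of the same length: `TRUE` means
#'   the 5-year endpoint was observed.
#' @return An object of class `um_confusion`: a list with integer fields
#'   `tp`, `fp`, `fn`, `tn` summing to `length(endpoints)`.
#' @examples
#' confusion(c(TRUE, TRUE, FALSE, FALSE), c(1, 0, 1, 0))
#' @export
confusion <- function(decisions, endpoints) {
  if (inherits(decisions, "um_decisions")) decisions <- decisions$high_risk
  decisions <- as.logical(decisions)
  endpoints <- as.logical(endpoints)
  if (length(decisions) != length(endpoints)) {
    stop("`decisions` (", length(decisions), ") and `endpoints` (",
         length(endpoints), ") have different lengths")
  }
  if (anyNA(decisions) || anyNA(endpoints)) {
    stop("`decisions` and `endpoints` must not contain missing values")
  }
  out <- list(
    tp = sum(decisions & endpoints),
    fp = sum(decisions & !endpoints),
    fn = sum(!decisions & endpoints),
    tn = sum(!decisions & !endpoints)
  )
  structure(out, class = "um_confusion")
}

#' @export
print.um_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2,
              dimnames = list(c("high_risk", "low_risk"),
                              c("endpoint", "no_endpoint")))
  print(m)
  invisible(x)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact two-sided interval for a binomial proportion from inverted tail
#' probabilities, in the Beta-quantile form: the lower limit is the
#' `alpha/2` quantile of Beta(k, n - k + 1) (0 when k = 0) and the upper
#' limit the `1 - alpha/2` quantile of Beta(k + 1, n - k) (1 when k = n).
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param level Confidence level, default 0.95.
#' @return An object of class `um_propci`: list with `estimate`, `lower`,
#'   `upper`, `level`, `numerator`, `denominator`.
#' @examples
#' clopper_pearson(292, 1047)
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  stopifnot(length(k) == 1, length(n) == 1, is.finite(k), is.finite(n))
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n with n >= 1")
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)")
  alpha <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  structure(
    list(estimate = k / n, lower = lower, upper = upper, level = level,
         numerator = as.integer(k), denominator = as.integer(n)),
    class = "um_propci"
  )
}

#' @export
print.um_propci <- function(x, ...) {
  cat(sprintf("%.3f (%g%% CI %.3f-%.3f; %d/%d)\n", x$estimate,
              100 * x$level, x$lower, x$upper, x$numerator, x$denominator))
  invisible(x)
}

#' Sensitivity and specificity with exact confidence intervals
#'
#' Sensitivity = TP / (TP + FN); specificity = TN / (TN + FP), each with a
#' Clopper-Pearson exact interval.
#'
#' @param counts An `um_confusion` object from [confusion()].
#' @param level Confidence level for the intervals.
#' @return List with elements `sensitivity` and `specificity`, each an
#'   `um_propci`.
#' @export
sens_spec <- function(counts, level = 0.95) {
  stopifnot(inherits(counts, "um_confusion"))
  npos <- counts$tp + counts$fn
  nneg <- counts$tn + counts$fp
  if (npos < 1) stop("sensitivity undefined: no endpoint-positive patients")
  if (nneg < 1) stop("specificity undefined: no endpoint-negative patients")
  list(
    sensitivity = clopper_pearson(counts$tp, npos, level),
    specificity = clopper_pearson(counts$tn, nneg, level)
  )
}

#' Predictive values and surveillance fraction
#'
#' In counts mode (an `um_confusion` object), PPV = TP/(TP+FP),
#' NPV = TN/(TN+FN) and the surveillance fraction is the proportion of the
#' cohort stratified high-risk. In scenario mode (explicit sensitivity,
#' specificity and prevalence) the same quantities follow from Bayes'
#' theorem:
#' \deqn{PPV = s\pi / (s\pi + (1-c)(1-\pi))}
#' \deqn{NPV = c(1-\pi) / ((1-s)\pi + c(1-\pi))}
#' \deqn{surveillance = s\pi + (1-c)(1-\pi)}
#' with sensitivity \eqn{s}, specificity \eqn{c} and prevalence \eqn{\pi}.
#'
#' @param counts An `um_confusion` object, or `NULL` to use scenario mode.
#' @param sensitivity,specificity,prevalence Scenario-mode rates (all in
#'   \[0,1\], prevalence in (0,1)); ignored when `counts` is supplied.
#' @return List with numeric `ppv`, `npv`, `surveillance_fraction`.
#' @examples
#' predictive_values(sensitivity = 0.95, specificity = 0.46,
#'                   prevalence = 292 / 1047)
#' @export
predictive_values <- function(counts = NULL, sensitivity = NULL,
                              specificity = NULL, prevalence = NULL) {
  if (!is.null(counts)) {
    stopifnot(inherits(counts, "um_confusion"))
    pred_pos <- counts$tp + counts$fp
    pred_neg <- counts$tn + counts$fn
    if (pred_pos < 1) stop("PPV undefined: no patient stratified high-risk")
    if (pred_neg < 1) stop("NPV undefined: no patient stratified low-risk")
    n <- pred_pos + pred_neg
    return(list(ppv = counts$tp / pred_pos,
                npv = counts$tn / pred_neg,
                surveillance_fraction = pred_pos / n))
  }
  s <- sensitivity; c <- specificity; p <- prevalence
  stopifnot(is.numeric(s), is.numeric(c), is.numeric(p))
  if (s < 0 || s > 1 || c < 0 || c > 1) stop("rates must be in [0, 1]")
  if (p <= 0 || p >= 1) stop("`prevalence` must be in (0, 1)")
  list(
    ppv = s * p / (s * p + (1 - c) * (1 - p)),
    npv = c * (1 - p) / ((1 - s) * p + c * (1 - p)),
    surveillance_fraction = s * p + (1 - c) * (1 - p)
  )
}

#' Round a proportion to a whole percentage
#'
#' Report-table rounding: halves round up, so 0.615 prints as 62.
#'
#' @param x Proportion(s) in \[0, 1\].
#' @return Integer percentage(s).
#' @export
percent_round <- function(x) {
  as.integer(floor(100 * x + 0.5))
}

#' Evaluate one stratification strategy on a cohort (or subgroup)
#'
#' Applies the strategy, cross-tabulates decisions against the endpoint and
#' derives sensitivity, specificity (with exact intervals), predictive
#' values and the surveillance fraction. Subgroup evaluation restricts to
#' patients with known (tested) or unknown chromosome 3 status, mirroring a
#' chromosome-3 availability subgroup analysis.
#'
#' @param cohort A cohort data frame (see [generate_cohort()]).
#' @param strategy An `um_strategy` object.
#' @param subgroup One of `"all"`, `"chr3_known"`, `"chr3_unknown"`.
#' @param level Confidence level.
#' @return An object of class `um_diagnostic_summary`.
#' @export
evaluate_strategy <- function(cohort, strategy,
                              subgroup = c("all", "chr3_known", "chr3_unknown"),
                              level = 0.95) {
  subgroup <- match.arg(subgroup)
  keep <- switch(subgroup,
    all = rep(TRUE, nrow(cohort)),
    chr3_known = cohort$chr3_status != "unknown",
    chr3_unknown = cohort$chr3_status == "unknown"
  )
  sub <- cohort[keep, , drop = FALSE]
  if (nrow(sub) == 0) stop("subgroup '", subgroup, "' is empty")
  if (length(unique(sub$endpoint)) < 2) {
    stop("subgroup '", subgroup, "' has a single endpoint class")
  }
  dec <- stratify(sub, strategy)
  cts <- confusion(dec, sub$endpoint)
  ss <- sens_spec(cts, level)
  pv <- predictive_values(cts)
  structure(
    list(strategy = strategy$label, subgroup = subgroup, n = nrow(sub),
         counts = cts, sensitivity = ss$sensitivity,
         specificity = ss$specificity, ppv = pv$ppv, npv = pv$npv,
         surveillance_fraction = pv$surveillance_fraction),
    class = "um_diagnostic_summary"
  )
}

#' @export
print.um_diagnostic_summary <- function(x, ...) {
  cat(sprintf("%s [%s, n=%d]\n", x$strategy, x$subgroup, x$n))
  cat(sprintf("  sensitivity %d%% (%d-%d)  specificity %d%% (%d-%d)\n",
              percent_round(x$sensitivity$estimate),
              percent_round(x$sensitivity$lower),
              percent_round(x$sensitivity$upper),
              percent_round(x$specificity$estimate),
              percent_round(x$specificity$lower),
              percent_round(x$specificity$upper)))
  cat(sprintf("  PPV %d%%  NPV %d%%  surveillance %d%%\n",
              percent_round(x$ppv), percent_round(x$npv),
              percent_round(x$surveillance_fraction)))
  invisible(x)
}

#' Summarise several strategies as a report table
#'
#' One row per strategy x subgroup, in the layout of a published
#' strategy-comparison table: whole-percent sensitivity and specificity with
#' exact confidence intervals, PPV, NPV and the surveillance fraction.
#'
#' @param cohort A cohort data frame.
#' @param strategies A list of `um_strategy` objects.
#' @param subgroups Character vector of subgroups to evaluate.
#' @param level Confidence level.
#' @return A data frame with character-formatted percentage columns.
#' @export
strategy_summary_table <- function(cohort, strategies,
                                   subgroups = "all", level = 0.95) {
  rows <- list()
  for (st in strategies) {
    for (sg in subgroups) {
      s <- evaluate_strategy(cohort, st, sg, level)
      rows[[length(rows) + 1L]] <- data.frame(
        system = s$strategy,
        subgroup = s$subgroup,
        n = s$n,
        sensitivity = sprintf("%d%% (%d-%d)",
                              percent_round(s$sensitivity$estimate),
                              percent_round(s$sensitivity$lower),
                              percent_round(s$sensitivity$upper)),
        specificity = sprintf("%d%% (%d-%d)",
                              percent_round(s$specificity$estimate),
                              percent_round(s$specificity$lower),
                              percent_round(s$specificity$upper)),
        ppv = sprintf("%d%%", percent_round(s$ppv)),
        npv = sprintf("%d%%", percent_round(s$npv)),
        surveillance = sprintf("%d%%", percent_round(s$surveillance_fraction)),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Matched-sensitivity comparison of the continuous score against the
#' stage rule
#'
#' Reproduces, on one cohort, the comparison at the heart of the analysis:
#' can thresholding the continuous metastasis-risk score detect the same
#' cases as the ordinal-stage rule while enrolling fewer endpoint-negative
#' patients? Within each chromosome-3 subgroup the score channel available
#' there (`mam5_full` for tested patients, `mam5_nochr3` for untested) is
#' thresholded at the largest value attaining the stage rule's sensitivity
#' in that subgroup -- the dual-threshold decision algorithm -- and the
#' pooled specificity is compared with the stage rule's.
#'
#' @param cohort A cohort data frame.
#' @param stage_cut Stage threshold defining the comparator rule.
#' @return List with `stage_sensitivity`, `stage_specificity`,
#'   `score_sensitivity`, `score_specificity`, the two chosen thresholds
#'   (`threshold_known`, `threshold_unknown`), and logical `dominates`
#'   (score specificity strictly greater at matched sensitivity).
#' @export
matched_sensitivity_comparison <- function(cohort, stage_cut = "IIA") {
  stage_all <- evaluate_strategy(cohort, strategy_stage_threshold(stage_cut))
  stage_k <- evaluate_strategy(cohort, strategy_stage_threshold(stage_cut),
                               "chr3_known")
  stage_u <- evaluate_strategy(cohort, strategy_stage_threshold(stage_cut),
                               "chr3_unknown")
  known <- cohort$chr3_status != "unknown"
  tk <- threshold_for_sensitivity(cohort[known, , drop = FALSE], "mam5_full",
                                  stage_k$sensitivity$estimate)
  tu <- threshold_for_sensitivity(cohort[!known, , drop = FALSE],
                                  "mam5_nochr3",
                                  stage_u$sensitivity$estimate)
  dec <- stratify_dual_threshold(cohort, "mam5_full", "mam5_nochr3",
                                 tk$threshold, tu$threshold)
  ss <- sens_spec(confusion(dec, cohort$endpoint))
  list(stage_sensitivity = stage_all$sensitivity$estimate,
       stage_specificity = stage_all$specificity$estimate,
       score_sensitivity = ss$sensitivity$estimate,
       score_specificity = ss$specificity$estimate,
       threshold_known = tk$threshold,
       threshold_unknown = tu$threshold,
       dominates = ss$specificity$estimate > stage_all$specificity$estimate)
}

#' Largest threshold attaining a target sensitivity
#'
#' Scans the distinct observed scores as inclusive thresholds and returns
#' the largest one whose sensitivity is at least `target`. Because
#' sensitivity decreases and specificity increases as the threshold rises,
#' this is also the threshold with maximal specificity among those meeting
#' the target -- the basis of matched-sensitivity comparisons between a
#' continuous score and a coarser rule.
#'
#' @param cohort A cohort data frame.
#' @param score_field Name of the score column.
#' @param target Target sensitivity in (0, 1\].
#' @return List with `threshold`, the achieved `sensitivity` and
#'   `specificity` at that threshold, and a logical `degenerate` flag set
#'   when every endpoint-positive score is 0 (threshold 0 returned).
#' @export
threshold_for_sensitivity <- function(cohort, score_field, target) {
  if (target <= 0 || target > 1) stop("`target` must be in (0, 1]")
  scores <- cohort[[score_field]]
  if (is.null(scores)) stop("unknown score field '", score_field, "'")
  y <- as.logical(cohort$endpoint)
  pos <- scores[y]
  neg <- scores[!y]
  if (length(pos) == 0) stop("no endpoint-positive patients")
  cand <- sort(unique(scores), decreasing = TRUE)
  sens <- vapply(cand, function(t) mean(pos >= t), numeric(1))
  ok <- which(sens >= target)
  if (length(ok) == 0 || max(pos) == 0) {
    # all positives score 0: only threshold 0 captures them
    return(list(threshold = 0, sensitivity = mean(pos >= 0),
                specificity = mean(neg < 0), degenerate = TRUE))
  }
  t <- cand[ok[1]]
  list(threshold = t, sensitivity = mean(pos >= t),
       specificity = mean(neg < t), degenerate = FALSE)
}
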