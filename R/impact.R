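# round half away from zero; report tables round to the nearest whole number
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Health-economic impact scenario
#'
#' Fixes the population scenario used to translate a strategy's sensitivity
#' and specificity into expected patient counts, liver-scan totals and
#' imaging costs. Defaults describe a typical ocular oncology centre year:
#' 200 uveal-melanoma patients, a 28% 5-year endpoint incidence, 6-monthly
#' surveillance for 5 years in which a false positive receives 10 scans, a
#' true positive 3 scans (surveillance stops at detection) and negatives
#' none, with 2020/21 NHS England unit costs for a non-contrast liver MRI
#' (GBP 211.24) and a 20-minute-plus outpatient ultrasound (GBP 135.09).
#'
#' @param population Number of patients in the scenario.
#' @param incidence 5-year endpoint incidence in the population.
#' @param scans_per_fp,scans_per_tp,scans_per_negative Scans received over
#'   the horizon by false positives, true positives, and (true or false)
#'   negatives.
#' @param unit_cost_mri,unit_cost_us Cost per scan in GBP by modality.
#' @param horizon_years Surveillance horizon.
#' @return An object of class `um_scenario`.
#' @export
impact_scenario <- function(population = 200, incidence = 0.28,
                            scans_per_fp = 10, scans_per_tp = 3,
                            scans_per_negative = 0,
                            unit_cost_mri = 211.24, unit_cost_us = 135.09,
                            horizon_years = 5) {
  if (population < 1) stop("`population` must be >= 1")
  if (incidence < 0 || incidence > 1) stop("`incidence` must be in [0, 1]")
  if (any(c(scans_per_fp, scans_per_tp, scans_per_negative) < 0) ||
      any(c(unit_cost_mri, unit_cost_us) < 0)) {
    stop("scan counts and unit costs must be non-negative")
  }
  structure(
    list(population = population, incidence = incidence,
         scans_per_fp = scans_per_fp, scans_per_tp = scans_per_tp,
         scans_per_negative = scans_per_negative,
         unit_cost_mri = unit_cost_mri, unit_cost_us = unit_cost_us,
         horizon_years = horizon_years),
    class = "um_scenario"
  )
}

#' Expected confusion counts for a population scenario
#'
#' Total positives = population x incidence; total negatives the remainder.
#' TP = positives x sensitivity, FN = positives x (1 - sensitivity),
#' TN = negatives x specificity, FP = negatives x (1 - specificity), each
#' rounded to the nearest whole patient. If rounding breaks the population
#' total, the cell with the largest rounding remainder is adjusted and the
#' result flagged via `attr(, "rounding_adjusted")`.
#'
#' @param scenario An `um_scenario`.
#' @param sensitivity,specificity Strategy operating characteristics in
#'   \[0, 1\].
#' @return An `um_confusion` object whose counts sum to the population.
#' @examples
#' expected_counts(impact_scenario(), 0.95, 0.51)
#' @export
expected_counts <- function(scenario, sensitivity, specificity) {
  stopifnot(inherits(scenario, "um_scenario"))
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1) {
    stop("sensitivity and specificity must be in [0, 1]")
  }
  total_pos <- scenario$population * scenario$incidence
  total_neg <- scenario$population - total_pos
  exact <- c(tp = total_pos * sensitivity,
             fn = total_pos * (1 - sensitivity),
             fp = total_neg * (1 - specificity),
             tn = total_neg * specificity)
  rounded <- round_half_up(exact)
  adjusted <- FALSE
  short <- scenario$population - sum(rounded)
  if (short != 0) {
    rem <- exact - floor(exact)
    i <- if (short > 0) which.max(rem) else which.min(rem)
    rounded[i] <- rounded[i] + short
    adjusted <- TRUE
  }
  out <- structure(as.list(as.integer(rounded)), class = "um_confusion")
  names(out) <- names(exact)
  attr(out, "rounding_adjusted") <- adjusted
  out
}

#' Scan totals and imaging costs for a set of counts
#'
#' Scans follow the scenario schedule (`scans_per_fp * FP +
#' scans_per_tp * TP + scans_per_negative * (FN + TN)`); costs are the scan
#' total times the unit cost, truncated to whole pounds.
#'
#' @param scenario An `um_scenario`.
#' @param counts An `um_confusion` object (e.g. from [expected_counts()]).
#' @param strategy Optional label carried into the report.
#' @return An object of class `um_impact`: counts, `scans_total`,
#'   `cost_mri`, `cost_us`, `strategy`.
#' @export
scans_and_costs <- function(scenario, counts, strategy = NA_character_) {
  stopifnot(inherits(scenario, "um_scenario"), inherits(counts, "um_confusion"))
  scans <- scenario$scans_per_fp * counts$fp +
    scenario$scans_per_tp * counts$tp +
    scenario$scans_per_negative * (counts$fn + counts$tn)
  structure(
    list(counts = counts, scans_total = scans,
         cost_mri = floor(scans * scenario$unit_cost_mri),
         cost_us = floor(scans * scenario$unit_cost_us),
         strategy = strategy),
    class = "um_impact"
  )
}

#' @export
print.um_impact <- function(x, ...) {
  cat(sprintf("impact%s: tp %d, fn %d, fp %d, tn %d; %d scans; GBP %s (MRI) / %s (US)\n",
              if (is.na(x$strategy)) "" else paste0(" [", x$strategy, "]"),
              x$counts$tp, x$counts$fn, x$counts$fp, x$counts$tn,
              x$scans_total, format(x$cost_mri, big.mark = ","),
              format(x$cost_us, big.mark = ",")))
  invisible(x)
}

#' Compare the impact of two strategies
#'
#' Computes expected counts for each strategy (rounding each strategy's
#' cells to whole patients first, then differencing), the number of false
#' positives avoided by strategy `a` relative to `b`, the scans thereby
#' avoided, and the cost savings by modality (truncated to whole pounds).
#' When the two sensitivities are equal the false-negative difference is 0
#' and every avoided scan is a false-positive surveillance scan; when they
#' differ, `scans_avoided` still counts only false-positive scans and the
#' additional missed cases are reported separately as `extra_fn` (flagged
#' via `sensitivities_differ`).
#'
#' @param scenario An `um_scenario`.
#' @param a,b Each a numeric vector or list with elements `sensitivity` and
#'   `specificity`; `a` is the proposed strategy, `b` the comparator.
#' @return An object of class `um_impact_delta`: `fp_avoided`,
#'   `scans_avoided`, `saving_mri`, `saving_us`, `extra_fn`,
#'   `sensitivities_differ`, plus the per-strategy `um_impact` reports.
#' @examples
#' compare_strategies(impact_scenario(),
#'                    a = c(sensitivity = 0.95, specificity = 0.51),
#'                    b = c(sensitivity = 0.95, specificity = 0.38))
#' @export
compare_strategies <- function(scenario, a, b) {
  a <- as.list(a); b <- as.list(b)
  ca <- expected_counts(scenario, a$sensitivity, a$specificity)
  cb <- expected_counts(scenario, b$sensitivity, b$specificity)
  fp_avoided <- cb$fp - ca$fp
  scans_avoided <- fp_avoided * scenario$scans_per_fp
  structure(
    list(fp_avoided = fp_avoided,
         scans_avoided = scans_avoided,
         saving_mri = sign(scans_avoided) *
           floor(abs(scans_avoided) * scenario$unit_cost_mri),
         saving_us = sign(scans_avoided) *
           floor(abs(scans_avoided) * scenario$unit_cost_us),
         extra_fn = ca$fn - cb$fn,
         sensitivities_differ = !isTRUE(all.equal(a$sensitivity, b$sensitivity)),
         impact_a = scans_and_costs(scenario, ca),
         impact_b = scans_and_costs(scenario, cb)),
    class = "um_impact_delta"
  )
}

#' @export
print.um_impact_delta <- function(x, ...) {
  cat(sprintf("%d false positives avoided -> %d scans avoided; savings GBP %s (MRI) / %s (US)\n",
              x$fp_avoided, x$scans_avoided,
              format(x$saving_mri, big.mark = ","),
              format(x$saving_us, big.mark = ",")))
  if (x$sensitivities_differ) {
    cat(sprintf("sensitivities differ: %+d additional missed cases (extra_fn); scan delta counts false-positive scans only\n",
                x$extra_fn))
  }
  invisible(x)
}

#' Impact table for several strategies
#'
#' One row per (sensitivity, specificity) pair: expected counts, scan total
#' and costs under the scenario.
#'
#' @param scenario An `um_scenario`.
#' @param strategies Named list; each element a vector/list with
#'   `sensitivity` and `specificity`.
#' @return A data frame.
#' @export
impact_table <- function(scenario, strategies) {
  rows <- lapply(names(strategies), function(nm) {
    st <- as.list(strategies[[nm]])
    rep <- scans_and_costs(scenario,
                           expected_counts(scenario, st$sensitivity,
                                           st$specificity),
                           strategy = nm)
    data.frame(system = nm,
               sensitivity = sprintf("%d%%", percent_round(st$sensitivity)),
               specificity = sprintf("%d%%", percent_round(st$specificity)),
               tp = rep$counts$tp, fn = rep$counts$fn,
               fp = rep$counts$fp, tn = rep$counts$tn,
               total = rep$counts$tp + rep$counts$fn + rep$counts$fp +
                 rep$counts$tn,
               scans = rep$scans_total,
               cost_mri = rep$cost_mri, cost_us = rep$cost_us,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
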