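# tiny polynomial hash over a string; enough to fingerprint a config in the
# run log (not cryptographic)
config_fingerprint <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Build a stratification strategy from a tagged list
#'
#' Converts a plain list (e.g. parsed from a YAML strategy table) with a
#' `kind` tag into an `um_strategy`. Recognised kinds:
#' `score_threshold`, `dual_threshold`, `stage_threshold`, `monosomy3`.
#'
#' @param x A list with element `kind` plus the fields that kind requires.
#' @return An `um_strategy`.
#' @export
strategy_from_list <- function(x) {
  if (is.null(x$kind)) stop("strategy list needs a `kind` tag")
  lbl <- x$label
  switch(x$kind,
    score_threshold = strategy_score_threshold(x$score_field, x$threshold, lbl),
    dual_threshold = strategy_dual_threshold(
      x$t_known, x$t_unknown,
      x$score_field_known %||% "mam5_full",
      x$score_field_unknown %||% "mam5_nochr3", lbl),
    stage_threshold = strategy_stage_threshold(x$stage_cut, lbl),
    monosomy3 = strategy_monosomy3(lbl %||% "Monosomy 3"),
    stop("unknown strategy kind '", x$kind, "'")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default strategy set
#'
#' The four surveillance systems compared throughout the package: the
#' full-information continuous score at a single threshold (0.05), the
#' chromosome-3-dependent dual-threshold rule (0.07 for tested patients,
#' 0.045 for untested), ordinal stage at IIA and above, and monosomy 3
#' (untested patients also enrolled).
#'
#' @return A named list of `um_strategy` objects.
#' @export
default_strategies <- function() {
  list(
    score_0.05 = strategy_score_threshold("mam5_full", 0.05,
                                          "MAM >= 0.05"),
    dual_0.07_0.045 = strategy_dual_threshold(0.07, 0.045),
    stage_IIA = strategy_stage_threshold("IIA"),
    monosomy3 = strategy_monosomy3()
  )
}

#' Configuration of a full pipeline run
#'
#' @param generator An `um_config` (a cohort is generated), or a path to an
#'   existing cohort CSV.
#' @param strategies Named list of `um_strategy` objects; score-based
#'   strategies are additionally evaluated within the chromosome-3
#'   subgroups.
#' @param scenario An `um_scenario` for the impact analysis.
#' @param impact_strategies Named list of `c(sensitivity=, specificity=)`
#'   pairs for the impact table; the first entry is compared against each
#'   later entry in the delta report.
#' @param comparisons List of score-channel pairs (each
#'   `c(field_a, field_b)`) compared with the DeLong paired test on the full
#'   cohort; the Holm family is the set of comparisons run.
#' @param out_dir Output directory, created if needed.
#' @param level Confidence level used throughout.
#' @return An object of class `um_run_config`.
#' @export
run_config <- function(generator = cohort_config(),
                       strategies = default_strategies(),
                       scenario = impact_scenario(),
                       impact_strategies = list(
                         LUMPOIII = c(sensitivity = 0.95, specificity = 0.51),
                         AJCC = c(sensitivity = 0.95, specificity = 0.38)),
                       comparisons = list(c("mam5_full", "mam5_nochr3"),
                                          c("mam5_full", "mam5_nogenetics")),
                       out_dir = "results",
                       level = 0.95) {
  stopifnot(inherits(generator, "um_config") || is.character(generator),
            inherits(scenario, "um_scenario"))
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)")
  for (st in strategies) stopifnot(inherits(st, "um_strategy"))
  structure(
    list(generator = generator, strategies = strategies, scenario = scenario,
         impact_strategies = impact_strategies, comparisons = comparisons,
         out_dir = out_dir, level = level),
    class = "um_run_config"
  )
}

#' Run the full comparison pipeline
#'
#' Generates (or reads) a cohort, evaluates every configured strategy on the
#' whole cohort -- and, for strategies that use the continuous scores, within
#' the chromosome-3 known/unknown subgroups -- computes ROC curves, AUCs and
#' DeLong paired comparisons across the configured score channels with Holm
#' adjustment over that family, computes the impact table and strategy
#' deltas, and writes everything to `out_dir` as CSV plus a plain-text run
#' log. All CSV outputs are deterministic functions of the configuration
#' (byte-identical across runs with the same seed); the log carries
#' wall-clock timestamps.
#'
#' @param config An `um_run_config`.
#' @return Invisibly, a list with the cohort, the summary data frame, the
#'   ROC objects, the DeLong results, the impact table and delta reports,
#'   and the paths written.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "um_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  log_lines <- character()
  say <- function(...) {
    line <- sprintf("%s %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                    sprintf(...))
    log_lines <<- c(log_lines, line)
  }
  stage_wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # cohort
  cohort <- stage_wrap("cohort", {
    if (is.character(config$generator)) {
      say("reading cohort from %s", config$generator)
      read_cohort(config$generator)
    } else {
      say("generating cohort: n=%d seed=%d config=%s",
          config$generator$n_patients, config$generator$seed,
          config_fingerprint(paste(deparse(unclass(config$generator)),
                                   collapse = "")))
      generate_cohort(config$generator)
    }
  })
  paths <- c(cohort = file.path(config$out_dir, "cohort.csv"))
  write_cohort(cohort, paths[["cohort"]])

  # strategy summaries: every strategy on "all"; score-based ones by subgroup
  summary_df <- stage_wrap("evaluate", {
    rows <- list()
    for (nm in names(config$strategies)) {
      st <- config$strategies[[nm]]
      subgroups <- if (st$kind %in% c("score_threshold", "dual_threshold")) {
        c("all", "chr3_known", "chr3_unknown")
      } else "all"
      rows[[nm]] <- strategy_summary_table(cohort, list(st), subgroups,
                                           config$level)
    }
    do.call(rbind, c(rows, make.row.names = FALSE))
  })
  paths["summary"] <- file.path(config$out_dir, "strategy_summary.csv")
  utils::write.csv(summary_df, paths[["summary"]], row.names = FALSE)
  say("evaluated %d strategy x subgroup combinations", nrow(summary_df))

  # ROC + DeLong family with Holm adjustment
  rocs <- list()
  delong_df <- stage_wrap("roc", {
    fields <- unique(unlist(config$comparisons))
    for (f in fields) {
      rocs[[f]] <- empirical_roc(cohort[[f]], cohort$endpoint, config$level)
      pts_path <- file.path(config$out_dir, sprintf("roc_%s.csv", f))
      utils::write.csv(rocs[[f]]$points, pts_path, row.names = FALSE)
      paths[sprintf("roc_%s", f)] <- pts_path
    }
    tests <- lapply(config$comparisons, function(cp) {
      delong_paired(cohort[[cp[1]]], cohort[[cp[2]]], cohort$endpoint)
    })
    p_adj <- holm_adjust(vapply(tests, `[[`, numeric(1), "p_value"))
    say("Holm family: %d DeLong comparisons (%s)", length(tests),
        paste(vapply(config$comparisons, paste, character(1),
                     collapse = " vs "), collapse = "; "))
    data.frame(
      score_a = vapply(config$comparisons, `[`, character(1), 1),
      score_b = vapply(config$comparisons, `[`, character(1), 2),
      auc_a = vapply(tests, `[[`, numeric(1), "auc_a"),
      auc_b = vapply(tests, `[[`, numeric(1), "auc_b"),
      statistic = vapply(tests, `[[`, numeric(1), "statistic"),
      p_raw = vapply(tests, `[[`, numeric(1), "p_value"),
      p_adjusted = p_adj,
      stringsAsFactors = FALSE
    )
  })
  paths["delong"] <- file.path(config$out_dir, "delong_comparisons.csv")
  utils::write.csv(delong_df, paths[["delong"]], row.names = FALSE)

  # impact table and deltas against the first (reference) strategy
  impact_df <- stage_wrap("impact", {
    impact_table(config$scenario, config$impact_strategies)
  })
  paths["impact"] <- file.path(config$out_dir, "impact.csv")
  utils::write.csv(impact_df, paths[["impact"]], row.names = FALSE)
  deltas <- stage_wrap("impact", {
    nms <- names(config$impact_strategies)
    if (length(nms) < 2) {
      list()
    } else {
      out <- lapply(nms[-1], function(nm) {
        d <- compare_strategies(config$scenario,
                                a = config$impact_strategies[[nms[1]]],
                                b = config$impact_strategies[[nm]])
        data.frame(reference = nms[1], comparator = nm,
                   fp_avoided = d$fp_avoided, scans_avoided = d$scans_avoided,
                   saving_mri = d$saving_mri, saving_us = d$saving_us,
                   extra_fn = d$extra_fn,
                   sensitivities_differ = d$sensitivities_differ,
                   stringsAsFactors = FALSE)
      })
      out
    }
  })
  if (length(deltas)) {
    delta_df <- do.call(rbind, deltas)
    paths["impact_delta"] <- file.path(config$out_dir, "impact_delta.csv")
    utils::write.csv(delta_df, paths[["impact_delta"]], row.names = FALSE)
  } else {
    delta_df <- NULL
  }

  if (inherits(config$generator, "um_config")) {
    paths["config"] <- file.path(config$out_dir, "generator_config.yaml")
    write_cohort_config(config$generator, paths[["config"]])
  }
  say("wrote %d output files to %s", length(paths), config$out_dir)
  writeLines(log_lines, logf)
  invisible(list(cohort = cohort, summary = summary_df, rocs = rocs,
                 delong = delong_df, impact = impact_df, deltas = delta_df,
                 paths = paths, log = logf))
}
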