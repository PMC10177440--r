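test_that("confusion counts match hand counts and a loop oracle", {
  cts <- confusion(c(TRUE, TRUE, FALSE, FALSE), c(1, 0, 1, 0))
  expect_equal(unclass(cts)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))

  all_high <- confusion(rep(TRUE, 6), c(1, 1, 0, 0, 1, 0))
  expect_equal(all_high$fn, 0L)
  expect_equal(all_high$tn, 0L)

  set.seed(31)
  d <- runif(50) < 0.5
  y <- runif(50) < 0.4
  expect_equal(unclass(confusion(d, y))[c("tp", "fp", "fn", "tn")],
               confusion_loop_oracle(d, y)[c("tp", "fp", "fn", "tn")],
               ignore_attr = TRUE)

  expect_error(confusion(c(TRUE, FALSE), c(1, 0, 1)), "lengths")
})

test_that("Clopper-Pearson interval matches the binomial-tail bisection oracle", {
  cases <- list(c(95, 100), c(53, 56), c(1, 20), c(10, 10), c(0, 15),
                c(292, 1047))
  for (cs in cases) {
    ci <- clopper_pearson(cs[1], cs[2])
    or <- cp_bisection_oracle(cs[1], cs[2])
    expect_equal(ci$lower, or[["lower"]], tolerance = 1e-9)
    expect_equal(ci$upper, or[["upper"]], tolerance = 1e-9)
    expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
  }
  expect_equal(clopper_pearson(10, 10)$upper, 1)
  expect_equal(clopper_pearson(0, 10)$lower, 0)
  # agreement with the stats::binom.test inversion
  bt <- stats::binom.test(53, 56)$conf.int
  ci <- clopper_pearson(53, 56)
  expect_equal(c(ci$lower, ci$upper), as.numeric(bt), tolerance = 1e-12)
})

test_that("exact intervals reach nominal coverage in simulation", {
  set.seed(61)
  reps <- 5000
  for (p in c(0.05, 0.5, 0.9)) {
    k <- stats::rbinom(reps, 50, p)
    bounds <- vapply(k, function(ki) {
      ci <- clopper_pearson(ki, 50)
      c(ci$lower, ci$upper)
    }, numeric(2))
    cover <- mean(bounds[1, ] <= p & p <= bounds[2, ])
    # exactness: coverage >= nominal, allow 3 MC standard errors below
    expect_gte(cover, 0.95 - 3 * sqrt(0.95 * 0.05 / reps))
  }
})

test_that("sensitivity and specificity follow their defining ratios", {
  cts <- confusion(c(TRUE, TRUE, TRUE, FALSE, FALSE),
                   c(1, 1, 0, 1, 0))
  ss <- sens_spec(cts)
  expect_equal(ss$sensitivity$estimate, 2 / 3)
  expect_equal(ss$specificity$estimate, 1 / 2)
  # tp = 53, fn = 3 as in a 200-patient scenario at 95% sensitivity
  cts2 <- structure(list(tp = 53L, fp = 71L, fn = 3L, tn = 73L),
                    class = "um_confusion")
  expect_equal(sens_spec(cts2)$sensitivity$estimate, 53 / 56,
               tolerance = 1e-12)

  one_class <- confusion(c(TRUE, FALSE), c(1, 1))
  expect_error(sens_spec(one_class), "specificity undefined")
})

test_that("scenario-mode predictive values equal a large-n count computation", {
  pi0 <- 292 / 1047
  pv <- predictive_values(sensitivity = 0.95, specificity = 0.37,
                          prevalence = pi0)
  n <- 1e6
  tp <- n * pi0 * 0.95
  fn <- n * pi0 * 0.05
  tn <- n * (1 - pi0) * 0.37
  fp <- n * (1 - pi0) * 0.63
  expect_equal(pv$ppv, tp / (tp + fp), tolerance = 1e-12)
  expect_equal(pv$npv, tn / (tn + fn), tolerance = 1e-12)
  expect_equal(pv$surveillance_fraction, (tp + fp) / n, tolerance = 1e-12)
})

test_that("counts-mode and scenario-mode predictive values agree", {
  cts <- confusion(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                   c(1, 1, 0, 0, 0, 1))
  pv <- predictive_values(cts)
  ss <- sens_spec(cts)
  pv2 <- predictive_values(sensitivity = ss$sensitivity$estimate,
                           specificity = ss$specificity$estimate,
                           prevalence = 3 / 6)
  expect_equal(pv$ppv, pv2$ppv, tolerance = 1e-12)
  expect_equal(pv$npv, pv2$npv, tolerance = 1e-12)

  perfect <- predictive_values(sensitivity = 1, specificity = 1,
                               prevalence = 0.3)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)
  expect_equal(perfect$surveillance_fraction, 0.3)
})

test_that("subgroup evaluation equals evaluating the filtered cohort", {
  coh <- generate_cohort(cohort_config(n_patients = 700, seed = 13))
  st <- strategy_score_threshold("mam5_full", 0.1)
  sub <- evaluate_strategy(coh, st, "chr3_unknown")
  manual <- evaluate_strategy(coh[coh$chr3_status == "unknown", ], st, "all")
  expect_equal(sub$sensitivity$estimate, manual$sensitivity$estimate)
  expect_equal(sub$specificity$estimate, manual$specificity$estimate)
  expect_equal(sub$counts, manual$counts)
  expect_equal(sub$n, manual$n)
})

test_that("a separable fixture scores perfectly", {
  coh <- make_fixture_cohort(20, seed = 6)
  coh$endpoint <- coh$mam5_full > 0.5
  st <- strategy_score_threshold("mam5_full", 0.5)
  s <- evaluate_strategy(coh, st)
  expect_equal(s$sensitivity$estimate, 1)
  expect_equal(s$specificity$estimate, 1)
  expect_equal(s$ppv, 1)
  expect_equal(s$npv, 1)
})

test_that("threshold search meets the target with maximal specificity", {
  coh <- make_fixture_cohort(150, seed = 23)
  # exhaustive-scan oracle over the distinct observed scores
  target <- 0.9
  res <- threshold_for_sensitivity(coh, "mam5_full", target)
  pos <- coh$mam5_full[coh$endpoint]
  cand <- sort(unique(coh$mam5_full), decreasing = TRUE)
  ok <- cand[vapply(cand, function(t) mean(pos >= t) >= target, logical(1))]
  expect_equal(res$threshold, max(ok))
  expect_gte(res$sensitivity, target)
  larger <- cand[cand > res$threshold]
  if (length(larger)) {
    expect_lt(mean(pos >= min(larger)), target)
  }

  # separable fixture at target 1: threshold is the lowest positive score
  sep <- make_fixture_cohort(20, seed = 6)
  sep$endpoint <- sep$mam5_full > 0.5
  r1 <- threshold_for_sensitivity(sep, "mam5_full", 1)
  expect_equal(r1$threshold, min(sep$mam5_full[sep$endpoint]))

  # lowering the target never lowers the threshold
  prev <- -Inf
  for (tg in c(0.99, 0.9, 0.8, 0.5, 0.2)) {
    cur <- threshold_for_sensitivity(coh, "mam5_full", tg)$threshold
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("score beats stage specificity at matched sensitivity in expectation", {
  reps <- 30
  gap_single <- gap_dual <- numeric(reps)
  for (i in seq_len(reps)) {
    coh <- generate_cohort(cohort_config(seed = 7000 + i))
    stage_eval <- evaluate_strategy(coh, strategy_stage_threshold("IIA"))
    thr <- threshold_for_sensitivity(coh, "mam5_full",
                                     stage_eval$sensitivity$estimate)
    gap_single[i] <- thr$specificity - stage_eval$specificity$estimate
    gap_dual[i] <- with(matched_sensitivity_comparison(coh),
                        score_specificity - stage_specificity)
  }
  # one-sided: mean specificity gain is positive for both formulations
  expect_gt(mean(gap_single) / (stats::sd(gap_single) / sqrt(reps)), 3)
  expect_gt(mean(gap_dual) / (stats::sd(gap_dual) / sqrt(reps)), 3)
})

test_that("summary tables carry one row per strategy and subgroup", {
  coh <- generate_cohort(cohort_config(n_patients = 600, seed = 3))
  tab <- strategy_summary_table(
    coh, list(strategy_score_threshold("mam5_full", 0.05),
              strategy_monosomy3()),
    subgroups = "all")
  expect_equal(nrow(tab), 2)
  expect_true(all(grepl("^\\d+%", tab$sensitivity)))
  expect_named(tab, c("system", "subgroup", "n", "sensitivity", "specificity",
                      "ppv", "npv", "surveillance"))
})

test_that("percent rounding rounds halves up as in report tables", {
  expect_equal(percent_round(0.375), 38L)  # 37.5 rounds up, not to even
  expect_equal(percent_round(0.625), 63L)
  expect_equal(percent_round(292 / 1047), 28L)
})
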