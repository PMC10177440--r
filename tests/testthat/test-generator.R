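test_that("generated cohorts satisfy their structural invariants", {
  cfg <- cohort_config(n_patients = 800, seed = 7)
  coh <- generate_cohort(cfg)

  expect_s3_class(coh, "um_cohort")
  expect_equal(nrow(coh), 800)
  expect_false(any(duplicated(coh$patient_id)))
  expect_true(all(coh$mam5_full >= 0 & coh$mam5_full <= 1))
  expect_true(all(coh$mam5_nochr3 >= 0 & coh$mam5_nochr3 <= 1))
  expect_true(all(coh$mam5_nogenetics >= 0 & coh$mam5_nogenetics <= 1))
  expect_true(all(coh$stage %in% stage_levels))
  expect_true(all(coh$chr3_status %in% c("monosomy", "disomy", "unknown")))

  # untested patients carry the degraded score in both columns, and only they
  unk <- coh$chr3_status == "unknown"
  expect_identical(coh$mam5_full[unk], coh$mam5_nochr3[unk])
  expect_true(all(coh$mam5_full[!unk] != coh$mam5_nochr3[!unk]))

  # subgroup sizes partition the cohort
  expect_equal(sum(unk) + sum(!unk), nrow(coh))
})

test_that("perfect calibration separates endpoint classes on every cohort", {
  for (seed in 1:5) {
    coh <- generate_cohort(cohort_config(n_patients = 600, seed = seed))
    expect_gt(mean(coh$mam5_full[coh$endpoint]),
              mean(coh$mam5_full[!coh$endpoint]))
  }
})

test_that("subgroup endpoint rates track their targets over replicates", {
  reps <- 40
  rk <- ru <- numeric(reps)
  for (i in seq_len(reps)) {
    coh <- generate_cohort(cohort_config(seed = 1000 + i))
    known <- coh$chr3_status != "unknown"
    rk[i] <- mean(coh$endpoint[known])
    ru[i] <- mean(coh$endpoint[!known])
  }
  # mean within 3 Monte-Carlo standard errors of target
  expect_lt(abs(mean(rk) - 0.34), 3 * stats::sd(rk) / sqrt(reps))
  expect_lt(abs(mean(ru) - 0.14), 3 * stats::sd(ru) / sqrt(reps))
})

test_that("masking genetic inputs degrades discrimination in expectation", {
  reps <- 30
  d <- numeric(reps)
  for (i in seq_len(reps)) {
    coh <- generate_cohort(cohort_config(n_patients = 600, seed = 2000 + i))
    d[i] <- empirical_roc(coh$mam5_full, coh$endpoint)$auc -
      empirical_roc(coh$mam5_nogenetics, coh$endpoint)$auc
  }
  expect_gt(mean(d) / (stats::sd(d) / sqrt(reps)), 3)  # one-sided t
})

test_that("zero degradation noise reproduces the full score exactly", {
  coh <- generate_cohort(cohort_config(n_patients = 300, noise_nochr3 = 0,
                                       seed = 3))
  expect_identical(coh$mam5_nochr3, coh$mam5_full)
})

test_that("identical config and seed give byte-identical cohort CSVs", {
  cfg <- cohort_config(n_patients = 250, seed = 11)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_cohort(generate_cohort(cfg), f1)
  write_cohort(generate_cohort(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(42)
  before <- runif(3)
  set.seed(42)
  invisible(generate_cohort(cohort_config(n_patients = 50, seed = 9)))
  expect_identical(runif(3), before)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(frac_chr3_known = 1.2), "proportions")
  expect_error(cohort_config(stage_cutpoints = c(0.5, 0.4, 0.6, 0.7, 0.8)),
               "increasing")
  expect_error(cohort_config(noise_nochr3 = -1), "dispersions")
  expect_error(cohort_config(incidence_known = 0.5), "mixture mean")
  bad_mix <- list(known = list(weights = c(0.6, 0.6),
                               shape1 = c(1, 2), shape2 = c(3, 4)),
                  unknown = list(weights = c(0.75, 0.25),
                                 shape1 = c(0.4, 2.05),
                                 shape2 = c(7.6, 2.95)))
  expect_error(cohort_config(latent_mixture = bad_mix), "sum to 1")
})

test_that("distribution summaries conserve counts and keep stage order", {
  coh <- generate_cohort(cohort_config(seed = 5))
  h <- summarize_distribution(coh, "mam5_full", bins = 10)
  expect_equal(sum(h$count), nrow(coh))
  st <- summarize_distribution(coh, "stage")
  expect_identical(st$stage, stage_levels)
  expect_equal(sum(st$count), nrow(coh))
  # the generated population is skewed to the low stages
  expect_true(which.max(st$count) %in% 1:2)
  expect_error(summarize_distribution(coh, "nonesuch"), "unknown field")
})

test_that("three-score hand fixture bins as counted by hand", {
  coh <- make_fixture_cohort(3)
  coh$mam5_full <- c(0.1, 0.1, 0.9)
  h <- summarize_distribution(coh, "mam5_full", bins = 2)
  expect_equal(h$count, c(2L, 1L))
})
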