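test_that("ROC handles perfect separation and ties-only input", {
  perfect <- empirical_roc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$points$fpr[1], 0)
  expect_equal(perfect$points$tpr[1], 0)
  expect_equal(utils::tail(perfect$points$fpr, 1), 1)
  expect_equal(utils::tail(perfect$points$tpr, 1), 1)

  ties <- empirical_roc(rep(0.4, 10), c(rep(1, 4), rep(0, 6)))
  expect_equal(ties$auc, 0.5)

  expect_error(empirical_roc(c(0.1, 0.2), c(1, 1)), "positive and one negative")
})

test_that("trapezoid AUC equals brute-force pair counting on random fixtures", {
  set.seed(71)
  for (rep in 1:5) {
    n <- 30
    scores <- round(runif(n), 2)  # coarse grid forces ties
    y <- runif(n) < 0.4
    if (sum(y) == 0 || sum(y) == n) next
    roc <- empirical_roc(scores, y)
    expect_equal(roc$auc, auc_pair_oracle(scores, y), tolerance = 1e-12)
  }
})

test_that("ROC operating points are monotone along the curve", {
  set.seed(73)
  roc <- empirical_roc(runif(100), runif(100) < 0.3)
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))
})

test_that("swapping endpoint labels reflects the AUC", {
  set.seed(79)
  scores <- round(runif(60), 2)
  y <- runif(60) < 0.5
  a1 <- empirical_roc(scores, y)$auc
  a2 <- empirical_roc(scores, !y)$auc
  expect_equal(a1 + a2, 1, tolerance = 1e-12)
})

test_that("AUC and DeLong interval agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(83)
  scores <- round(runif(100), 2)
  y <- runif(100) < 0.35
  roc <- empirical_roc(scores, y)
  proc <- pROC::roc(response = y, predictor = scores, quiet = TRUE,
                    direction = "<")
  expect_equal(roc$auc, as.numeric(pROC::auc(proc)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(proc, method = "delong"))
  expect_equal(c(roc$auc_ci$lower, roc$auc_ci$upper), ci[c(1, 3)],
               tolerance = 1e-9)
})

test_that("identical scores give a zero statistic and p = 1", {
  set.seed(89)
  scores <- runif(50)
  y <- runif(50) < 0.5
  res <- delong_paired(scores, scores, y)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("paired test matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(97)
  n <- 120
  lat <- runif(n)
  y <- runif(n) < lat
  a <- plogis(qlogis(pmin(pmax(lat, 1e-4), 1 - 1e-4)) + rnorm(n, 0, 1))
  b <- plogis(qlogis(pmin(pmax(lat, 1e-4), 1 - 1e-4)) + rnorm(n, 0, 2))
  res <- delong_paired(a, b, y)
  ra <- pROC::roc(y, a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(y, b, quiet = TRUE, direction = "<")
  pt <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(abs(res$statistic), abs(as.numeric(pt$statistic)),
               tolerance = 1e-9)
  expect_equal(res$p_value, as.numeric(pt$p.value), tolerance = 1e-9)
})

test_that("paired AUC variance agrees with a paired bootstrap", {
  set.seed(101)
  n <- 300
  lat <- rbeta(n, 1.2, 3)
  y <- runif(n) < lat
  if (sum(y) < 10) y[1:10] <- TRUE
  lg <- qlogis(pmin(pmax(lat, 1e-4), 1 - 1e-4))
  a <- plogis(lg + rnorm(n, 0, 0.8))
  b <- plogis(lg + rnorm(n, 0, 0.8))
  res <- delong_paired(a, b, y)

  auc_rank <- function(s, yy) {
    r <- rank(s)
    m <- sum(yy)
    (sum(r[yy]) - m * (m + 1) / 2) / (m * (length(yy) - m))
  }
  boots <- replicate(2000, {
    idx <- sample.int(n, n, replace = TRUE)
    while (length(unique(y[idx])) < 2) idx <- sample.int(n, n, replace = TRUE)
    auc_rank(a[idx], y[idx]) - auc_rank(b[idx], y[idx])
  })
  expect_lt(abs(res$var_diff - stats::var(boots)) / stats::var(boots), 0.15)
})

test_that("paired test p-values are uniform under the null", {
  set.seed(103)
  reps <- 500
  n <- 2000
  pvals <- replicate(reps, {
    lat <- rbeta(n, 1.5, 3.5)
    y <- runif(n) < lat
    lg <- qlogis(pmin(pmax(lat, 1e-4), 1 - 1e-4))
    a <- plogis(lg + rnorm(n, 0, 1))   # equal-information noisy copies
    b <- plogis(lg + rnorm(n, 0, 1))
    delong_paired(a, b, y)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Holm adjustment matches the hand-applied step-down rule", {
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  set.seed(107)
  p <- runif(10)
  expect_true(all(holm_adjust(p) >= p))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})
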