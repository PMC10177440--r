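# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity so they share no code
# with the implementation under test.

# AUC by explicit O(m*n) positive-negative pair counting, ties worth 1/2.
auc_pair_oracle <- function(scores, endpoints) {
  y <- as.logical(endpoints)
  pos <- scores[y]
  neg <- scores[!y]
  total <- 0
  for (xp in pos) {
    for (xn in neg) {
      total <- total + (xp > xn) + 0.5 * (xp == xn)
    }
  }
  total / (length(pos) * length(neg))
}

# Exact binomial interval by bisection on the binomial tail CDF:
# lower solves P(X >= k | p) = alpha/2, upper solves P(X <= k | p) = alpha/2.
cp_bisection_oracle <- function(k, n, level = 0.95, tol = 1e-12) {
  alpha <- 1 - level
  bisect <- function(f, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  lower <- if (k == 0) 0 else {
    bisect(function(p) sum(stats::dbinom(k:n, n, p)) - alpha / 2, 0, 1)
  }
  upper <- if (k == n) 1 else {
    bisect(function(p) -(sum(stats::dbinom(0:k, n, p)) - alpha / 2), 0, 1)
  }
  c(lower = lower, upper = upper)
}

# Confusion counts by an explicit per-record loop.
confusion_loop_oracle <- function(high_risk, endpoint) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(high_risk)) {
    if (high_risk[i] && endpoint[i]) tp <- tp + 1L
    else if (high_risk[i] && !endpoint[i]) fp <- fp + 1L
    else if (!high_risk[i] && endpoint[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# A small hand-constructed cohort exercising every column, independent of
# the generator.
make_fixture_cohort <- function(n = 40, seed = 99) {
  set.seed(seed)
  full <- round(stats::runif(n), 4)
  known <- seq_len(n) %% 3 != 0
  nochr3 <- ifelse(known, round(stats::plogis(stats::qlogis(pmin(pmax(
    full, 1e-4), 1 - 1e-4)) + stats::rnorm(n, 0, 0.5)), 4), NA)
  nochr3[!known] <- full[!known]
  stage <- sample(stage_levels, n, replace = TRUE)
  data.frame(
    patient_id = sprintf("F%03d", seq_len(n)),
    age = sample(20:90, n, replace = TRUE),
    sex = sample(c("F", "M"), n, replace = TRUE),
    diameter_mm = round(stats::runif(n, 2, 25), 1),
    height_mm = round(stats::runif(n, 1, 15), 1),
    ciliary_body = stats::runif(n) < 0.2,
    extraocular = stats::runif(n) < 0.05,
    chr3_status = ifelse(known, sample(c("monosomy", "disomy"), n, TRUE),
                         "unknown"),
    mam5_full = full,
    mam5_nochr3 = nochr3,
    mam5_nogenetics = round(stats::runif(n), 4),
    stage = stage,
    endpoint = stats::runif(n) < full,
    stringsAsFactors = FALSE
  )
}
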