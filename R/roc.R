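# DeLong structural components via midranks (Sun & Xu style O(n log n)):
# V10[i] = (1/n) * sum_j psi(x_i, y_j), V01[j] = (1/m) * sum_i psi(x_i, y_j)
# with psi = 1, 1/2, 0 for x > y, x == y, x < y. AUC = mean(V10) = mean(V01).
delong_components <- function(scores, endpoints) {
  y <- as.logical(endpoints)
  x_pos <- scores[y]
  x_neg <- scores[!y]
  m <- length(x_pos)
  n <- length(x_neg)
  if (m == 0 || n == 0) stop("need at least one positive and one negative")
  r_all <- rank(c(x_pos, x_neg), ties.method = "average")
  r_pos <- rank(x_pos, ties.method = "average")
  r_neg <- rank(x_neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' Empirical ROC curve with AUC and DeLong confidence interval
#'
#' Operating points are taken at every distinct observed score used as an
#' inclusive threshold (score >= threshold means high-risk), plus the (0,0)
#' corner; the (1,1) corner arises at the minimum observed score. The AUC is
#' computed by trapezoidal integration over the curve and equals the
#' tie-corrected Mann-Whitney statistic (ties between a positive and a
#' negative score contribute 1/2). The confidence interval is the DeLong
#' normal interval, clipped to \[0, 1\].
#'
#' @param scores Numeric risk scores.
#' @param endpoints Logical/0-1 endpoint indicator, same length.
#' @param level Confidence level for the AUC interval.
#' @return An object of class `um_roc`: list with `points` (data frame of
#'   `threshold`, `fpr`, `tpr`), `auc`, `auc_ci` (an `um_propci`), `n_pos`,
#'   `n_neg`.
#' @examples
#' empirical_roc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc
#' @export
empirical_roc <- function(scores, endpoints, level = 0.95) {
  y <- as.logical(endpoints)
  if (length(scores) != length(y)) stop("length mismatch")
  if (anyNA(scores) || anyNA(y)) stop("missing values not allowed")
  cmp <- delong_components(scores, y)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[y] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!y] >= t), numeric(1))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1) {
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  auc_trap <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                     utils::tail(pts$tpr, -1)) / 2)
  v <- stats::var(cmp$v10) / cmp$m + stats::var(cmp$v01) / cmp$n
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- structure(
    list(estimate = cmp$auc,
         lower = max(0, cmp$auc - z * sqrt(v)),
         upper = min(1, cmp$auc + z * sqrt(v)),
         level = level, numerator = NA_integer_, denominator = NA_integer_),
    class = "um_propci"
  )
  structure(
    list(points = pts, auc = auc_trap, auc_ci = ci,
         n_pos = cmp$m, n_neg = cmp$n),
    class = "um_roc"
  )
}

#' @export
print.um_roc <- function(x, ...) {
  cat(sprintf("empirical ROC: %d positives, %d negatives, %d operating points\n",
              x$n_pos, x$n_neg, nrow(x$points)))
  cat(sprintf("AUC = %.3f (%g%% CI %.3f-%.3f)\n", x$auc,
              100 * x$auc_ci$level, x$auc_ci$lower, x$auc_ci$upper))
  invisible(x)
}

#' DeLong paired test comparing two AUCs on the same patients
#'
#' Nonparametric comparison of the AUCs of two risk scores measured on the
#' same patients, using U-statistic structural components. The variance of
#' the AUC difference is `var(V10a - V10b)/m + var(V01a - V01b)/n`; the
#' statistic is the difference divided by its standard error, referred to
#' the standard normal (two-sided). When the paired variance is zero and the
#' AUCs are equal (e.g. identical scores) the statistic is 0 and p = 1.
#'
#' @param scores_a,scores_b Two score vectors for the same patients.
#' @param endpoints Endpoint indicator.
#' @return An object of class `um_delong`: list with `auc_a`, `auc_b`,
#'   `statistic`, `p_value`, `var_diff`.
#' @export
delong_paired <- function(scores_a, scores_b, endpoints) {
  y <- as.logical(endpoints)
  if (length(scores_a) != length(y) || length(scores_b) != length(y)) {
    stop("scores and endpoints must have equal lengths")
  }
  a <- delong_components(scores_a, y)
  b <- delong_components(scores_b, y)
  d10 <- a$v10 - b$v10
  d01 <- a$v01 - b$v01
  v <- stats::var(d10) / a$m + stats::var(d01) / a$n
  diff <- a$auc - b$auc
  if (v <= .Machine$double.eps) {
    if (abs(diff) > 1e-12) {
      stop("degenerate paired variance with unequal AUCs; ",
           "inputs are not exchangeable paired scores")
    }
    stat <- 0
    p <- 1
  } else {
    stat <- diff / sqrt(v)
    p <- 2 * stats::pnorm(-abs(stat))
  }
  structure(
    list(auc_a = a$auc, auc_b = b$auc, statistic = stat, p_value = p,
         var_diff = v),
    class = "um_delong"
  )
}

#' @export
print.um_delong <- function(x, ...) {
  cat(sprintf("DeLong paired test: AUC %.3f vs %.3f, z = %.3f, p = %.4g\n",
              x$auc_a, x$auc_b, x$statistic, x$p_value))
  invisible(x)
}

#' Holm step-down adjustment for a family of p-values
#'
#' Controls the family-wise error rate; adjusted p-values dominate the raw
#' ones elementwise. Thin validated wrapper over [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, in the original order.
#' @export
holm_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be numeric in [0, 1]")
  }
  stats::p.adjust(p, method = "holm")
}
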