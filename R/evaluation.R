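# Evaluation: confusion-matrix metrics, rank-based AUC, per-fold
# summaries with t-distribution confidence intervals, percentile
# bootstrap, and DeLong's test for paired AUCs.

#' Confusion counts and threshold metrics
#'
#' Computes TP/TN/FP/FN from hard 0/1 predictions and the six derived
#' metrics ACC, PPV, NPV, SEN, SPE, F1.  Zero-denominator cases are
#' reported as `NA` (flagged undefined) rather than silently coerced to
#' zero.
#'
#' @param labels 0/1 truth vector.
#' @param predictions 0/1 prediction vector of equal length.
#' @return list with `counts` (named TP/TN/FP/FN) and `metrics` (named
#'   numeric: ACC, PPV, NPV, SEN, SPE, F1).
#' @export
confusion_and_metrics <- function(labels, predictions) {
  stop_if_not(length(labels) > 0, "empty input")
  stop_if_not(length(labels) == length(predictions),
              "labels and predictions must have equal length")
  tp <- sum(labels == 1 & predictions == 1)
  tn <- sum(labels == 0 & predictions == 0)
  fp <- sum(labels == 0 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  metrics <- c(ACC = div(tp + tn, tp + tn + fp + fn),
               PPV = div(tp, tp + fp),
               NPV = div(tn, tn + fn),
               SEN = div(tp, tp + fn),
               SPE = div(tn, tn + fp),
               F1 = div(2 * tp, 2 * tp + fp + fn))
  list(counts = c(TP = tp, TN = tn, FP = fp, FN = fn), metrics = metrics)
}

#' Area under the ROC curve
#'
#' Rank-based (Wilcoxon) computation: the probability that a random
#' positive scores above a random negative, with ties counted half.
#'
#' @param labels 0/1 vector (both classes required).
#' @param scores numeric scores, higher = more pCR-like.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(labels, scores) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  stop_if_not(n1 > 0 && n0 > 0, "AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Summarize per-fold metric values
#'
#' Mean, standard deviation and a 95% Student-t confidence interval
#' `mean +/- t_{0.975, k-1} * SD / sqrt(k)`.  The SD uses the population
#' (denominator `k`) convention by default, which is the convention that
#' reproduces published fold tables of this form; the sample convention
#' is available by flag.
#'
#' @param values numeric vector of per-fold values (k >= 2).
#' @param level confidence level.
#' @param sd_convention `"population"` (default) or `"sample"`.
#' @return list with `mean`, `sd`, `ci` (lower, upper), `df`.
#' @export
fold_summary <- function(values, level = 0.95,
                         sd_convention = c("population", "sample")) {
  sd_convention <- match.arg(sd_convention)
  k <- length(values)
  stop_if_not(k >= 2, "need at least two fold values")
  m <- mean(values)
  s <- stats::sd(values)
  if (sd_convention == "population") s <- s * sqrt((k - 1) / k)
  tcrit <- stats::qt(1 - (1 - level) / 2, df = k - 1)
  half <- tcrit * s / sqrt(k)
  list(mean = m, sd = s, ci = c(lower = m - half, upper = m + half),
       df = k - 1)
}

#' Percentile bootstrap confidence interval for a metric
#'
#' Case resampling with replacement; resamples on which the metric is
#' undefined (e.g. a single-class resample for AUC) are redrawn and
#' counted.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores (or hard predictions, depending on
#'   `metric`).
#' @param metric function `(labels, scores) -> scalar`.
#' @param B number of bootstrap iterations (default 1000).
#' @param seed RNG seed.
#' @param level confidence level.
#' @return list with `lower`, `upper`, `B`, `n_redrawn`.
#' @export
bootstrap_ci <- function(labels, scores, metric = auc_score, B = 1000L,
                         seed = 1L, level = 0.95) {
  stop_if_not(B >= 1, "B must be >= 1")
  point <- tryCatch(metric(labels, scores), error = function(e) NA_real_)
  stop_if_not(is.finite(point), "metric undefined on the full sample")
  n <- length(labels)
  stats_ <- numeric(B)
  n_redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        val <- tryCatch(suppressWarnings(metric(labels[idx], scores[idx])),
                        error = function(e) NA_real_)
        if (is.finite(val)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > 100L * B) stop("metric undefined on nearly all resamples")
      }
      stats_[b] <- val
    }
  })
  a <- (1 - level) / 2
  q <- stats::quantile(stats_, c(a, 1 - a), names = FALSE, type = 7)
  list(lower = q[1], upper = q[2], B = B, n_redrawn = n_redrawn)
}

# DeLong structural components: V10 (per positive) and V01 (per negative)
delong_components <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  m <- length(pos)
  n <- length(neg)
  all_r <- rank(c(pos, neg), ties.method = "average")
  rp <- rank(pos, ties.method = "average")
  rn <- rank(neg, ties.method = "average")
  v10 <- (all_r[seq_len(m)] - rp) / n
  v01 <- 1 - (all_r[m + seq_len(n)] - rn) / m
  auc <- sum(all_r[seq_len(m)]) / (m * n) - (m + 1) / (2 * n)
  list(v10 = v10, v01 = v01, auc = auc)
}

#' DeLong's test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors evaluated on the same samples
#' using the fast rank-based formulation of the DeLong structural
#' components; returns the AUC difference (A minus B) and the two-sided
#' asymptotic-normal p-value.  Identical score vectors (zero variance of
#' the difference) return p = 1 by convention, flagged via
#' `zero_variance`.
#'
#' @param labels shared 0/1 vector (both classes required).
#' @param scoresA,scoresB paired score vectors.
#' @return list with `auc_a`, `auc_b`, `auc_difference`, `z`, `p_value`,
#'   `zero_variance`.
#' @export
delong_test <- function(labels, scoresA, scoresB) {
  stop_if_not(sum(labels == 1) > 0 && sum(labels == 0) > 0,
              "both classes required")
  stop_if_not(length(scoresA) == length(labels) &&
              length(scoresB) == length(labels), "paired scores required")
  ca <- delong_components(labels, scoresA)
  cb <- delong_components(labels, scoresB)
  m <- sum(labels == 1)
  n <- sum(labels == 0)
  s10 <- stats::var(cbind(ca$v10, cb$v10))
  s01 <- stats::var(cbind(ca$v01, cb$v01))
  # variance of (auc_a - auc_b)
  L <- c(1, -1)
  v <- drop(t(L) %*% s10 %*% L) / m + drop(t(L) %*% s01 %*% L) / n
  diff <- ca$auc - cb$auc
  if (v <= .Machine$double.eps) {
    return(list(auc_a = ca$auc, auc_b = cb$auc, auc_difference = diff,
                z = 0, p_value = 1, zero_variance = TRUE))
  }
  z <- diff / sqrt(v)
  list(auc_a = ca$auc, auc_b = cb$auc, auc_difference = diff, z = z,
       p_value = 2 * stats::pnorm(-abs(z)), zero_variance = FALSE)
}
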