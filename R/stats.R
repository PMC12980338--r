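#' Evaluation statistics
#'
#' AUC in its Mann-Whitney form, the DeLong test for two correlated ROC
#' curves computed from structural components (placement values with
#' midrank tie handling), Benjamini-Hochberg FDR adjustment, and the Pearson
#' correlation test.
#'
#' @name stats_layer
NULL

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  labels == "positive"
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Mean over all (positive, negative) score pairs of
#' `[s+ > s-] + 0.5 [s+ = s-]`, computed via midranks.
#'
#' @param scores numeric scores, higher = more promoter-like.
#' @param labels logical/0-1/"positive"-"negative" class labels.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  m <- sum(y); n <- sum(!y)
  if (m == 0 || n == 0) {
    stop_promtok("both classes must be present", "promtok_data_error")
  }
  r <- rank(scores)
  (sum(r[y]) - m * (m + 1) / 2) / (m * n)
}

# Placement values (structural components): V10 per positive, V01 per
# negative, midrank tie treatment.
placements <- function(scores, y) {
  pos <- scores[y]; neg <- scores[!y]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg))
  v10 <- (r_all[seq_len(m)] - rank(pos)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(neg)) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated AUCs
#'
#' Both models must score the same records. The variance of the AUC
#' difference is assembled from the empirical covariance of the two models'
#' placement values; the test statistic is referred to the standard normal.
#'
#' @param scores_a,scores_b scores from the two models on identical records.
#' @param labels class labels (shared).
#' @return list: `auc_a`, `auc_b`, `var_diff`, `z`, `p` (two-sided).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels)) {
    stop_promtok("scores_a, scores_b and labels must align",
                 "promtok_pairing_error")
  }
  y <- as_binary_labels(labels)
  pa <- placements(scores_a, y)
  pb <- placements(scores_b, y)
  m <- sum(y); n <- sum(!y)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  if (var_diff <= 0) {
    if (abs(d) < 1e-12) {
      z <- 0; p <- 1
    } else {
      warning("zero variance with nonzero AUC difference; reporting p = 0")
      z <- sign(d) * Inf; p <- 0
    }
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, var_diff = max(var_diff, 0),
       z = z, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement, order-
#' preserving with the input.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return adjusted p-values.
#' @export
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop_promtok("p-values must lie in [0, 1]", "promtok_domain_error")
  }
  p.adjust(pvalues, method = "BH")
}

#' Pearson correlation test
#'
#' Sample Pearson r with the exact t-based two-sided p-value
#' (`t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df).
#'
#' @param x,y numeric vectors, length >= 3, non-constant.
#' @return list: `r`, `p`, `n`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_promtok("need aligned vectors of length >= 3", "promtok_data_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_promtok("correlation undefined for constant input",
                 "promtok_domain_error")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
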