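#' Area under the ROC curve
#'
#' Computes AUROC via the Mann-Whitney U statistic with the standard
#' mid-rank tie correction: the probability that a randomly chosen positive
#' outscores a randomly chosen negative, ties counting one half.
#'
#' @param scores Numeric vector of predicted scores (higher = more positive).
#' @param labels Binary vector (0/1, or logical) of true classes.
#' @return AUROC in \[0, 1\].
#' @examples
#' auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
auroc <- function(scores, labels) {
  labels <- check_binary_labels(labels, length(scores))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("auroc requires both classes present in `labels`")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) integral of precision over recall: scores are
#' sorted decreasingly and the curve accumulates
#' \eqn{\sum_i (R_i - R_{i-1}) P_i}, with tied scores collapsed into a single
#' step so the value does not depend on the within-tie ordering. Equivalent to
#' average precision. For uninformative scores AUPRC approaches the
#' prevalence of the positive class, which is what makes it the stricter
#' metric under class imbalance.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- check_binary_labels(labels, length(scores))
  n_pos <- sum(labels == 1)
  if (n_pos == 0L || sum(labels == 0) == 0L) {
    stop("auprc requires both classes present in `labels`")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # keep only the last index of each tied-score block
  keep <- c(diff(s) != 0, TRUE)
  tp <- tp[keep]
  fp <- fp[keep]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Sensitivity and specificity at a threshold
#'
#' @inheritParams auroc
#' @param threshold Scores strictly greater than or equal to `threshold` are
#'   called positive. Default 0.5, matching probability outputs.
#' @return Named numeric vector `c(sensitivity =, specificity =)`.
#' @export
sens_spec <- function(scores, labels, threshold = 0.5) {
  labels <- check_binary_labels(labels, length(scores))
  if (!any(labels == 1) || !any(labels == 0)) {
    stop("sens_spec requires both classes present in `labels`")
  }
  pred <- as.integer(scores >= threshold)
  c(
    sensitivity = sum(pred == 1 & labels == 1) / sum(labels == 1),
    specificity = sum(pred == 0 & labels == 0) / sum(labels == 0)
  )
}

#' Two-sided paired t-test between matched metric values
#'
#' Thin wrapper over [stats::t.test] for paired, per-repeat metric values.
#' Zero-variance differences (the two vectors identical up to a constant of
#' zero spread) make the t statistic undefined; that degenerate case returns
#' p = 1 with a warning rather than erroring, so evaluation reports stay
#' total.
#'
#' @param values_a,values_b Equal-length numeric vectors paired by repeat.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return List with `p_value`, `t`, `df`, `mean_diff`, `significant`.
#' @export
paired_t_test <- function(values_a, values_b, alpha = 0.05) {
  if (length(values_a) != length(values_b)) {
    stop("paired_t_test requires equal-length vectors")
  }
  if (length(values_a) < 2) {
    stop("paired_t_test requires at least 2 pairs")
  }
  d <- values_a - values_b
  if (stats::sd(d) == 0) {
    warning("zero-variance paired differences; p-value degenerate, reported as 1")
    return(list(
      p_value = 1.0, t = NA_real_, df = length(d) - 1L,
      mean_diff = mean(d), significant = FALSE
    ))
  }
  ht <- stats::t.test(values_a, values_b, paired = TRUE)
  list(
    p_value = unname(ht$p.value),
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    mean_diff = mean(d),
    significant = unname(ht$p.value) < alpha
  )
}

# coerce labels to 0/1 integer and validate length
check_binary_labels <- function(labels, n) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (is.factor(labels)) labels <- as.integer(as.character(labels))
  if (length(labels) != n) stop("scores and labels must have equal length")
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be binary 0/1")
  }
  as.integer(labels)
}
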