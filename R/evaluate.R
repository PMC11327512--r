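#' Decision rule on the normal-class probability
#'
#' A sample is called normal when its normal-class probability strictly
#' exceeds the threshold, and aspiration otherwise (ties go to
#' aspiration — the conservative side for a screening tool).
#'
#' @param prob_aspiration probability of the aspiration class, in \[0, 1\].
#' @param threshold decision threshold on `P(normal)` (default 0.5).
#' @return character vector of `"normal"` / `"aspiration"` calls.
#' @export
classifyProb <- function(prob_aspiration, threshold = 0.5) {
  stopifnot(all(prob_aspiration >= 0 & prob_aspiration <= 1))
  ifelse((1 - prob_aspiration) > threshold, "normal", "aspiration")
}

#' Binary cross-entropy with logits
#'
#' Numerically stable form
#' `max(z, 0) - z*y + log(1 + exp(-|z|))`.
#'
#' @param logits numeric logits.
#' @param labels 0/1 labels (1 = aspiration).
#' @param reduce return the mean (default) instead of per-sample losses.
#' @return mean loss, or per-sample losses when `reduce = FALSE`.
#' @export
bceWithLogits <- function(logits, labels, reduce = TRUE) {
  l <- pmax(logits, 0) - logits * labels + log1p(exp(-abs(logits)))
  if (reduce) mean(l) else l
}

#' Confusion counts from labels and calls
#'
#' @param labels 0/1 truth (1 = aspiration, the positive class).
#' @param calls `"normal"`/`"aspiration"` calls from [classifyProb()], or
#'   0/1.
#' @return list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusionCounts <- function(labels, calls) {
  if (is.character(calls)) calls <- as.integer(calls == "aspiration")
  stopifnot(length(labels) == length(calls),
            all(labels %in% 0:1), all(calls %in% 0:1))
  list(tp = sum(labels == 1L & calls == 1L),
       fp = sum(labels == 0L & calls == 1L),
       tn = sum(labels == 0L & calls == 0L),
       fn = sum(labels == 1L & calls == 0L))
}

#' Threshold metrics from a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`,
#' NPV `tn/(tn+fn)`, accuracy `(tp+tn)/total` — reported as percentages —
#' and the F1 score (harmonic mean of PPV and sensitivity) on \[0, 1\].
#' A metric with a zero denominator is reported as `NA` (undefined), never
#' as zero.
#'
#' @param counts list with `tp`, `fp`, `tn`, `fn` (see
#'   [confusionCounts()]).
#' @return one-row data.frame with columns `accuracy`, `sensitivity`,
#'   `specificity`, `f1`, `ppv`, `npv`.
#' @export
confusionMetrics <- function(counts) {
  with(counts, {
    total <- tp + fp + tn + fn
    stopifnot(total > 0)
    frac <- function(num, den) if (den > 0) num / den else NA_real_
    sens <- frac(tp, tp + fn)
    spec <- frac(tn, tn + fp)
    ppv <- frac(tp, tp + fp)
    npv <- frac(tn, tn + fn)
    f1 <- if (!is.na(ppv) && !is.na(sens) && (ppv + sens) > 0)
      2 * ppv * sens / (ppv + sens) else NA_real_
    data.frame(accuracy = 100 * (tp + tn) / total, sensitivity = 100 * sens,
               specificity = 100 * spec, f1 = f1, ppv = 100 * ppv,
               npv = 100 * npv)
  })
}

#' Area under the ROC curve
#'
#' Midrank (Mann-Whitney) formulation: the probability that a randomly
#' chosen aspiration score exceeds a randomly chosen normal score, with
#' ties counted one half.
#'
#' @param labels 0/1 truth (1 = aspiration).
#' @param scores numeric scores, larger = more aspiration-like.
#' @return AUC in \[0, 1\].
#' @export
rocAuc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% 0:1))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC requires both classes to be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-fold metrics report
#'
#' @param labels 0/1 truth for the fold's test pairs.
#' @param probs aspiration-class probabilities.
#' @param threshold decision threshold (see [classifyProb()]).
#' @param loss mean test binary cross-entropy (optional).
#' @param train_accuracy,train_loss final-epoch training metrics
#'   (optional).
#' @return one-row data.frame with columns `auc`, `accuracy`,
#'   `sensitivity`, `specificity`, `f1`, `ppv`, `npv`, `loss`,
#'   `train_accuracy`, `train_loss`.
#' @export
metricsReport <- function(labels, probs, threshold = 0.5, loss = NA_real_,
                          train_accuracy = NA_real_,
                          train_loss = NA_real_) {
  cm <- confusionMetrics(confusionCounts(labels,
                                         classifyProb(probs, threshold)))
  cbind(data.frame(auc = rocAuc(labels, probs)), cm,
        data.frame(loss = loss, train_accuracy = train_accuracy,
                   train_loss = train_loss))
}

#' Fold summary: mean, 95% CI, max
#'
#' Summarizes per-fold metrics as the mean, a t-distribution 95%
#' confidence interval (`mean +/- t(0.975, n-1) * sd / sqrt(n)`), and the
#' maximum. Intervals are not clipped to the metric's natural range.
#'
#' @param reports data.frame of fold metric rows (e.g. stacked
#'   [metricsReport()] rows); non-numeric and index columns are ignored.
#' @return data.frame with columns `metric`, `mean`, `ci_low`, `ci_high`,
#'   `max`.
#' @export
summarizeFolds <- function(reports) {
  if (nrow(reports) < 2L)
    stop("at least two fold reports are needed for a confidence interval")
  cols <- setdiff(names(reports)[vapply(reports, is.numeric, logical(1))],
                  "fold")
  rows <- lapply(cols, function(cl) {
    v <- reports[[cl]]
    v <- v[!is.na(v)]
    if (length(v) < 2L)
      return(data.frame(metric = cl, mean = mean(v), ci_low = NA_real_,
                        ci_high = NA_real_,
                        max = if (length(v)) max(v) else NA_real_))
    half <- qt(0.975, length(v) - 1L) * sd(v) / sqrt(length(v))
    data.frame(metric = cl, mean = mean(v), ci_low = mean(v) - half,
               ci_high = mean(v) + half, max = max(v))
  })
  do.call(rbind, rows)
}
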