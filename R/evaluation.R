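# Evaluation battery: thresholded category selection with missed-trial
# counting, one-vs-rest confusion counts and metrics, ROC points, and
# McNemar paired comparisons.

#' Thresholded category selection
#'
#' A category is selected only if its indicated probability exceeds the
#' threshold; otherwise the case is missed. The default threshold 0.17
#' sits just above the six-category chance level 1/6 = 16.66%. Ties at
#' the maximum go to the lowest class index.
#'
#' @param probabilities Probability vector (sums to 1 within 1e-9).
#' @param threshold Selection threshold (default 0.17).
#' @return A list of class `"class_decision"`: `probabilities`,
#'   `selected` (class index, or `NA` for a missed case), `threshold`.
#' @examples
#' select_category(c(0.9, 0.02, 0.02, 0.02, 0.02, 0.02))$selected # 1
#' select_category(rep(1 / 6, 6))$selected                        # NA
#' @export
select_category <- function(probabilities, threshold = 0.17) {
  p <- as.numeric(probabilities)
  if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop_domain("probabilities must be non-negative and sum to 1")
  }
  sel <- if (max(p) > threshold) which.max(p) else NA_integer_
  structure(list(probabilities = p, selected = sel, threshold = threshold),
            class = "class_decision")
}

#' Count missed cases among decisions
#'
#' @param decisions A list of [select_category()] decisions, or an
#'   integer vector of selections with `NA` for missed (as returned by
#'   `predict(type = "decision")`).
#' @return Number of missed cases.
#' @export
count_missed <- function(decisions) {
  if (is.list(decisions)) {
    decisions <- vapply(decisions, function(d) d$selected, integer(1))
  }
  sum(is.na(decisions))
}

#' One-vs-rest confusion counts per class
#'
#' For each class, the case counts of true/false positives/negatives
#' against all other classes. Missed cases (`NA` predictions) are
#' excluded before counting, so per-class totals equal the number of
#' classified cases.
#'
#' @param true_labels,predicted_labels Equal-length integer label
#'   vectors in `1..n_classes` (`NA` predictions allowed and excluded).
#' @param n_classes Number of classes.
#' @return A data.frame with columns `class`, `tp`, `fp`, `fn`, `tn`.
#' @examples
#' confusion_counts(c(1, 1, 2), c(1, 2, 2), 2)
#' @export
confusion_counts <- function(true_labels, predicted_labels, n_classes) {
  n_classes <- check_count(n_classes, "n_classes")
  true_labels <- as.integer(true_labels)
  predicted_labels <- as.integer(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    stop_domain("label vectors must have equal length")
  }
  keep <- !is.na(predicted_labels)
  true_labels <- true_labels[keep]
  predicted_labels <- predicted_labels[keep]
  if (any(c(true_labels, predicted_labels) < 1L) ||
      any(c(true_labels, predicted_labels) > n_classes)) {
    stop_domain("labels must lie in 1..n_classes")
  }
  out <- do.call(rbind, lapply(seq_len(n_classes), function(k) {
    pos <- true_labels == k
    sel <- predicted_labels == k
    data.frame(class = k,
               tp = sum(pos & sel), fp = sum(!pos & sel),
               fn = sum(pos & !sel), tn = sum(!pos & !sel))
  }))
  out
}

metric_pct <- function(num, den) {
  ifelse(den == 0, NA_real_, round_half_up(100 * num / den, 1))
}

#' Per-class metrics from confusion counts
#'
#' Precision `tp/(tp+fp)`, true-positive rate `tp/(tp+fn)`,
#' false-positive rate `fp/(fp+tn)` and accuracy
#' `(tp+tn)/(tp+fp+fn+tn)`, reported in percent rounded half-up to one
#' decimal. Zero denominators yield `NA`.
#'
#' @param counts A data.frame with columns `tp`, `fp`, `fn`, `tn`
#'   (e.g. from [confusion_counts()]).
#' @return The input with columns `precision`, `tpr`, `fpr`,
#'   `accuracy` appended (percent, one decimal).
#' @examples
#' metrics_from_counts(data.frame(tp = 1017, fp = 33, fn = 8, tn = 4338))
#' @export
metrics_from_counts <- function(counts) {
  counts <- as.data.frame(counts)
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(counts)))
  within(counts, {
    accuracy <- metric_pct(tp + tn, tp + fp + fn + tn)
    fpr <- metric_pct(fp, fp + tn)
    tpr <- metric_pct(tp, tp + fn)
    precision <- metric_pct(tp, tp + fp)
  })
}

#' Overall classification accuracy from per-class confusion counts
#'
#' Summed true positives over the total number of trials, in percent
#' (half-up, one decimal). With one-vs-rest counts the summed true
#' positives equal the number of correctly classified cases.
#'
#' @param counts Per-class counts (columns `tp`, ...).
#' @param n_total Total number of trials to divide by.
#' @return Accuracy in percent.
#' @examples
#' # the six-class study: 5302 summed true positives over 5400 trials
#' @export
overall_accuracy <- function(counts, n_total) {
  round_half_up(100 * sum(counts$tp) / n_total, 1)
}

#' One-vs-rest ROC points
#'
#' Sweeps the decision threshold over all distinct scores, yielding
#' (false-positive rate, true-positive rate) pairs including the
#' endpoints (0,0) and (1,1); FPR is non-decreasing along the list.
#'
#' @param scores Per-case scores for the class (higher = more
#'   positive).
#' @param truth Per-case logicals (`TRUE` = positive class).
#' @return A data.frame with columns `fpr`, `tpr`, ordered by
#'   threshold from strictest to loosest.
#' @examples
#' roc_points(c(0.9, 0.8, 0.4, 0.1), c(TRUE, TRUE, FALSE, FALSE))
#' @export
roc_points <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth) || anyNA(scores) || anyNA(truth)) {
    stop_domain("scores and truth must be equal-length and complete")
  }
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L) {
    stop_domain("need at least one positive and one negative case")
  }
  th <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(th, function(cut) {
    sel <- scores >= cut
    c(fpr = sum(sel & !truth) / n_neg, tpr = sum(sel & truth) / n_pos)
  }, numeric(2)))
  pts <- rbind(c(fpr = 0, tpr = 0), pts, c(fpr = 1, tpr = 1))
  as.data.frame(unique(pts))
}

#' McNemar statistic for paired classifier comparison
#'
#' `(b - c)^2 / (b + c)` on the discordant-pair counts, without
#' continuity correction (df = 1); e.g. discordant counts (3, 10) give
#' 49/13 = 3.769.
#'
#' @param discordant_b,discordant_c Non-negative discordant-pair
#'   counts (cases one classifier gets right and the other wrong).
#' @return The chi-square statistic.
#' @seealso [mcnemar_pvalue()], [discordant_counts()]
#' @examples
#' mcnemar_statistic(3, 10) # 3.769
#' @export
mcnemar_statistic <- function(discordant_b, discordant_c) {
  b <- discordant_b
  c_ <- discordant_c
  if (b < 0 || c_ < 0 || b != floor(b) || c_ != floor(c_)) {
    stop_domain("discordant counts must be non-negative integers")
  }
  if (b + c_ == 0) stop_domain("statistic undefined: no discordant pairs")
  (b - c_)^2 / (b + c_)
}

#' @rdname mcnemar_statistic
#' @param statistic A McNemar chi-square value.
#' @return `mcnemar_pvalue()`: the upper-tail chi-square p-value
#'   (df = 1).
#' @export
mcnemar_pvalue <- function(statistic) {
  pchisq(statistic, df = 1, lower.tail = FALSE)
}

#' @rdname mcnemar_statistic
#' @param correct_a,correct_b Aligned logical vectors of per-case
#'   correctness for two classifiers on the same cases.
#' @return `discordant_counts()`: a named vector `c(b = ..., c = ...)`
#'   where `b` counts cases only classifier A gets right.
#' @export
discordant_counts <- function(correct_a, correct_b) {
  if (length(correct_a) != length(correct_b)) {
    stop_domain("correctness vectors must be aligned")
  }
  c(b = sum(correct_a & !correct_b), c = sum(!correct_a & correct_b))
}
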