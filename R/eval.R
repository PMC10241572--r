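# Confusion-matrix metrics, ROC/AUC, the paired DeLong test, and the
# integer reconstruction oracle for published performance tables.
# Positive class throughout = the disease coded 1 (appendicitis in the
# clinical setting).

#' Confusion matrix container
#'
#' @param tp,fn,fp,tn non-negative integer counts. TP = positive classified
#'   positive, FN = positive classified negative, FP = negative classified
#'   positive, TN = negative classified negative.
#' @return an object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  v <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(v < 0)) stop("counts must be non-negative")
  if (sum(v) < 1) stop("confusion matrix must contain at least one case")
  structure(as.list(v), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix (N = %d):\n", x$tp + x$fn + x$fp + x$tn))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(truth = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Confusion matrix from scores at a threshold
#'
#' A case is predicted positive iff its score is at least `threshold`.
#'
#' @param labels 0/1 truth vector.
#' @param scores numeric scores, same length.
#' @param threshold decision threshold (default 0.5).
#' @return a [confusion_matrix()].
#' @export
confusion_from_scores <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores)) stop("labels and scores differ in length")
  pred <- as.numeric(scores >= threshold)
  confusion_matrix(tp = sum(labels == 1 & pred == 1),
                   fn = sum(labels == 1 & pred == 0),
                   fp = sum(labels == 0 & pred == 1),
                   tn = sum(labels == 0 & pred == 0))
}

#' Pool per-fold confusion matrices
#'
#' Elementwise sum over folds: with every case tested exactly once across
#' the cross-validation, the pooled matrix is the confusion matrix of the
#' whole dataset.
#'
#' @param cms non-empty list of [confusion_matrix()] objects.
#' @return a [confusion_matrix()].
#' @export
pool_confusions <- function(cms) {
  if (length(cms) == 0) stop("need at least one confusion matrix")
  confusion_matrix(tp = sum(vapply(cms, `[[`, 1, "tp")),
                   fn = sum(vapply(cms, `[[`, 1, "fn")),
                   fp = sum(vapply(cms, `[[`, 1, "fp")),
                   tn = sum(vapply(cms, `[[`, 1, "tn")))
}

.wilson_ci <- function(x, n) {
  if (n == 0) return(c(NA_real_, NA_real_))
  # prop.test warns about the chi-squared *test* approximation at small
  # counts; the Wilson interval itself is exactly what we want
  ci <- suppressWarnings(stats::prop.test(x, n, correct = FALSE)$conf.int)
  100 * as.numeric(ci)
}

#' Accuracy, precision and recall with Wilson intervals
#'
#' Percentages with 95% Wilson score intervals. A metric whose denominator
#' is zero is reported as `NA` rather than fabricated.
#'
#' @param cm a [confusion_matrix()].
#' @return an object of class `metric_report`: a data frame with one row
#'   per metric (`estimate`, `lo`, `hi`, all in percent).
#' @export
metrics_from_confusion <- function(cm) {
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  pp <- cm$tp + cm$fp   # predicted positive
  ap <- cm$tp + cm$fn   # actual positive
  row <- function(x, d) {
    if (d == 0) return(c(NA_real_, NA_real_, NA_real_))
    c(100 * x / d, .wilson_ci(x, d))
  }
  out <- rbind(accuracy = row(cm$tp + cm$tn, n),
               precision = row(cm$tp, pp),
               recall = row(cm$tp, ap))
  out <- as.data.frame(out)
  names(out) <- c("estimate", "lo", "hi")
  class(out) <- c("metric_report", class(out))
  out
}

#' @export
print.metric_report <- function(x, ...) {
  for (m in rownames(x)) {
    cat(sprintf("%-9s %6.2f%% (95%% CI %.2f-%.2f)\n",
                m, x[m, "estimate"], x[m, "lo"], x[m, "hi"]))
  }
  invisible(x)
}

#' Mann-Whitney AUC
#'
#' The probability that a random positive case scores above a random
#' negative one, ties counted half; computed from midranks, and identical
#' to the trapezoidal area under the ROC curve.
#'
#' @param labels 0/1 truth vector (both classes present).
#' @param scores numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(labels, scores) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Sweeps the decision threshold over the distinct score values (ties
#' grouped) and returns the (FPR, TPR) staircase from (0, 0) to (1, 1),
#' monotone in both coordinates.
#'
#' @param labels 0/1 truth vector.
#' @param scores numeric scores.
#' @return data frame with columns `fpr`, `tpr`, `threshold`.
#' @export
roc_curve <- function(labels, scores) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  keep <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tie group
  tpr <- cumsum(y)[keep] / n1
  fpr <- cumsum(1 - y)[keep] / n0
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
             threshold = c(Inf, s[keep]))
}

#' Trapezoidal area under a ROC curve
#' @param curve data frame from [roc_curve()].
#' @return numeric area.
#' @export
roc_auc_trapezoid <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

# Midrank-based DeLong structural components: V10 per positive case, V01
# per negative case (Sun & Xu fast formulation).
.delong_components <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stop("both classes must be present")
  r_all <- rank(c(pos, neg))
  r_pos <- rank(pos); r_neg <- rank(neg)
  v10 <- (r_all[1:m] - r_pos) / n
  v01 <- 1 - (r_all[(m + 1):(m + n)] - r_neg) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong variance of a single AUC
#'
#' @param labels 0/1 truth vector.
#' @param scores numeric scores.
#' @return estimated variance of the AUC estimator.
#' @export
delong_auc_variance <- function(labels, scores) {
  cp <- .delong_components(labels, scores)
  stats::var(cp$v10) / length(cp$v10) + stats::var(cp$v01) / length(cp$v01)
}

#' Paired DeLong comparison of two correlated AUCs
#'
#' Both score vectors come from the same cases (paired design). The
#' structural-components estimator gives the variances of and covariance
#' between the two AUCs; the difference is tested with a two-sided normal
#' z statistic. When the variance of the difference degenerates to zero,
#' an exactly zero difference yields p = 1 by convention and a nonzero one
#' is flagged degenerate.
#'
#' @param labels 0/1 truth vector shared by both classifiers.
#' @param scores_a,scores_b score vectors of the two classifiers.
#' @return an object of class `delong_comparison`: list with `auc_a`,
#'   `auc_b`, `delta`, `var_delta`, `z`, `p_value`, `ci_a`, `ci_b` (95%
#'   normal intervals on each AUC) and `degenerate`.
#' @export
delong_paired_test <- function(labels, scores_a, scores_b) {
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  ca <- .delong_components(labels, scores_a)
  cb <- .delong_components(labels, scores_b)
  m <- length(ca$v10); n <- length(ca$v01)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  S <- s10 / m + s01 / n
  var_delta <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  delta <- ca$auc - cb$auc
  degenerate <- FALSE
  if (var_delta <= 0) {
    if (delta == 0) {
      z <- 0; p <- 1
    } else {
      z <- NA_real_; p <- NA_real_; degenerate <- TRUE
    }
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  ci <- function(auc, v) pmin(pmax(auc + c(-1, 1) * 1.959963984540054 * sqrt(v), 0), 1)
  structure(list(auc_a = ca$auc, auc_b = cb$auc, delta = delta,
                 var_delta = var_delta, z = z, p_value = p,
                 ci_a = ci(ca$auc, S[1, 1]), ci_b = ci(cb$auc, S[2, 2]),
                 degenerate = degenerate),
            class = "delong_comparison")
}

#' @export
print.delong_comparison <- function(x, ...) {
  cat(sprintf("paired DeLong test: AUC %.4f (95%% CI %.4f-%.4f) vs %.4f (95%% CI %.4f-%.4f)\n",
              x$auc_a, x$ci_a[1], x$ci_a[2], x$auc_b, x$ci_b[1], x$ci_b[2]))
  if (x$degenerate) {
    cat("  degenerate: zero variance with nonzero AUC difference\n")
  } else {
    cat(sprintf("  delta = %.4f, z = %.3f, two-sided p = %.4g\n",
                x$delta, x$z, x$p_value))
  }
  invisible(x)
}

#' Reconstruct integer confusion matrices from printed precision/recall
#'
#' Exhaustive integer search: given the class totals and a (precision,
#' recall) pair printed at two decimals, finds every confusion matrix whose
#' recall `100*TP/n_pos` and precision `100*TP/(TP+FP)` round (half away
#' from zero) to the printed values. A published table row is internally
#' consistent when the result is unique and its accuracy matches the
#' printed accuracy.
#'
#' @param n_pos,n_neg class totals (actual positives/negatives).
#' @param recall_2dp,precision_2dp printed values in percent, two decimals.
#' @return list of [confusion_matrix()] candidates (possibly empty).
#' @export
reconstruct_confusion_from_printed <- function(n_pos, n_neg, recall_2dp,
                                               precision_2dp) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  out <- list()
  eq2 <- function(a, b) abs(a - b) < 1e-9
  for (tp in 0:n_pos) {
    if (!eq2(round_half_away(100 * tp / n_pos, 2), recall_2dp)) next
    for (fp in 0:n_neg) {
      if (tp + fp == 0) next
      if (eq2(round_half_away(100 * tp / (tp + fp), 2), precision_2dp)) {
        out[[length(out) + 1L]] <-
          confusion_matrix(tp = tp, fn = n_pos - tp, fp = fp, tn = n_neg - fp)
      }
    }
  }
  out
}
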