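#' Reported clinical cross-validation performance table
#'
#' Reference values from the clinical appendicitis-vs-diverticulitis
#' evaluation of the RGB-superposition method: pooled 5-fold accuracy,
#' precision and recall (percent, two decimals) and AUC for three
#' EfficientNet backbones, each trained on single-slice ("original") and on
#' RGB superposition inputs, over 1,959 appendicitis (positive) and 823
#' diverticulitis (negative) slice images. These printed values serve as
#' inputs to the integer consistency check of
#' [reconstruct_confusion_from_printed()]: each row's precision and recall
#' determine a unique integer confusion matrix whose accuracy must
#' reproduce the printed accuracy.
#'
#' @return data frame with columns `backbone`, `input`, `accuracy`,
#'   `precision`, `recall`, `auc`, `n_pos`, `n_neg`.
#' @export
published_performance <- function() {
  data.frame(
    backbone = rep(c("EfficientNetB0", "EfficientNetB2", "EfficientNetB4"), 2),
    input = rep(c("original", "superposition"), each = 3),
    accuracy = c(88.75, 90.47, 89.65, 90.98, 91.27, 91.98),
    precision = c(91.11, 92.78, 93.13, 92.91, 92.56, 93.40),
    recall = c(93.11, 93.77, 92.09, 94.38, 95.25, 95.35),
    auc = c(0.948, 0.955, 0.959, 0.956, 0.962, 0.967),
    n_pos = 1959L,
    n_neg = 823L,
    stringsAsFactors = FALSE
  )
}

#' Consistency check of a printed performance row
#'
#' Reconstructs all integer confusion matrices compatible with a row's
#' printed precision and recall, and reports whether the solution is unique
#' and whether its accuracy reproduces the printed accuracy at two
#' decimals.
#'
#' @param n_pos,n_neg class totals.
#' @param accuracy,precision,recall printed percentages (two decimals).
#' @return list with `n_candidates`, `unique`, `confusion` (the matrix when
#'   unique, else `NULL`), `accuracy` (reconstructed, percent) and
#'   `consistent`.
#' @export
check_printed_row <- function(n_pos, n_neg, accuracy, precision, recall) {
  cand <- reconstruct_confusion_from_printed(n_pos, n_neg, recall, precision)
  if (length(cand) != 1)
    return(list(n_candidates = length(cand), unique = FALSE,
                confusion = NULL, accuracy = NA_real_, consistent = FALSE))
  cm <- cand[[1]]
  acc <- round_half_away(100 * (cm$tp + cm$tn) / (cm$tp + cm$fn + cm$fp + cm$tn), 2)
  list(n_candidates = 1L, unique = TRUE, confusion = cm, accuracy = acc,
       consistent = abs(acc - accuracy) < 1e-9)
}
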