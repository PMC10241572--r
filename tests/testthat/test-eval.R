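test_that("confusion counting follows the positive-class definitions", {
  cm <- confusion_from_scores(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))
  expect_equal(unlist(unclass(cm)), c(tp = 1, fn = 1, fp = 1, tn = 1))
  cm2 <- confusion_from_scores(c(1, 0, 1), c(0.8, 0.9, 0.99))
  expect_equal(cm2$fn + cm2$tn, 0)
  cm3 <- confusion_from_scores(c(1, 0), c(0.0, 0.0), threshold = 0)
  expect_equal(cm3$fn + cm3$tn, 0)
  expect_error(confusion_from_scores(c(1, 0), c(0.5)), "length")
})

test_that("pooling sums elementwise and keeps totals", {
  a <- confusion_matrix(1, 2, 3, 4)
  b <- confusion_matrix(4, 3, 2, 1)
  p <- pool_confusions(list(a, b))
  expect_equal(unlist(unclass(p)), c(tp = 5, fn = 5, fp = 5, tn = 5))
  expect_equal(unclass(pool_confusions(list(a))), unclass(a))
  expect_error(pool_confusions(list()), "at least one")
})

test_that("pooled metrics equal metrics on the unpartitioned predictions", {
  set.seed(10)
  for (rep in 1:5) {
    n <- 120
    labels <- rbinom(n, 1, 0.6)
    scores <- runif(n)
    folds <- sample(rep(1:4, length.out = n))
    cms <- lapply(1:4, function(f)
      confusion_from_scores(labels[folds == f], scores[folds == f]))
    pooled <- metrics_from_confusion(pool_confusions(cms))
    direct <- metrics_from_confusion(confusion_from_scores(labels, scores))
    expect_equal(pooled, direct)
  }
})

test_that("metrics reproduce a pooled clinical confusion matrix to 2 dp", {
  m <- metrics_from_confusion(confusion_matrix(1868, 91, 132, 691))
  expect_equal(round_half_away(m["accuracy", "estimate"], 2), 91.98)
  expect_equal(round_half_away(m["precision", "estimate"], 2), 93.40)
  expect_equal(round_half_away(m["recall", "estimate"], 2), 95.35)
  expect_true(all(m$lo <= m$estimate & m$estimate <= m$hi))
})

test_that("degenerate and symmetric confusion matrices behave", {
  perfect <- metrics_from_confusion(confusion_matrix(10, 0, 0, 10))
  expect_equal(perfect$estimate, c(100, 100, 100))
  even <- metrics_from_confusion(confusion_matrix(5, 5, 5, 5))
  expect_equal(even$estimate, c(50, 50, 50))
  nopos <- metrics_from_confusion(confusion_matrix(0, 0, 0, 10))
  expect_true(is.na(nopos["precision", "estimate"]))
  expect_true(is.na(nopos["recall", "estimate"]))
  expect_equal(nopos["accuracy", "estimate"], 100)
})

test_that("rank AUC matches brute-force pair counting", {
  labels <- c(1, 1, 1, 0, 0, 0)
  scores <- c(0.9, 0.8, 0.4, 0.7, 0.3, 0.2)
  expect_equal(auc_mann_whitney(labels, scores), 8 / 9)
  expect_equal(auc_mann_whitney(labels, scores), auc_brute_force(labels, scores))
  expect_equal(auc_mann_whitney(c(1, 1, 0), c(5, 4, 1)), 1)
  expect_equal(auc_mann_whitney(c(1, 0, 1, 0), rep(0.3, 4)), 0.5)
  expect_error(auc_mann_whitney(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("rank AUC equals trapezoidal ROC area, with ties", {
  set.seed(123)
  for (rep in 1:30) {
    n <- sample(10:200, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- sample(round(runif(n), sample(c(1, 2, 6), 1)))  # forces ties
    curve <- roc_curve(labels, scores)
    expect_true(all(diff(curve$fpr) >= 0))
    expect_true(all(diff(curve$tpr) >= 0))
    expect_equal(roc_auc_trapezoid(curve), auc_mann_whitney(labels, scores),
                 tolerance = 1e-12)
    expect_equal(auc_mann_whitney(labels, scores), auc_brute_force(labels, scores))
  }
})

test_that("identical classifiers give a null DeLong comparison", {
  set.seed(2)
  labels <- rbinom(60, 1, 0.5); labels[1:2] <- c(0, 1)
  s <- runif(60)
  d <- delong_paired_test(labels, s, s)
  expect_equal(d$delta, 0)
  expect_equal(d$p_value, 1)
  expect_false(d$degenerate)
})

test_that("joint relabeling leaves the paired comparison unchanged", {
  set.seed(3)
  n <- 80
  labels <- rbinom(n, 1, 0.5); labels[1:2] <- c(0, 1)
  a <- runif(n) + 0.5 * labels
  b <- runif(n) + 0.3 * labels
  d1 <- delong_paired_test(labels, a, b)
  perm <- sample(n)
  d2 <- delong_paired_test(labels[perm], a[perm], b[perm])
  expect_equal(d1$delta, d2$delta)
  expect_equal(d1$p_value, d2$p_value)
  expect_equal(d1$var_delta, d2$var_delta)
})

test_that("the DeLong machinery agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  n <- 100
  labels <- rbinom(n, 1, 0.5); labels[1:2] <- c(0, 1)
  a <- runif(n) + 0.8 * labels
  b <- runif(n) + 0.4 * labels
  ours <- delong_paired_test(labels, a, b)
  ra <- pROC::roc(labels, a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(labels, b, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(ours$auc_a, as.numeric(pROC::auc(ra)))
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  v <- delong_auc_variance(labels, a)
  expect_equal(v, as.numeric(pROC::var(ra, method = "delong")),
               tolerance = 1e-10)
})

test_that("the DeLong variance tracks the sampling variance of the AUC", {
  # resimulate a fixed score-generating model and compare the mean DeLong
  # variance with the empirical variance of the AUC across replicates
  gen <- function() {
    labels <- rep(c(1, 0), each = 100)
    scores <- rnorm(200, mean = labels)
    list(labels = labels, scores = scores)
  }
  set.seed(8)
  aucs <- numeric(2000); vars <- numeric(2000)
  for (i in 1:2000) {
    d <- gen()
    aucs[i] <- auc_mann_whitney(d$labels, d$scores)
    vars[i] <- delong_auc_variance(d$labels, d$scores)
  }
  expect_lt(abs(mean(vars) - var(aucs)) / var(aucs), 0.15)
})

test_that("degenerate paired comparisons are flagged, not fabricated", {
  labels <- c(1, 1, 0, 0)
  d <- delong_paired_test(labels, c(1, 1, 0, 0), c(0.9, 0.9, 0.1, 0.1))
  # both separate perfectly: zero variance, zero difference
  expect_equal(d$p_value, 1)
  d2 <- delong_paired_test(labels, c(1, 1, 0, 0), c(0.1, 0.1, 0.9, 0.9))
  expect_true(d2$degenerate)
  expect_true(is.na(d2$p_value))
})

test_that("printed rows reconstruct to unique integer confusion matrices", {
  r <- reconstruct_confusion_from_printed(1959, 823, 95.35, 93.40)
  expect_length(r, 1)
  expect_equal(unlist(unclass(r[[1]])), c(tp = 1868, fn = 91, fp = 132, tn = 691))
  r2 <- reconstruct_confusion_from_printed(1959, 823, 93.11, 91.11)
  expect_length(r2, 1)
  expect_equal(unlist(unclass(r2[[1]])), c(tp = 1824, fn = 135, fp = 178, tn = 645))
  r3 <- reconstruct_confusion_from_printed(10, 10, 100, 100)
  expect_length(r3, 1)
  expect_equal(unlist(unclass(r3[[1]])), c(tp = 10, fn = 0, fp = 0, tn = 10))
  # inconsistent pair: empty candidate set is reported, not invented
  expect_length(reconstruct_confusion_from_printed(10, 10, 95, 95), 0)
})
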