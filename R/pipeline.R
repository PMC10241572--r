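#' Pipeline configuration
#'
#' Resolved settings for a full two-arm phantom experiment: generate a
#' phantom cohort, build both input representations (RGB superposition and
#' single-slice), run patient-grouped k-fold cross-validation with the
#' reference CNN on each arm, and compare the pooled results.
#'
#' @param n_per_class phantom patients per class.
#' @param k number of cross-validation folds.
#' @param phantom a [phantom_spec()].
#' @param window a [window_spec()].
#' @param resolution classifier input side length in pixels.
#' @param train a [train_config()] (its `seed` is overridden by seeds
#'   derived from `seed`).
#' @param augment an [augment_params()] used when balancing.
#' @param balance balance training classes by augmentation (a no-op when
#'   classes are already equal).
#' @param val_frac fraction of training patients held out (grouped) for the
#'   early-stopping validation loss.
#' @param positive_label class label coded 1 (the phantom's `"tubular"`).
#' @param seed master seed; every other seed is derived from it.
#' @return an object of class `run_config`.
#' @export
run_config <- function(n_per_class = 100L, k = 2L, phantom = phantom_spec(),
                       window = window_spec(), resolution = 32L,
                       train = train_config(max_epochs = 80L, batch_size = 16L,
                                            base_lr = 3e-3, reduced_lr = 1e-3,
                                            lr_switch_epoch = 50L,
                                            early_stop_patience = 15L,
                                            resolution = resolution),
                       augment = augment_params(), balance = TRUE,
                       val_frac = 0.15, positive_label = "tubular",
                       seed = 1L) {
  structure(list(n_per_class = as.integer(n_per_class), k = as.integer(k),
                 phantom = phantom, window = window,
                 resolution = as.integer(resolution), train = train,
                 augment = augment, balance = isTRUE(balance),
                 val_frac = val_frac, positive_label = positive_label,
                 seed = as.integer(seed)),
            class = "run_config")
}

.derived_seed <- function(seed, ...) {
  h <- as.numeric(seed)
  for (v in c(...)) h <- (h * 131 + as.numeric(v) * 7919 + 17) %% 2147483629
  as.integer(h)
}

#' Run the full two-arm phantom experiment
#'
#' Executes the comparison the package exists for: the same reference CNN
#' is trained on RGB superposition images (previous/current/next slice in
#' R/G/B) and on single-slice images (current slice replicated across the
#' three channels), under identical patient-grouped folds, seeds and
#' budgets. Test scores are pooled over folds into one confusion matrix and
#' ROC per arm, and the two pooled AUCs are compared with the paired DeLong
#' test.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return an object of class `fusion_report`: list with `config_summary`,
#'   `arms` (per-arm pooled metrics, AUC, ROC curve, per-record scores) and
#'   `comparison` (DeLong test of superposition vs single-slice AUC).
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  say("generating phantom cohort (%d patients/class)", config$n_per_class)
  cohort <- generate_cohort(config$n_per_class, config$phantom,
                            seed = .derived_seed(config$seed, 1))
  say("building superposition images for %d annotated slices",
      nrow(cohort$manifest))
  sup_images <- list()
  for (ann in cohort$annotations) {
    id <- sprintf("%s_s%02d", ann$patient_id, ann$slice_index)
    sup_images[[id]] <- make_superposition(cohort$volumes[[ann$patient_id]],
                                           ann, config$window,
                                           config$resolution)
  }
  orig_images <- lapply(sup_images, as_single_slice)
  manifest <- assign_patient_folds(cohort$manifest, config$k,
                                   seed = .derived_seed(config$seed, 2))
  arms <- list(superposition = sup_images, original = orig_images)
  results <- list()
  for (arm in names(arms)) {
    imgs <- arms[[arm]]
    scores <- numeric(0)
    fold_cms <- list()
    fold_info <- list()
    for (f in seq_len(config$k)) {
      sp <- split_fold(manifest, f)
      hv <- holdout_validation(sp$train, config$val_frac,
                               seed = .derived_seed(config$seed, 3, f))
      train_recs <- imgs[hv$train$id]
      if (config$balance &&
          length(unique(vapply(train_recs, function(r) r$source$label, ""))) == 2) {
        ap <- config$augment
        ap$seed <- .derived_seed(config$seed, 4, f)
        train_recs <- balance_classes(train_recs, ap)
      }
      train_ds <- images_to_dataset(train_recs, config$positive_label)
      val_ds <- images_to_dataset(imgs[hv$val$id], config$positive_label)
      test_ds <- images_to_dataset(imgs[sp$test$id], config$positive_label)
      tc <- config$train
      tc$seed <- .derived_seed(config$seed, 5, f)
      clf <- reference_cnn(config$resolution, seed = .derived_seed(config$seed, 6, f))
      say("[%s] fold %d/%d: training on %d images (val %d, test %d)",
          arm, f, config$k, ncol(train_ds$x), ncol(val_ds$x), ncol(test_ds$x))
      fit <- train_classifier(clf, train_ds, val_ds, tc)
      s <- predict(fit, test_ds)
      names(s) <- sp$test$id
      scores <- c(scores, s)
      fold_cms[[f]] <- confusion_from_scores(test_ds$y, s)
      fold_info[[f]] <- list(epochs_run = nrow(fit$history),
                             best_epoch = fit$best_epoch,
                             best_val_loss = min(fit$history$val_loss))
    }
    real <- manifest[!manifest$fake, ]
    scores <- scores[real$id]
    labels <- labels_to_binary(real$label, config$positive_label)
    cm <- pool_confusions(fold_cms)
    results[[arm]] <- list(scores = scores, labels = labels,
                           confusion = cm,
                           metrics = metrics_from_confusion(cm),
                           auc = auc_mann_whitney(labels, scores),
                           roc = roc_curve(labels, scores),
                           folds = fold_info)
  }
  comparison <- delong_paired_test(results$superposition$labels,
                                   results$superposition$scores,
                                   results$original$scores)
  structure(list(
    config_summary = list(
      seed = config$seed, k = config$k, n_per_class = config$n_per_class,
      resolution = config$resolution, positive_label = config$positive_label,
      window = unclass(config$window), phantom = unclass(config$phantom),
      train = unclass(config$train), augment = unclass(config$augment),
      balance = config$balance, val_frac = config$val_frac),
    manifest = manifest,
    arms = results,
    comparison = comparison), class = "fusion_report")
}

#' @export
print.fusion_report <- function(x, ...) {
  cat("two-arm phantom experiment\n")
  for (arm in names(x$arms)) {
    r <- x$arms[[arm]]
    cat(sprintf("  %-13s accuracy %6.2f%%, AUC %.4f\n",
                arm, r$metrics["accuracy", "estimate"], r$auc))
  }
  cat(sprintf("  DeLong (superposition vs original): delta AUC %.4f, p = %.4g\n",
              x$comparison$delta, x$comparison$p_value))
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' Serialises the resolved configuration, per-arm pooled metrics and the
#' DeLong comparison (scores and curves included) so a run can be archived
#' and reproduced.
#'
#' @param report a `fusion_report`.
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  arms <- lapply(report$arms, function(r) {
    list(confusion = unclass(r$confusion),
         metrics = as.data.frame(r$metrics),
         auc = r$auc,
         roc = r$roc,
         scores = as.list(r$scores),
         folds = r$folds)
  })
  out <- list(config = report$config_summary,
              arms = arms,
              comparison = unclass(report$comparison))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
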