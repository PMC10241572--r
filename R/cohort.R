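#' Build a dataset manifest
#'
#' A manifest is a data frame with one row per image record: `id`,
#' `patient_id`, `label`, `fold` (NA until assigned) and `fake`.
#'
#' @param id record identifiers (unique).
#' @param patient_id patient identifier per record.
#' @param label class label per record.
#' @param fake logical per record; synthesized (augmented) images are fake.
#' @return a manifest data frame.
#' @export
build_manifest <- function(id, patient_id, label, fake = FALSE) {
  df <- data.frame(id = as.character(id),
                   patient_id = as.character(patient_id),
                   label = as.character(label),
                   fold = NA_integer_,
                   fake = as.logical(fake),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("record ids must be unique")
  df
}

#' Assign patient-grouped cross-validation folds
#'
#' Partitions *patients* (never single images) into `k` folds so that every
#' image inherits its patient's fold and no patient straddles folds. Within
#' each class, patients are sorted by descending image count (ties shuffled
#' by `seed`) and assigned greedily to the currently lightest fold by image
#' count (ties broken by lowest fold index). This balances image counts
#' across folds while keeping patients intact, the grouping that prevents a
#' classifier from being tested on patients it trained on.
#'
#' @param manifest a manifest data frame (see [build_manifest()]).
#' @param k number of folds (>= 2); each class must have at least `k`
#'   patients.
#' @param seed integer seed for tie shuffling.
#' @return the manifest with its `fold` column filled (integers in `1..k`).
#' @export
assign_patient_folds <- function(manifest, k = 5, seed = 1L) {
  stopifnot(k >= 2)
  pl <- unique(manifest[, c("patient_id", "label")])
  if (anyDuplicated(pl$patient_id))
    stop("a patient carries more than one class label")
  counts <- table(manifest$patient_id)
  loads <- numeric(k)
  fold_of <- integer(0)
  set.seed(seed)
  for (cls in sort(unique(pl$label))) {
    pats <- pl$patient_id[pl$label == cls]
    if (length(pats) < k)
      stop("class '", cls, "' has fewer than k = ", k, " patients")
    n_img <- as.numeric(counts[pats])
    ord <- order(-n_img, sample(length(pats)))
    for (j in ord) {
      f <- which.min(loads)  # which.min takes the lowest index on ties
      loads[f] <- loads[f] + n_img[j]
      fold_of[pats[j]] <- f
    }
  }
  manifest$fold <- as.integer(fold_of[manifest$patient_id])
  manifest
}

#' Split a manifest into train and test records for one fold
#'
#' The test set is the given fold's *real* records only (synthesized images
#' never reach a test set); the training set is everything else, fakes
#' included. Train and test never share a patient.
#'
#' @param manifest a manifest with assigned folds.
#' @param fold_index fold to hold out (1-based).
#' @return list with `train` and `test` manifest subsets.
#' @export
split_fold <- function(manifest, fold_index) {
  if (anyNA(manifest$fold)) stop("folds not assigned; run assign_patient_folds()")
  if (!fold_index %in% manifest$fold) stop("unknown fold index ", fold_index)
  in_fold <- manifest$fold == fold_index
  list(train = manifest[!in_fold, , drop = FALSE],
       test = manifest[in_fold & !manifest$fake, , drop = FALSE])
}

#' Hold out a fraction of training patients for validation
#'
#' Splits a training manifest by patient (grouped, per class) so early
#' stopping can watch a validation loss that shares no patients with the
#' training images.
#'
#' @param train_manifest manifest subset used for training.
#' @param frac fraction of patients (per class) moved to validation.
#' @param seed integer seed.
#' @return list with `train` and `val` manifest subsets.
#' @export
holdout_validation <- function(train_manifest, frac = 0.2, seed = 1L) {
  pl <- unique(train_manifest[, c("patient_id", "label")])
  set.seed(seed)
  val_pat <- character(0)
  for (cls in sort(unique(pl$label))) {
    pats <- pl$patient_id[pl$label == cls]
    n_val <- max(1L, floor(frac * length(pats)))
    val_pat <- c(val_pat, sample(pats, n_val))
  }
  in_val <- train_manifest$patient_id %in% val_pat
  list(train = train_manifest[!in_val, , drop = FALSE],
       val = train_manifest[in_val & !train_manifest$fake, , drop = FALSE])
}
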