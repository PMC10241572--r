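#' Augmentation parameter ranges
#'
#' Ranges for the four geometric augmentations (rotation, width shift,
#' height shift, zoom) drawn uniformly and independently per generated
#' image. Defaults: rotation within +/-15 degrees, shifts within +/-10% of
#' the image extent, zoom in `[0.9, 1.1]`.
#'
#' @param rotation_deg_range length-2 numeric, degrees.
#' @param shift_frac_range length-2 numeric, fraction of width/height
#'   (drawn independently for the two axes).
#' @param zoom_range length-2 numeric, both entries > 0.
#' @param seed integer seed used when drawing augmentations in batch
#'   operations such as [balance_classes()].
#' @return an object of class `augment_params`.
#' @export
augment_params <- function(rotation_deg_range = c(-15, 15),
                           shift_frac_range = c(-0.1, 0.1),
                           zoom_range = c(0.9, 1.1),
                           seed = 1L) {
  stopifnot(length(rotation_deg_range) == 2, length(shift_frac_range) == 2,
            length(zoom_range) == 2)
  if (diff(rotation_deg_range) < 0 || diff(shift_frac_range) < 0 ||
      diff(zoom_range) < 0)
    stop("parameter ranges must be ordered (lo <= hi)")
  if (any(zoom_range <= 0)) stop("zoom bounds must be > 0")
  structure(list(rotation_deg_range = rotation_deg_range,
                 shift_frac_range = shift_frac_range,
                 zoom_range = zoom_range,
                 seed = as.integer(seed)),
            class = "augment_params")
}

#' Draw one set of augmentation values from parameter ranges
#'
#' Uses the current RNG stream; callers seed it (see [balance_classes()]).
#'
#' @param params an [augment_params()].
#' @return list with `rotation_deg`, `shift_x_frac`, `shift_y_frac`, `zoom`.
#' @export
draw_augmentation <- function(params) {
  u <- function(r) stats::runif(1, r[1], r[2])
  list(rotation_deg = u(params$rotation_deg_range),
       shift_x_frac = u(params$shift_frac_range),
       shift_y_frac = u(params$shift_frac_range),
       zoom = u(params$zoom_range))
}

#' Apply a geometric augmentation to a superposition image
#'
#' Applies rotation, then shift, then zoom about the image centre, with
#' bilinear interpolation and reflect padding; all three channels receive
#' the identical transform, and the output keeps the input's shape, 8-bit
#' range and metadata. The identity transform returns the image pixelwise
#' unchanged.
#'
#' @param image a `superposition_image`.
#' @param rotation_deg rotation angle in degrees.
#' @param shift_x_frac,shift_y_frac translation as a fraction of the image
#'   width/height.
#' @param zoom zoom factor (> 0); values > 1 magnify.
#' @return an augmented `superposition_image`.
#' @export
augment_image <- function(image, rotation_deg = 0, shift_x_frac = 0,
                          shift_y_frac = 0, zoom = 1) {
  stopifnot(inherits(image, "superposition_image"))
  if (zoom <= 0) stop("zoom must be > 0")
  out <- image
  for (ch in 1:3) {
    w <- .affine_warp(image$pixels[, , ch], rotation_deg, shift_x_frac,
                      shift_y_frac, zoom)
    out$pixels[, , ch] <- pmin(pmax(round_half_away(w), 0), 255)
  }
  out
}

#' Number of synthetic records needed to balance a minority class
#'
#' @param minority_count,majority_count class sizes.
#' @param target_ratio desired minority/majority ratio after balancing
#'   (default 1, exact parity).
#' @return non-negative integer count of records to synthesize.
#' @export
n_fakes_needed <- function(minority_count, majority_count, target_ratio = 1) {
  max(0L, as.integer(round_half_away(target_ratio * majority_count)) -
        as.integer(minority_count))
}

#' Balance classes by augmenting the minority class
#'
#' Synthesizes augmented copies of minority-class images, cycling through
#' the minority records with fresh random draws, until the minority count
#' reaches `round(target_ratio * majority count)`. Originals are always
#' preserved; synthesized images carry `fake = TRUE`. Apply to *training*
#' records only, after fold splitting, so no synthetic image can leak into
#' a test fold.
#'
#' @param records list of `superposition_image` objects (their
#'   `source$label` fields carry the class).
#' @param params an [augment_params()]; its `seed` makes the draws
#'   reproducible.
#' @param target_ratio desired minority/majority ratio (default 1).
#' @return list of `superposition_image`, the originals followed by the
#'   synthesized images.
#' @export
balance_classes <- function(records, params = augment_params(),
                            target_ratio = 1) {
  labels <- vapply(records, function(r) r$source$label, "")
  counts <- table(labels)
  if (length(counts) < 2) stop("balancing needs two classes present")
  minority_label <- names(counts)[which.min(counts)]
  n_fake <- n_fakes_needed(min(counts), max(counts), target_ratio)
  if (n_fake == 0) return(records)
  minority_idx <- which(labels == minority_label)
  if (length(minority_idx) == 0) stop("empty minority class")
  fakes <- vector("list", n_fake)
  set.seed(params$seed)
  for (j in seq_len(n_fake)) {
    src <- records[[minority_idx[(j - 1L) %% length(minority_idx) + 1L]]]
    d <- draw_augmentation(params)
    img <- augment_image(src, d$rotation_deg, d$shift_x_frac,
                         d$shift_y_frac, d$zoom)
    img$fake <- TRUE
    fakes[[j]] <- img
  }
  c(records, fakes)
}

#' Is a record a synthesized (augmented) image?
#' @param record a `superposition_image`.
#' @return logical.
#' @export
is_fake <- function(record) isTRUE(record$fake)
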