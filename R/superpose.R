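#' Extract the (previous, current, next) slice triplet
#'
#' Returns the stored-value grids of slices `i-1`, `i`, `i+1` around a
#' 0-based slice index, clamping at the volume boundary (the first slice is
#' its own predecessor and the last its own successor).
#'
#' @param volume a [ct_volume()].
#' @param slice_index 0-based axial slice index.
#' @return list with `prev`, `current`, `next_` stored grids and `indices`,
#'   the clamped 0-based triplet indices.
#' @export
extract_triplet <- function(volume, slice_index) {
  n <- n_slices(volume)
  if (n < 1) stop("empty volume")
  if (slice_index < 0 || slice_index >= n)
    stop("slice_index out of range [0, ", n - 1, "]")
  i <- as.integer(slice_index)
  idx <- c(max(i - 1L, 0L), i, min(i + 1L, n - 1L))
  list(prev = volume$slices[[idx[1] + 1L]],
       current = volume$slices[[idx[2] + 1L]],
       next_ = volume$slices[[idx[3] + 1L]],
       indices = idx)
}

.crop_box <- function(grid, box) {
  # box is 0-based half-open (x0, y0, w, h); rows = y, cols = x
  rows <- (box[2] + 1):(box[2] + box[4])
  cols <- (box[1] + 1):(box[1] + box[3])
  grid[rows, cols, drop = FALSE]
}

.prep_channel <- function(stored, box, volume, window, resolution) {
  hu <- raw_to_hu(.crop_box(stored, box), volume$rescale_slope,
                  volume$rescale_intercept)
  disp <- window_to_uint8(hu, window)
  out <- bilinear_resize(disp, resolution, resolution)
  pmin(pmax(round_half_away(out), 0), 255)
}

#' Build an RGB superposition image from a slice triplet
#'
#' Crops the previous, current and next axial slices at the *current*
#' slice's annotation box, converts each crop to Hounsfield units, windows
#' it to 8-bit display intensities, resizes it to `resolution` x
#' `resolution` (bilinear), and fuses the three crops into one colour image
#' with the fixed channel semantics red = previous slice, green = current
#' slice, blue = next slice. Cropping the neighbours at the current box
#' preserves the lesion's inter-slice displacement inside the crop, which is
#' the signal the 2.5D method exploits.
#'
#' @param volume a [ct_volume()].
#' @param annotation a [box_annotation()] on that volume.
#' @param window a [window_spec()]; defaults to the abdominal window.
#' @param resolution output side length in pixels (224, 260 and 380 match
#'   the standard EfficientNet input sizes; any positive integer works).
#' @return an object of class `superposition_image` with fields `pixels`
#'   (`resolution` x `resolution` x 3, integers in `[0, 255]`),
#'   `resolution`, `channel_map` and `source`.
#' @export
make_superposition <- function(volume, annotation, window = window_spec(),
                               resolution = 224) {
  stopifnot(inherits(volume, "ct_volume"), inherits(annotation, "box_annotation"))
  validate_annotation(annotation, volume)
  trip <- extract_triplet(volume, annotation$slice_index)
  box <- annotation$box
  px <- array(0, dim = c(resolution, resolution, 3))
  px[, , 1] <- .prep_channel(trip$prev, box, volume, window, resolution)
  px[, , 2] <- .prep_channel(trip$current, box, volume, window, resolution)
  px[, , 3] <- .prep_channel(trip$next_, box, volume, window, resolution)
  structure(list(pixels = px,
                 resolution = as.integer(resolution),
                 channel_map = c(R = "previous", G = "current", B = "next"),
                 source = list(patient_id = annotation$patient_id,
                               slice_index = annotation$slice_index,
                               label = annotation$label)),
            class = "superposition_image")
}

#' Replicate the current-slice channel into all three channels
#'
#' The "original image" comparison arm: the single annotated slice is
#' replicated across R, G and B so both arms share one classifier input
#' shape while this arm carries no inter-slice information.
#'
#' @param image a `superposition_image`.
#' @return a `superposition_image` whose three channels all equal the input
#'   green (current-slice) channel.
#' @export
as_single_slice <- function(image) {
  stopifnot(inherits(image, "superposition_image"))
  g <- image$pixels[, , 2]
  image$pixels[, , 1] <- g
  image$pixels[, , 3] <- g
  image$channel_map <- c(R = "current", G = "current", B = "current")
  image
}

#' @export
print.superposition_image <- function(x, ...) {
  cat(sprintf("RGB superposition image %d x %d (R=%s, G=%s, B=%s)\n",
              x$resolution, x$resolution,
              x$channel_map[1], x$channel_map[2], x$channel_map[3]))
  cat(sprintf("  source: patient %s, slice %d, label '%s'\n",
              x$source$patient_id, x$source$slice_index, x$source$label))
  invisible(x)
}

#' Write a superposition image as an 8-bit RGB PNG
#'
#' @param image a `superposition_image`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_superposition_png <- function(image, path) {
  stopifnot(inherits(image, "superposition_image"))
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}
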