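#' CT volume container
#'
#' An ordered stack of axial CT slices held as stored (pre-rescale) integer
#' matrices, together with the linear rescale to Hounsfield units and the
#' slice geometry. Slices are kept sorted ascending by position along the
#' scan axis.
#'
#' @param patient_id patient identifier string.
#' @param slices list of integer matrices, all the same dimensions, in
#'   ascending position order.
#' @param rescale_slope,rescale_intercept linear map from stored values to HU.
#' @param pixel_spacing numeric length-2, mm per pixel (row, column).
#' @param slice_positions numeric vector, mm along the scan axis, strictly
#'   monotone; one entry per slice.
#' @param slice_thickness slice thickness in mm.
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(patient_id, slices, rescale_slope = 1,
                      rescale_intercept = 0, pixel_spacing = c(1, 1),
                      slice_positions = NULL, slice_thickness = 1) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  if (!is.list(slices) || length(slices) < 1L)
    stop("a ct_volume needs at least one slice")
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all slices must share one shape")
  n <- length(slices)
  if (is.null(slice_positions))
    slice_positions <- seq_len(n) * slice_thickness
  if (length(slice_positions) != n)
    stop("one slice position per slice required")
  ord <- order(slice_positions)
  slice_positions <- slice_positions[ord]
  slices <- slices[ord]
  if (any(diff(slice_positions) <= 0))
    stop("slice positions must be strictly monotone")
  structure(list(patient_id = patient_id,
                 slices = slices,
                 rescale_slope = rescale_slope,
                 rescale_intercept = rescale_intercept,
                 pixel_spacing = as.numeric(pixel_spacing),
                 slice_positions = as.numeric(slice_positions),
                 slice_thickness = as.numeric(slice_thickness)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("CT volume '%s': %d axial slices of %d x %d px\n",
              x$patient_id, length(x$slices), d[1], d[2]))
  cat(sprintf("  rescale: HU = %g * stored %+g\n",
              x$rescale_slope, x$rescale_intercept))
  cat(sprintf("  spacing: %.3g x %.3g mm/px, thickness %g mm, positions %g..%g mm\n",
              x$pixel_spacing[1], x$pixel_spacing[2], x$slice_thickness,
              min(x$slice_positions), max(x$slice_positions)))
  invisible(x)
}

#' Number of slices in a volume
#' @param volume a [ct_volume()].
#' @return integer count.
#' @export
n_slices <- function(volume) length(volume$slices)

#' Extract one slice in Hounsfield units
#'
#' @param volume a [ct_volume()].
#' @param i slice index (1-based).
#' @return numeric matrix of HU values.
#' @export
hu_slice <- function(volume, i) {
  stopifnot(i >= 1, i <= n_slices(volume))
  raw_to_hu(volume$slices[[i]], volume$rescale_slope, volume$rescale_intercept)
}

#' Rectangular lesion annotation on one axial slice
#'
#' Boxes use 0-based, top-left-origin, half-open pixel coordinates (the
#' ImageJ convention): a box `(x0, y0, w, h)` covers columns `x0 .. x0+w-1`
#' and rows `y0 .. y0+h-1`.
#'
#' @param patient_id patient identifier.
#' @param slice_index 0-based axial slice index.
#' @param box numeric length-4 `(x0, y0, width, height)`.
#' @param label class label string (e.g. `"appendicitis"`).
#' @return an object of class `box_annotation`.
#' @export
box_annotation <- function(patient_id, slice_index, box, label) {
  stopifnot(length(box) == 4L, is.character(label), length(label) == 1L)
  box <- as.numeric(box)
  if (slice_index < 0) stop("slice_index must be >= 0")
  if (box[3] < 1 || box[4] < 1) stop("box width and height must be >= 1")
  if (box[1] < 0 || box[2] < 0) stop("box origin must be >= 0")
  structure(list(patient_id = as.character(patient_id),
                 slice_index = as.integer(slice_index),
                 box = box, label = label),
            class = "box_annotation")
}

#' @export
print.box_annotation <- function(x, ...) {
  cat(sprintf("annotation: patient %s, slice %d, box (x0=%g, y0=%g, w=%g, h=%g), label '%s'\n",
              x$patient_id, x$slice_index, x$box[1], x$box[2], x$box[3],
              x$box[4], x$label))
  invisible(x)
}

#' Check that an annotation's box lies inside a volume's slices
#'
#' @param annotation a [box_annotation()].
#' @param volume a [ct_volume()].
#' @return invisibly `TRUE`; errors when the box leaves the slice bounds or
#'   the slice index does not exist.
#' @export
validate_annotation <- function(annotation, volume) {
  d <- dim(volume$slices[[1]])
  b <- annotation$box
  if (annotation$slice_index >= n_slices(volume))
    stop("annotation slice index beyond volume")
  if (b[1] + b[3] > d[2] || b[2] + b[4] > d[1])
    stop("annotation box extends outside the slice")
  invisible(TRUE)
}
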