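#' Round half away from zero
#'
#' Deterministic rounding used everywhere a real value is quantised to an
#' integer grid (8-bit display values, stored CT values, percentage tables).
#' Unlike [base::round()], which rounds half to even, 0.5 maps to 1 and
#' -0.5 to -1.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 127.5))
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Display window specification
#'
#' A CT display window: the Hounsfield interval `[level - width/2,
#' level + width/2]` is mapped linearly onto display intensities. The default
#' is the standard abdominal soft-tissue window (level 40 HU, width 400 HU).
#'
#' @param level window centre in Hounsfield units.
#' @param width window width in Hounsfield units; must be positive.
#' @return an object of class `window_spec`.
#' @export
window_spec <- function(level = 40, width = 400) {
  stopifnot(is.numeric(level), length(level) == 1L,
            is.numeric(width), length(width) == 1L)
  if (width <= 0) stop("window width must be > 0")
  structure(list(level = level, width = width), class = "window_spec")
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("CT display window: level %g HU, width %g HU\n",
              x$level, x$width))
  invisible(x)
}

#' Convert stored CT values to Hounsfield units
#'
#' Applies the DICOM linear rescale `HU = slope * stored + intercept`.
#'
#' @param stored integer (or numeric) grid of stored pixel values.
#' @param slope rescale slope.
#' @param intercept rescale intercept in HU.
#' @return numeric grid of Hounsfield units, same shape as `stored`.
#' @export
raw_to_hu <- function(stored, slope = 1, intercept = 0) {
  slope * stored + intercept
}

#' Convert Hounsfield units back to stored values
#'
#' Inverse of [raw_to_hu()]; requires a nonzero slope.
#'
#' @param hu numeric grid in Hounsfield units.
#' @inheritParams raw_to_hu
#' @return numeric grid of stored values.
#' @export
hu_to_raw <- function(hu, slope = 1, intercept = 0) {
  if (slope == 0) stop("rescale slope must be nonzero")
  (hu - intercept) / slope
}

#' Window a Hounsfield grid to 8-bit display intensities
#'
#' Linearly maps `[level - width/2, level + width/2]` onto `[0, 255]`,
#' clamping outside the window, and quantises with half-away-from-zero
#' rounding.
#'
#' @param hu numeric grid in Hounsfield units.
#' @param window a [window_spec()].
#' @return grid of integers in `[0, 255]`, same shape as `hu`.
#' @export
#' @examples
#' w <- window_spec(40, 400)
#' window_to_uint8(c(-160, 40, 240), w)  # 0, 128, 255
window_to_uint8 <- function(hu, window = window_spec()) {
  if (!inherits(window, "window_spec")) window <- do.call(window_spec, as.list(window))
  lo <- window$level - window$width / 2
  y <- (hu - lo) / window$width * 255
  y <- pmin(pmax(y, 0), 255)
  out <- round_half_away(y)
  out[] <- as.numeric(out)
  out
}
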