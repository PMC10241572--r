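# Bilinear sampling primitives shared by resizing and augmentation.
# Conventions (used consistently package-wide): 1-based pixel centres, the
# image centre is at ((H+1)/2, (W+1)/2); resizing aligns half-pixel centres
# (source = (dest - 0.5) * scale + 0.5).

.fold_index <- function(x, n, pad) {
  if (n == 1L) return(rep(1, length(x)))
  if (pad == "clamp") return(pmin(pmax(x, 1), n))
  # symmetric reflection about the edge pixels, period 2(n-1)
  t <- abs(x - 1) %% (2 * (n - 1))
  1 + pmin(t, 2 * (n - 1) - t)
}

# Sample img at fractional (Y, X) coordinates with bilinear interpolation.
# Y and X share a dimension, which the result inherits.
.bilinear_sample <- function(img, Y, X, pad = c("clamp", "reflect")) {
  pad <- match.arg(pad)
  H <- nrow(img); W <- ncol(img)
  out_dim <- dim(Y)
  y <- as.vector(Y); x <- as.vector(X)
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  ya <- .fold_index(y0, H, pad); yb <- .fold_index(y0 + 1, H, pad)
  xa <- .fold_index(x0, W, pad); xb <- .fold_index(x0 + 1, W, pad)
  ya <- round(ya); yb <- round(yb); xa <- round(xa); xb <- round(xb)
  v <- (1 - fy) * (1 - fx) * img[cbind(ya, xa)] +
       (1 - fy) * fx       * img[cbind(ya, xb)] +
       fy       * (1 - fx) * img[cbind(yb, xa)] +
       fy       * fx       * img[cbind(yb, xb)]
  dim(v) <- out_dim
  v
}

#' Bilinear image resize
#'
#' Resizes a 2-D grid to `out_h` x `out_w` with bilinear interpolation,
#' aligning half-pixel centres and clamping at the borders. Constant images
#' resize to the same constant exactly.
#'
#' @param img numeric matrix.
#' @param out_h,out_w output dimensions.
#' @return numeric `out_h` x `out_w` matrix.
#' @export
bilinear_resize <- function(img, out_h, out_w = out_h) {
  H <- nrow(img); W <- ncol(img)
  ys <- (seq_len(out_h) - 0.5) * (H / out_h) + 0.5
  xs <- (seq_len(out_w) - 0.5) * (W / out_w) + 0.5
  Y <- matrix(ys, out_h, out_w)
  X <- matrix(xs, out_h, out_w, byrow = TRUE)
  .bilinear_sample(img, Y, X, pad = "clamp")
}

# Inverse-map an output pixel grid through rotate -> shift -> zoom about the
# image centre and sample the source with reflect padding. Angles in
# degrees, shifts as fractions of the image extent, zoom > 1 magnifies.
.affine_warp <- function(img, rotation_deg = 0, shift_x_frac = 0,
                         shift_y_frac = 0, zoom = 1) {
  if (zoom <= 0) stop("zoom must be > 0")
  H <- nrow(img); W <- ncol(img)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ty <- shift_y_frac * H; tx <- shift_x_frac * W
  # sinpi/cospi keep multiples of 90 degrees exact
  co <- cospi(rotation_deg / 180); si <- sinpi(rotation_deg / 180)
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  dy <- (yy - cy - ty) / zoom
  dx <- (xx - cx - tx) / zoom
  # inverse rotation
  Y <- co * dy - si * dx + cy
  X <- si * dy + co * dx + cx
  .bilinear_sample(img, Y, X, pad = "reflect")
}
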