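#' Gradient-weighted class activation map
#'
#' Standard Grad-CAM: each feature map is weighted by the global average of
#' the class-score gradient over that map, the weighted maps are summed,
#' negative evidence is clipped (ReLU), the map is upsampled bilinearly to
#' `target_size`, and finally scaled so its maximum is 1 (an all-zero map
#' stays all-zero). The result localises the evidence the classifier used
#' for the positive class.
#'
#' @param activations `h x w x K` array of feature maps (e.g. the last
#'   convolution block's post-ReLU output).
#' @param gradients `h x w x K` array of the class-score gradient with
#'   respect to each activation; same shape as `activations`.
#' @param target_size output side length(s); either one integer or
#'   `c(height, width)`.
#' @return a `target_size` matrix with values in `[0, 1]`.
#' @export
grad_cam <- function(activations, gradients, target_size) {
  if (!identical(dim(activations), dim(gradients)))
    stop("activations and gradients must share a shape")
  if (length(dim(activations)) != 3) stop("expected h x w x K arrays")
  if (length(target_size) == 1) target_size <- c(target_size, target_size)
  K <- dim(activations)[3]
  alpha <- apply(gradients, 3, mean)
  L <- matrix(0, dim(activations)[1], dim(activations)[2])
  for (k in seq_len(K)) L <- L + alpha[k] * activations[, , k]
  L[L < 0] <- 0
  up <- bilinear_resize(L, target_size[1], target_size[2])
  up[up < 0] <- 0
  mx <- max(up)
  if (mx > 0) up <- up / mx
  up
}
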