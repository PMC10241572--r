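# Small reference convolutional classifier: three 3x3 valid-convolution
# blocks (ReLU, 2x2 max pool after the first two), global average pooling
# and a single logit. Implemented with im2col gathers and BLAS matrix
# multiplies; images live as (H*W*C) x N column-major matrices with the
# channel as the outermost dimension.

.conv_geom <- function(H, W, C) {
  Ho <- H - 2L; Wo <- W - 2L
  if (Ho < 1 || Wo < 1) stop("input too small for a 3x3 valid convolution")
  oi <- rep(seq_len(Ho), Wo)
  oj <- rep(seq_len(Wo), each = Ho)
  base <- (oj - 1L) * H + oi                     # linear index of (oi, oj, ch 1)
  di <- rep(0:2, times = 3 * C)
  dj <- rep(rep(0:2, each = 3), C)
  cc <- rep(seq_len(C) - 1L, each = 9)
  offs <- cc * H * W + dj * H + di
  idx <- outer(offs, base, "+")                  # P x Q
  list(H = H, W = W, C = C, Ho = Ho, Wo = Wo,
       P = 9L * C, Q = Ho * Wo, idx = idx)
}

.he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

#' Construct the reference convolutional classifier
#'
#' A deliberately small, CPU-trainable 2D CNN fulfilling the pluggable
#' classifier contract: three 3x3 convolution blocks with ReLU (2x2 max
#' pooling after the first two), global average pooling, and one logit with
#' a sigmoid score for the positive class. Inputs are H x W x 3 images
#' scaled to `[0, 1]` (no ImageNet-style normalisation). Weight
#' initialisation is seeded and He-scaled.
#'
#' @param resolution input side length in pixels (>= 18).
#' @param channels integer length-3, feature maps per convolution block.
#' @param seed integer seed for weight initialisation.
#' @return an object of class `reference_cnn`.
#' @export
reference_cnn <- function(resolution = 32, channels = c(8L, 16L, 32L),
                          seed = 1L) {
  stopifnot(length(channels) == 3, resolution >= 18)
  r <- as.integer(resolution)
  ch <- as.integer(channels)
  g1 <- .conv_geom(r, r, 3L)
  h1p <- g1$Ho %/% 2L; w1p <- g1$Wo %/% 2L
  g2 <- .conv_geom(h1p, w1p, ch[1])
  h2p <- g2$Ho %/% 2L; w2p <- g2$Wo %/% 2L
  g3 <- .conv_geom(h2p, w2p, ch[2])
  set.seed(seed)
  params <- list(W1 = .he_init(ch[1], g1$P, g1$P), b1 = numeric(ch[1]),
                 W2 = .he_init(ch[2], g2$P, g2$P), b2 = numeric(ch[2]),
                 W3 = .he_init(ch[3], g3$P, g3$P), b3 = numeric(ch[3]),
                 w4 = matrix(stats::rnorm(ch[3], sd = 1 / sqrt(ch[3]))),
                 b4 = 0)
  adam <- list(m = lapply(params, function(p) p * 0),
               v = lapply(params, function(p) p * 0),
               t = 0L)
  structure(list(resolution = r, channels = ch,
                 g1 = g1, g2 = g2, g3 = g3,
                 params = params, adam = adam, seed = as.integer(seed)),
            class = "reference_cnn")
}

#' @export
print.reference_cnn <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 1L))
  cat(sprintf("reference CNN: input %d x %d x 3, conv channels %s, %d parameters\n",
              x$resolution, x$resolution,
              paste(x$channels, collapse = "/"), n_par))
  invisible(x)
}

.conv_forward <- function(X, g, W, b) {
  N <- ncol(X)
  cols <- X[as.vector(g$idx), , drop = FALSE]
  dim(cols) <- c(g$P, g$Q * N)
  Z <- W %*% cols + b
  A <- Z
  A[A < 0] <- 0
  Fc <- nrow(W)
  arr <- array(A, c(Fc, g$Q, N))
  Amat <- aperm(arr, c(2, 1, 3))
  dim(Amat) <- c(g$Q * Fc, N)
  list(out = Amat, cols = cols)
}

.conv_backward <- function(dOut, act, cols, g, W) {
  # dOut, act: (Q*F) x N in spatial-major layout
  N <- ncol(dOut)
  Fc <- nrow(W)
  dZ <- dOut
  dZ[act <= 0] <- 0
  arr <- array(dZ, c(g$Q, Fc, N))
  dZmat <- aperm(arr, c(2, 1, 3))
  dim(dZmat) <- c(Fc, g$Q * N)
  dW <- dZmat %*% t(array(cols, c(g$P, g$Q * N)))
  db <- rowSums(dZmat)
  dcols <- crossprod(W, dZmat)                   # P x (Q*N)
  dX <- matrix(0, g$H * g$W * g$C, N)
  for (p in seq_len(g$P)) {
    rows <- g$idx[p, ]
    dX[rows, ] <- dX[rows, ] + matrix(dcols[p, ], g$Q, N)
  }
  list(dW = dW, db = db, dX = dX)
}

.pool_forward <- function(X, H, W, Fc) {
  N <- ncol(X)
  arr <- array(X, c(H, W, Fc, N))
  He <- 2L * (H %/% 2L); We <- 2L * (W %/% 2L)
  ro <- seq(1L, He, 2L); re <- ro + 1L
  co <- seq(1L, We, 2L); ce <- co + 1L
  a1 <- arr[ro, co, , , drop = FALSE]; a2 <- arr[re, co, , , drop = FALSE]
  a3 <- arr[ro, ce, , , drop = FALSE]; a4 <- arr[re, ce, , , drop = FALSE]
  m <- pmax(a1, a2, a3, a4)
  s1 <- a1 == m
  s2 <- (a2 == m) & !s1
  s3 <- (a3 == m) & !(s1 | s2)
  s4 <- (a4 == m) & !(s1 | s2 | s3)
  Hp <- He %/% 2L; Wp <- We %/% 2L
  out <- m
  dim(out) <- c(Hp * Wp * Fc, N)
  list(out = out, sel = list(s1, s2, s3, s4),
       H = H, W = W, Fc = Fc, Hp = Hp, Wp = Wp)
}

.pool_backward <- function(dOut, pf) {
  N <- ncol(dOut)
  d <- array(dOut, c(pf$Hp, pf$Wp, pf$Fc, N))
  dX <- array(0, c(pf$H, pf$W, pf$Fc, N))
  He <- 2L * pf$Hp; We <- 2L * pf$Wp
  ro <- seq(1L, He, 2L); re <- ro + 1L
  co <- seq(1L, We, 2L); ce <- co + 1L
  dX[ro, co, , ] <- d * pf$sel[[1]]
  dX[re, co, , ] <- dX[re, co, , , drop = FALSE] + d * pf$sel[[2]]
  dX[ro, ce, , ] <- dX[ro, ce, , , drop = FALSE] + d * pf$sel[[3]]
  dX[re, ce, , ] <- dX[re, ce, , , drop = FALSE] + d * pf$sel[[4]]
  dim(dX) <- c(pf$H * pf$W * pf$Fc, N)
  dX
}

.cnn_forward <- function(model, X, keep = FALSE) {
  p <- model$params
  X <- X - 0.5    # centre [0,1] inputs so early layers start well-conditioned
  c1 <- .conv_forward(X, model$g1, p$W1, p$b1)
  pf1 <- .pool_forward(c1$out, model$g1$Ho, model$g1$Wo, model$channels[1])
  c2 <- .conv_forward(pf1$out, model$g2, p$W2, p$b2)
  pf2 <- .pool_forward(c2$out, model$g2$Ho, model$g2$Wo, model$channels[2])
  c3 <- .conv_forward(pf2$out, model$g3, p$W3, p$b3)
  Q3 <- model$g3$Q; F3 <- model$channels[3]
  feat <- colMeans(array(c3$out, c(Q3, F3, ncol(X))))
  dim(feat) <- c(F3, ncol(X))
  z <- as.vector(crossprod(p$w4, feat) + p$b4)
  out <- list(z = z, scores = stats::plogis(z))
  if (keep) out$cache <- list(c1 = c1, pf1 = pf1, c2 = c2, pf2 = pf2,
                              c3 = c3, feat = feat)
  out
}

.bce_loss <- function(z, y) {
  mean(pmax(z, 0) - y * z + log1p(exp(-abs(z))))
}

.adam_step <- function(model, grads, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  ad <- model$adam
  ad$t <- ad$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    ad$m[[nm]] <- beta1 * ad$m[[nm]] + (1 - beta1) * g
    ad$v[[nm]] <- beta2 * ad$v[[nm]] + (1 - beta2) * g^2
    mhat <- ad$m[[nm]] / (1 - beta1^ad$t)
    vhat <- ad$v[[nm]] / (1 - beta2^ad$t)
    model$params[[nm]] <- model$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  model$adam <- ad
  model
}

#' One gradient step of the classifier on a batch
#'
#' Part of the pluggable classifier contract: a single Adam update on a
#' batch under binary cross-entropy, returning the updated classifier and
#' the batch loss.
#'
#' @param classifier a classifier object (e.g. [reference_cnn()]).
#' @param x input matrix, one column per image (`resolution^2 * 3` rows,
#'   values in `[0, 1]`).
#' @param y numeric 0/1 labels, one per column of `x`.
#' @param lr learning rate for this step.
#' @return list with `classifier` (updated) and `loss`.
#' @export
fit_batch <- function(classifier, x, y, lr) UseMethod("fit_batch")

#' @export
fit_batch.reference_cnn <- function(classifier, x, y, lr) {
  model <- classifier
  N <- ncol(x)
  fw <- .cnn_forward(model, x, keep = TRUE)
  ca <- fw$cache
  loss <- .bce_loss(fw$z, y)
  dz <- (fw$scores - y) / N
  F3 <- model$channels[3]; Q3 <- model$g3$Q
  dw4 <- ca$feat %*% dz
  db4 <- sum(dz)
  dfeat <- model$params$w4 %*% matrix(dz, 1)     # F3 x N
  dA3 <- matrix(dfeat[rep(seq_len(F3), each = Q3), , drop = FALSE] / Q3,
                Q3 * F3, N)
  b3 <- .conv_backward(dA3, ca$c3$out, ca$c3$cols, model$g3, model$params$W3)
  dP2 <- .pool_backward(b3$dX, ca$pf2)
  b2 <- .conv_backward(dP2, ca$c2$out, ca$c2$cols, model$g2, model$params$W2)
  dP1 <- .pool_backward(b2$dX, ca$pf1)
  b1 <- .conv_backward(dP1, ca$c1$out, ca$c1$cols, model$g1, model$params$W1)
  grads <- list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db,
                W3 = b3$dW, b3 = b3$db, w4 = dw4, b4 = db4)
  model <- .adam_step(model, grads, lr)
  list(classifier = model, loss = loss)
}

#' Positive-class scores for a batch of images
#'
#' @param classifier a classifier object.
#' @param x input matrix, one column per image.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
predict_scores <- function(classifier, x) UseMethod("predict_scores")

#' @export
predict_scores.reference_cnn <- function(classifier, x) {
  .cnn_forward(classifier, x)$scores
}

#' Activations and gradients of the last convolutional stage
#'
#' The Grad-CAM probe of the classifier contract: for one image, the
#' post-ReLU feature maps of the final convolution block and the gradient
#' of the positive-class logit with respect to each of them.
#'
#' @param classifier a classifier object.
#' @param x input matrix with a single column (one image).
#' @return list with `activations` and `gradients`, both `h x w x K` arrays.
#' @export
cam_inputs <- function(classifier, x) UseMethod("cam_inputs")

#' @export
cam_inputs.reference_cnn <- function(classifier, x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == 1)
  fw <- .cnn_forward(classifier, x, keep = TRUE)
  g3 <- classifier$g3; F3 <- classifier$channels[3]
  A <- array(fw$cache$c3$out, c(g3$Ho, g3$Wo, F3))
  # logit = b4 + sum_k w4[k] * mean(A_k): the gradient is w4[k]/Q per cell
  G <- array(rep(classifier$params$w4 / g3$Q, each = g3$Ho * g3$Wo),
             c(g3$Ho, g3$Wo, F3))
  list(activations = A, gradients = G)
}

#' Pack superposition images into a classifier input matrix
#'
#' @param records list of `superposition_image` objects, all at one
#'   resolution.
#' @param positive_label label mapped to class 1.
#' @return list with `x` (input matrix, one column per image, values in
#'   `[0, 1]`) and `y` (0/1 labels).
#' @export
images_to_dataset <- function(records, positive_label) {
  stopifnot(length(records) >= 1)
  d <- records[[1]]$resolution^2 * 3
  x <- vapply(records, function(r) as.vector(r$pixels) / 255, numeric(d))
  y <- labels_to_binary(vapply(records, function(r) r$source$label, ""),
                        positive_label)
  list(x = x, y = y)
}
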