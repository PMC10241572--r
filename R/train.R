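#' Training configuration
#'
#' Defaults follow the published schedule: up to 200 epochs, batch size 64,
#' Adam at a base learning rate of 1e-4 dropped to 1e-5 once the epoch
#' number exceeds 30, and early stopping after 10 epochs without
#' validation-loss improvement.
#'
#' @param max_epochs maximum number of epochs.
#' @param batch_size minibatch size.
#' @param base_lr learning rate for epochs `1..lr_switch_epoch`.
#' @param reduced_lr learning rate afterwards; must be < `base_lr` (equal is
#'   allowed for a constant schedule).
#' @param lr_switch_epoch last epoch trained at `base_lr`.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (>= 1).
#' @param seed integer seed controlling shuffling (and any classifier
#'   initialisation derived from it).
#' @param resolution input image side length in pixels.
#' @return an object of class `train_config`.
#' @export
train_config <- function(max_epochs = 200L, batch_size = 64L,
                         base_lr = 1e-4, reduced_lr = 1e-5,
                         lr_switch_epoch = 30L, early_stop_patience = 10L,
                         seed = 1L, resolution = 32L) {
  if (reduced_lr > base_lr) stop("reduced_lr must not exceed base_lr")
  if (early_stop_patience < 1) stop("patience must be >= 1")
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 base_lr = base_lr, reduced_lr = reduced_lr,
                 lr_switch_epoch = as.integer(lr_switch_epoch),
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed),
                 resolution = as.integer(resolution)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' `base_lr` while `epoch <= lr_switch_epoch`, `reduced_lr` strictly after.
#'
#' @param epoch epoch number (1-based, >= 1).
#' @param config a [train_config()].
#' @return the learning rate.
#' @export
learning_rate_at <- function(epoch, config) {
  if (any(epoch < 1)) stop("epoch must be >= 1")
  ifelse(epoch <= config$lr_switch_epoch, config$base_lr, config$reduced_lr)
}

#' Early-stopping decision from a validation-loss history
#'
#' Stops (returns `TRUE`) when the minimum of the last `patience` entries
#' fails to improve on the minimum of all earlier entries; any strict
#' improvement inside the window keeps training. With `patience` or fewer
#' entries there is no earlier minimum to beat, so the answer is `FALSE`.
#'
#' @param val_loss_history numeric vector of per-epoch validation losses.
#' @param patience window length in epochs (>= 1).
#' @return logical.
#' @export
early_stop_check <- function(val_loss_history, patience) {
  n <- length(val_loss_history)
  if (n == 0) stop("history must be non-empty")
  if (n <= patience) return(FALSE)
  recent <- val_loss_history[(n - patience + 1L):n]
  earlier <- val_loss_history[1:(n - patience)]
  min(recent) >= min(earlier)
}

#' Train a binary classifier under the epoch schedule
#'
#' Runs the epoch loop with seeded per-epoch shuffling, the two-step
#' learning-rate schedule of [learning_rate_at()], and the patience rule of
#' [early_stop_check()] watched on the validation loss; the weights from
#' the best validation epoch are restored into the returned object.
#'
#' @param classifier a classifier fulfilling the contract
#'   ([fit_batch()], [predict_scores()]), e.g. [reference_cnn()].
#' @param train list with `x` (input matrix) and `y` (0/1 labels), as
#'   produced by [images_to_dataset()]; must be non-empty.
#' @param val like `train`; non-empty, used for scheduling only.
#' @param config a [train_config()].
#' @return an object of class `trained_classifier` with elements
#'   `classifier` (best-validation weights), `history` (data frame with
#'   epoch, lr, train_loss, val_loss), `best_epoch` and `config`.
#' @export
train_classifier <- function(classifier, train, val, config = train_config()) {
  if (is.null(train$x) || ncol(train$x) == 0) stop("empty training set")
  if (is.null(val$x) || ncol(val$x) == 0) stop("empty validation set")
  n <- ncol(train$x)
  set.seed(config$seed)
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_loss = numeric(), val_loss = numeric())
  best <- list(loss = Inf, classifier = classifier, epoch = 0L)
  for (epoch in seq_len(config$max_epochs)) {
    lr <- learning_rate_at(epoch, config)
    idx <- sample(n)
    starts <- seq(1L, n, by = config$batch_size)
    tl_sum <- 0
    for (s in starts) {
      b <- idx[s:min(s + config$batch_size - 1L, n)]
      step <- fit_batch(classifier, train$x[, b, drop = FALSE], train$y[b], lr)
      classifier <- step$classifier
      tl_sum <- tl_sum + step$loss * length(b)
    }
    vz <- predict_scores(classifier, val$x)
    val_loss <- -mean(val$y * log(pmax(vz, 1e-12)) +
                        (1 - val$y) * log(pmax(1 - vz, 1e-12)))
    history <- rbind(history, data.frame(epoch = epoch, lr = lr,
                                         train_loss = tl_sum / n,
                                         val_loss = val_loss))
    if (val_loss < best$loss) {
      best <- list(loss = val_loss, classifier = classifier, epoch = epoch)
    }
    if (early_stop_check(history$val_loss, config$early_stop_patience)) break
  }
  structure(list(classifier = best$classifier, history = history,
                 best_epoch = best$epoch, config = config),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("trained classifier: %d epochs run, best validation loss %.4f at epoch %d\n",
              nrow(x$history), min(x$history$val_loss), x$best_epoch))
  invisible(x)
}

#' @export
predict.trained_classifier <- function(object, newdata, ...) {
  x <- if (is.list(newdata) && !is.null(newdata$x)) newdata$x else newdata
  predict_scores(object$classifier, x)
}

#' @export
plot.trained_classifier <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}
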