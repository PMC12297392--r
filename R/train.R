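#' Train a T-Net with the Banerjee loss
#'
#' Minimizes the Banerjee compound loss with Adam, monitoring validation
#' loss with early stopping; the parameters of the best validation epoch
#' are restored at the end. Gradients are computed sample-by-sample and
#' averaged over mini-batches; batch normalization uses per-sample spatial
#' statistics during training and running averages at inference. Runs are
#' fully seeded and single-threaded, so identical seeds give identical
#' histories.
#'
#' @param net a `tnet` from [build_tnet()] (modified in place and
#'   returned inside the fit).
#' @param data either a `tatha_dataset` (its train/val splits are used) or
#'   a list with elements `train` and `val`, each a list of samples having
#'   `$image` and `$mask`.
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size mini-batch size (default 16).
#' @param max_epochs epoch cap (default 100).
#' @param patience early-stopping patience in epochs without validation
#'   improvement (default 8).
#' @param loss a [loss_params()] list.
#' @param augment apply random horizontal/vertical flips to training
#'   samples (default `TRUE`); validation is never augmented.
#' @param seed RNG seed for shuffling.
#' @param verbose print per-epoch progress.
#' @return object of class `tnet_fit`: the trained `net`, a `history`
#'   data frame (epoch, train loss, validation loss, validation Dice, IoU,
#'   F1) and the index of the best epoch.
#' @export
train_tnet <- function(net, data, learning_rate = 1e-3, batch_size = 16,
                       max_epochs = 100, patience = 8,
                       loss = loss_params(), augment = TRUE, seed = 1,
                       verbose = FALSE) {
  stopifnot(inherits(net, "tnet"))
  if (inherits(data, "tatha_dataset"))
    data <- list(train = split_samples(data, "train"),
                 val = split_samples(data, "val"))
  if (!length(data$train) || !length(data$val))
    stop("data must provide non-empty train and val splits")
  set.seed(seed)
  opt <- adam_init(net)
  hist <- list()
  best <- list(loss = Inf, epoch = 0, params = NULL)
  wait <- 0
  for (epoch in seq_len(max_epochs)) {
    ord <- sample(seq_along(data$train))
    ep_loss <- 0
    nb <- 0
    for (start in seq(1, length(ord), by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, length(ord))]
      acc <- NULL
      bl <- 0
      for (i in idx) {
        s <- data$train[[i]]
        im <- s$image; mk <- s$mask
        if (augment) {
          if (runif(1) < 0.5) { im <- im[nrow(im):1, ]; mk <- mk[nrow(mk):1, ] }
          if (runif(1) < 0.5) { im <- im[, ncol(im):1]; mk <- mk[, ncol(mk):1] }
          if (nrow(im) == ncol(im) && runif(1) < 0.5) {
            im <- t(im); mk <- t(mk)
          }
        }
        fwd <- tnet_forward(net, im, train = TRUE, keep = TRUE)
        lg <- banerjee_loss_grad(fwd$prob, mk, loss)
        if (!is.finite(lg$loss))
          stop(sprintf("training diverged (loss %s) at epoch %d",
                       lg$loss, epoch))
        bl <- bl + lg$loss
        acc <- grads_add(acc, tnet_backward(net, fwd, lg$grad))
      }
      acc <- grads_scale(acc, 1 / length(idx))
      adam_step(net, acc, opt, lr = learning_rate)
      ep_loss <- ep_loss + bl / length(idx)
      nb <- nb + 1
    }
    vm <- validate_tnet(net, data$val, loss)
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                val_loss = vm$loss, val_dice = vm$dice,
                                val_iou = vm$iou, val_f1 = vm$f1)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  dice %.4f",
                      epoch, ep_loss / nb, vm$loss, vm$dice))
    if (vm$loss < best$loss - 1e-6) {
      best <- list(loss = vm$loss, epoch = epoch,
                   params = as.list(net$params),
                   state = as.list(net$state))
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) break
    }
  }
  if (!is.null(best$params)) {
    for (nm in names(best$params)) net$params[[nm]] <- best$params[[nm]]
    for (nm in names(best$state)) net$state[[nm]] <- best$state[[nm]]
  }
  structure(list(net = net, history = do.call(rbind, hist),
                 best_epoch = best$epoch,
                 settings = list(learning_rate = learning_rate,
                                 batch_size = batch_size,
                                 max_epochs = max_epochs,
                                 patience = patience, seed = seed,
                                 loss = loss)),
            class = "tnet_fit")
}

validate_tnet <- function(net, val, loss) {
  tot <- c(loss = 0, dice = 0, iou = 0, f1 = 0)
  for (s in val) {
    p <- tnet_forward(net, s$image, train = FALSE)$prob
    m <- evaluate(p, s$mask, params = loss)
    tot <- tot + c(m$loss, m$dice, m$iou, m$f1)
  }
  as.list(tot / length(val))
}

#' @export
print.tnet_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("trained T-Net: %d epochs (best %d), val loss %.4f, val Dice %.4f\n",
              nrow(h), x$best_epoch, h$val_loss[x$best_epoch],
              h$val_dice[x$best_epoch]))
  invisible(x)
}

#' @export
summary.tnet_fit <- function(object, ...) {
  print(object)
  print(object$history, row.names = FALSE)
  invisible(object$history)
}

#' @export
predict.tnet_fit <- function(object, newdata, ...) {
  predict(object$net, newdata, ...)
}

#' @export
plot.tnet_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Cross-validate a T-Net configuration over precomputed folds
#'
#' For each fold a fresh network is built (seed offset by the fold index),
#' trained on the fold's train/validation samples and evaluated on the
#' fold's test samples; mean test accuracy, Dice and AUC are reported per
#' fold.
#'
#' @param samples list of phantom samples (the sample pool the fold
#'   indices refer to).
#' @param folds a [make_folds()] result.
#' @param config a [tnet_config()] used for every fold.
#' @param ... passed on to [train_tnet()].
#' @return data frame of class `tatha_cv` with columns `fold`, `accuracy`,
#'   `dice`, `auc`.
#' @export
cross_validate <- function(samples, folds, config, ...) {
  rows <- lapply(folds, function(fd) {
    res <- tryCatch({
      net <- build_tnet(modify_config_seed(config, config$seed + fd$fold))
      fit <- train_tnet(net, list(train = samples[fd$train],
                                  val = samples[fd$val]), ...)
      ev <- lapply(samples[fd$test], function(s)
        evaluate(predict(fit, s$image), s$mask))
      data.frame(fold = fd$fold,
                 accuracy = mean(vapply(ev, `[[`, 0, "accuracy")),
                 dice = mean(vapply(ev, `[[`, 0, "dice")),
                 auc = mean(vapply(ev, `[[`, 0, "auc")))
    }, error = function(e) {
      stop(sprintf("fold %d failed: %s", fd$fold, conditionMessage(e)),
           call. = FALSE)
    })
    res
  })
  structure(do.call(rbind, rows), class = c("tatha_cv", "data.frame"))
}

modify_config_seed <- function(config, seed) {
  config$seed <- seed
  config
}
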