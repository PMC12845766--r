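#' Training hyperparameters
#'
#' Defaults follow the published protocol: Adam with initial learning rate
#' 3e-4 and decoupled weight decay 1e-4, batch size 64, up to 500 epochs,
#' the learning rate halved on a stepwise schedule every eighth of the
#' total epoch budget, dropout 20%, early stopping with patience 50, and
#' global seed 42.
#'
#' @param lr0 Initial learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum number of epochs.
#' @param decay_factor Multiplicative learning-rate decay per interval.
#' @param interval_fraction Fraction of `epochs` forming one decay
#'   interval (default 1/8).
#' @param patience Epochs without validation improvement before stopping.
#' @param weight_decay Decoupled (AdamW-style) weight-decay coefficient.
#' @param dropout Dropout rate forwarded to the network blocks.
#' @param seed Integer seed covering weight init, shuffling and dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr0 = 3e-4, batch_size = 64L, epochs = 500L,
                         decay_factor = 0.5, interval_fraction = 1 / 8,
                         patience = 50L, weight_decay = 1e-4,
                         dropout = 0.2, seed = 42L) {
  if (decay_factor <= 0 || decay_factor > 1)
    stop_input("decay_factor must lie in (0, 1]")
  if (interval_fraction <= 0 || interval_fraction > 1)
    stop_input("interval_fraction must lie in (0, 1]")
  if (patience < 1L) stop_input("patience must be >= 1")
  if (interval_fraction * epochs < 1)
    stop_input("decay interval is shorter than one epoch")
  structure(list(lr0 = lr0, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), decay_factor = decay_factor,
                 interval_fraction = interval_fraction,
                 patience = as.integer(patience),
                 weight_decay = weight_decay, dropout = dropout,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Stepwise learning-rate schedule
#'
#' `lr = lr0 * decay_factor ^ floor(epoch / (interval_fraction * epochs))`
#' with 0-based epochs: the rate is constant within each interval and
#' drops by `decay_factor` at every interval boundary.
#'
#' @param epoch 0-based epoch index (vectorized).
#' @param cfg A [train_config()].
#' @return Learning rate(s).
#' @export
lr_schedule <- function(epoch, cfg = train_config()) {
  interval <- cfg$interval_fraction * cfg$epochs
  if (interval < 1) stop_input("decay interval is shorter than one epoch")
  cfg$lr0 * cfg$decay_factor^floor(epoch / interval)
}

#' Binary cross-entropy of foreground probabilities
#'
#' Mean over all pixels of `-[gt * log(p) + (1 - gt) * log(1 - p)]`, with
#' probabilities clipped to `[1e-7, 1 - 1e-7]` before the logarithms.
#'
#' @param pred_foreground_prob Numeric array of foreground probabilities.
#' @param gt Binary array of the same shape.
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(pred_foreground_prob, gt) {
  if (length(pred_foreground_prob) != length(gt))
    stop_validation("prediction and ground truth sizes differ")
  eps <- 1e-7
  p <- pmin(pmax(pred_foreground_prob, eps), 1 - eps)
  -mean(gt * log(p) + (1 - gt) * log(1 - p))
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
    params[[nm]] <- params[[nm]] - lr * upd - lr * weight_decay * params[[nm]]
  }
  list(params = params, state = state)
}

#' Fit the nucleus-segmentation network
#'
#' The single model-fitting entry point: trains the asymmetric U-Net on a
#' set of image patches with Adam (decoupled weight decay), the stepwise
#' learning-rate schedule of [lr_schedule()], per-epoch validation
#' (precision, recall, F1, MeanIoU), best-checkpoint selection by
#' validation F1 (MeanIoU as tie-breaker) and early stopping once the
#' selection metric has not improved for `config$patience` epochs. All
#' randomness (weight initialization, shuffling, dropout) derives from
#' `config$seed`, so identical calls reproduce identical fits.
#'
#' @param train Training data: a list of `ada_patch` objects (e.g. the
#'   `train` element of [prepare_patch_dataset()]) or a list with dense
#'   arrays `x` (`k x k x 3 x B`, intensities in `[0, 1]`) and `y`
#'   (`k x k x B` binary).
#' @param validation Validation data in the same form; when `NULL` the
#'   training set itself is monitored (discouraged except for smoke runs).
#' @param spec A [maunet_spec()]; pass `maunet_spec(width_scale = ...)`
#'   for width-reduced variants. The spec's dropout is overridden by
#'   `config$dropout`.
#' @param config A [train_config()].
#' @param checkpoint_dir Optional directory; when set, the best weights
#'   are additionally saved there as `best_weights.rds`.
#' @param viz_dir Optional directory; when set, a PNG triptych (image /
#'   truth / prediction) of one randomly sampled validation patch is
#'   written there after every epoch (off by default).
#' @param verbose Print one line per epoch.
#' @return Object of class `maunet`: list with `network` (best-checkpoint
#'   weights), `final_network`, `history` (one data.frame row per epoch:
#'   epoch, lr, train_loss, val_loss, val_precision, val_recall, val_f1,
#'   val_mean_iou), `best_epoch`, `best_metrics`, `config`, `spec`,
#'   `n_parameters`, `call`.
#' @seealso [predict.maunet()], [evaluate_network()], [run_pipeline()]
#' @export
maunet <- function(train, validation = NULL, spec = maunet_spec(),
                   config = train_config(), checkpoint_dir = NULL,
                   viz_dir = NULL, verbose = FALSE) {
  cl <- match.call()
  spec$dropout_rate <- config$dropout
  spec$blocks <- lapply(spec$blocks, function(b) {
    if (b$kind != "output") b$dropout_rate <- config$dropout
    b
  })
  tr <- if (!is.null(train$x)) train else patches_to_arrays(train)
  va <- if (is.null(validation)) tr
        else if (!is.null(validation$x)) validation
        else patches_to_arrays(validation)
  if (!dim(tr$x)[4]) stop_input("empty training set")
  net <- build_network(spec, seed = config$seed)
  state <- adam_init(net$params)
  n <- dim(tr$x)[4]
  history <- list()
  best <- list(f1 = -Inf, miou = -Inf, epoch = NA_integer_, params = NULL)
  since_improve <- 0L
  with_seed(config$seed + 1L, {
    for (epoch in 0:(config$epochs - 1L)) {
      lr <- lr_schedule(epoch, config)
      perm <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1L, n)]
        lg <- maunet_loss_grad(net,
                               tr$x[, , , idx, drop = FALSE],
                               tr$y[, , idx, drop = FALSE],
                               training = TRUE)
        if (!is.finite(lg$loss))
          stop("training diverged (non-finite loss) at epoch ", epoch)
        st <- adam_step(net$params, lg$grads, state, lr,
                        config$weight_decay)
        net$params <- st$params
        state <- st$state
        losses <- c(losses, lg$loss)
      }
      val <- evaluate_network(net, va, batch_size = config$batch_size)
      val_loss <- validation_loss(net, va, config$batch_size)
      history[[length(history) + 1L]] <- data.frame(
        epoch = epoch, lr = lr, train_loss = mean(losses),
        val_loss = val_loss, val_precision = val$precision,
        val_recall = val$recall, val_f1 = val$f1,
        val_mean_iou = val$mean_iou)
      improved <- val$f1 > best$f1 ||
        (val$f1 == best$f1 && val$mean_iou > best$miou)
      if (improved) {
        best <- list(f1 = val$f1, miou = val$mean_iou, epoch = epoch,
                     params = net$params, metrics = val)
        since_improve <- 0L
      } else {
        since_improve <- since_improve + 1L
      }
      if (verbose)
        cat(sprintf(
          "epoch %3d lr %.2e loss %.4f val_loss %.4f F1 %.4f MIoU %.4f%s\n",
          epoch, lr, mean(losses), val_loss, val$f1, val$mean_iou,
          if (improved) " *" else ""))
      if (!is.null(viz_dir)) dump_epoch_viz(net, va, epoch, viz_dir)
      if (since_improve >= config$patience) break
    }
  })
  best_net <- net
  best_net$params <- best$params
  if (!is.null(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(best_net$params, file.path(checkpoint_dir, "best_weights.rds"))
  }
  structure(list(network = best_net, final_network = net,
                 history = do.call(rbind, history),
                 best_epoch = best$epoch, best_metrics = best$metrics,
                 config = config, spec = spec,
                 n_parameters = count_parameters(net),
                 call = cl),
            class = "maunet")
}

# Visualization callback: image / ground truth / prediction of one random
# validation patch, side by side, one PNG per epoch.
dump_epoch_viz <- function(net, data, epoch, viz_dir) {
  dir.create(viz_dir, recursive = TRUE, showWarnings = FALSE)
  i <- sample.int(dim(data$x)[4], 1L)
  prob <- network_predict(net, data$x[, , , i, drop = FALSE])
  pred <- threshold_prediction(prob[, , , 1L])
  k <- dim(pred)[1]
  panel <- cbind(data$x[, , 1, i], data$y[, , i], pred)
  png::writePNG(clip01(panel),
                file.path(viz_dir, sprintf("epoch_%04d.png", epoch)))
  invisible(NULL)
}

validation_loss <- function(net, data, batch_size) {
  b <- dim(data$x)[4]
  tot <- 0
  for (start in seq(1L, b, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, b)
    prob <- network_predict(net, data$x[, , , idx, drop = FALSE])
    d <- dim(prob)
    p_fg <- array(prob[, , 2L, ], c(d[1], d[2], d[4]))
    tot <- tot + bce_loss(p_fg, data$y[, , idx, drop = FALSE]) * length(idx)
  }
  tot / b
}

#' @export
print.maunet <- function(x, ...) {
  h <- x$history
  cat("Asymmetric U-Net nucleus segmentation model\n")
  cat(sprintf("  %s trainable parameters (width scale %g)\n",
              format(x$n_parameters, big.mark = ","), x$spec$width_scale))
  cat(sprintf("  trained %d epoch(s), best epoch %d\n", nrow(h),
              x$best_epoch))
  if (!is.null(x$best_metrics))
    cat(sprintf("  best validation: F1 %.4f, MeanIoU %.4f\n",
                x$best_metrics$f1, x$best_metrics$mean_iou))
  invisible(x)
}

#' @export
summary.maunet <- function(object, ...) {
  print(object)
  cat("\nPer-layer parameters:\n")
  print(count_parameters(object$network, per_layer = TRUE))
  cat("\nLast epochs:\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' Extract fitted weights
#'
#' @param object A fitted `maunet`.
#' @param ... Unused.
#' @return Named list of weight/bias arrays (best checkpoint).
#' @export
coef.maunet <- function(object, ...) object$network$params

#' Predict segmentation for new patches
#'
#' @param object A fitted `maunet`.
#' @param newdata `H x W x 3 (x B)` intensity array in `[0, 1]`, or a list
#'   of `ada_patch` objects.
#' @param type `"prob"` for softmax maps, `"class"` for binary masks
#'   (argmax, ties to foreground).
#' @param ... Unused.
#' @return `H x W x 2 x B` probability array or `H x W (x B)` binary
#'   masks.
#' @export
predict.maunet <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.list(newdata) && !is.null(newdata[[1]]$image))
    newdata <- patches_to_arrays(newdata)$x
  prob <- network_predict(object$network, newdata)
  if (type == "prob") return(prob)
  out <- threshold_prediction(prob)
  if (dim(prob)[4] == 1L) out <- out[, , 1L]
  out
}

#' Plot the training history
#'
#' Two panels: losses and validation F1 / MeanIoU over epochs, with the
#' learning-rate steps marked on a secondary axis of the first panel.
#'
#' @param x A fitted `maunet`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.maunet <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red3"), xlab = "epoch",
                    ylab = "binary cross-entropy", main = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red3"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$val_f1, h$val_mean_iou), type = "l",
                    lty = 1, col = c("blue3", "darkgreen"), xlab = "epoch",
                    ylab = "score", ylim = c(0, 1), main = "validation", ...)
  graphics::abline(v = h$epoch[which(diff(h$lr) < 0)], lty = 3,
                   col = "grey60")
  graphics::legend("bottomright", c("F1", "MeanIoU"), lty = 1,
                   col = c("blue3", "darkgreen"), bty = "n")
  invisible(x)
}

#' Segment a whole image by stitching overlapping patch predictions
#'
#' Extracts the full patch grid (no balance filtering), predicts each
#' patch, and averages the per-pixel class probabilities over all patches
#' covering a pixel before thresholding.
#'
#' @param object A fitted `maunet`.
#' @param record An [image_record()].
#' @param params An [ada_params()] supplying patch size and stride.
#' @return List with `prob` (`H x W` foreground probability) and `mask`
#'   (`H x W` binary prediction) at the original image size.
#' @export
segment_image <- function(object, record, params = ada_params()) {
  patches <- extract_patches(record, params)
  k <- params$k
  h <- max(record$height, k); w <- max(record$width, k)
  acc <- matrix(0, h, w)
  cnt <- matrix(0, h, w)
  for (p in patches) {
    prob <- network_predict(object$network,
                            array(p$image / 255, c(k, k, 3L, 1L)))
    rows <- p$row0 + seq_len(k); cols <- p$col0 + seq_len(k)
    acc[rows, cols] <- acc[rows, cols] + prob[, , 2L, 1L]
    cnt[rows, cols] <- cnt[rows, cols] + 1
  }
  prob <- (acc / pmax(cnt, 1))[seq_len(record$height), seq_len(record$width)]
  list(prob = prob, mask = (prob >= 0.5) * 1L)
}
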