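#' Pixelwise confusion counts
#'
#' @param pred,gt Binary `H x W` matrices (or vectors of equal length);
#'   1 = nucleus (positive class), 0 = background.
#' @return Object of class `confusion_counts` with integer fields `tp`,
#'   `tn`, `fp`, `fn`; their sum equals the number of evaluated pixels.
#' @export
confusion <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)) || length(pred) != length(gt))
    stop_validation("pred and gt shapes differ")
  if (!is_binary(pred) || !is_binary(gt))
    stop_validation("pred and gt must be 0/1")
  p <- as.logical(pred); g <- as.logical(gt)
  structure(list(tp = sum(p & g), tn = sum(!p & !g),
                 fp = sum(p & !g), fn = sum(!p & g)),
            class = "confusion_counts")
}

#' Add confusion counts (micro-aggregation over patches/images)
#'
#' @param ... `confusion_counts` objects, or a single list of them.
#' @return Summed `confusion_counts`.
#' @export
sum_confusion <- function(...) {
  cs <- list(...)
  if (length(cs) == 1L && !inherits(cs[[1]], "confusion_counts"))
    cs <- cs[[1]]
  structure(list(tp = sum(vapply(cs, `[[`, numeric(1), "tp")),
                 tn = sum(vapply(cs, `[[`, numeric(1), "tn")),
                 fp = sum(vapply(cs, `[[`, numeric(1), "fp")),
                 fn = sum(vapply(cs, `[[`, numeric(1), "fn"))),
            class = "confusion_counts")
}

safe_div <- function(num, den) if (den == 0) 1.0 else num / den

#' Segmentation metrics from confusion counts
#'
#' Computes `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)`, their harmonic
#' mean F1, per-class intersection-over-union
#' (`iou_foreground = tp/(tp+fp+fn)`, `iou_background = tn/(tn+fp+fn)`),
#' `mean_iou` as the arithmetic mean of the two class IoUs, and pixel
#' accuracy. Vacuous 0/0 ratios (e.g. an all-background image predicted
#' all-background) are defined as 1.
#'
#' @param c A [confusion()] result.
#' @return Object of class `metrics_report` (named list of fractions in
#'   `[0, 1]`).
#' @export
compute_metrics <- function(c) {
  total <- c$tp + c$tn + c$fp + c$fn
  if (total <= 0) stop_input("no pixels to evaluate")
  precision <- safe_div(c$tp, c$tp + c$fp)
  recall <- safe_div(c$tp, c$tp + c$fn)
  f1 <- if (precision + recall == 0) 0
        else 2 * precision * recall / (precision + recall)
  iou_fg <- safe_div(c$tp, c$tp + c$fp + c$fn)
  iou_bg <- safe_div(c$tn, c$tn + c$fp + c$fn)
  structure(list(precision = precision, recall = recall, f1 = f1,
                 iou_foreground = iou_fg, iou_background = iou_bg,
                 mean_iou = (iou_fg + iou_bg) / 2,
                 accuracy = (c$tp + c$tn) / total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("MeanIoU %.*f | Precision %.*f | Recall %.*f | F1 %.*f\n",
              digits, x$mean_iou, digits, x$precision, digits, x$recall,
              digits, x$f1))
  cat(sprintf("  IoU(fg) %.*f  IoU(bg) %.*f  Accuracy %.*f\n",
              digits, x$iou_foreground, digits, x$iou_background,
              digits, x$accuracy))
  invisible(x)
}

#' Export a metrics report with benchmark-style column names
#'
#' Returns a one-row data.frame whose first four columns (`MIoU`,
#' `Precision`, `Recall`, `F1`) match the usual comparison tables for this
#' task; remaining columns carry the per-class IoUs and accuracy.
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return data.frame.
#' @export
as.data.frame.metrics_report <- function(x, ...) {
  data.frame(MIoU = x$mean_iou, Precision = x$precision, Recall = x$recall,
             F1 = x$f1, IoU_foreground = x$iou_foreground,
             IoU_background = x$iou_background, Accuracy = x$accuracy)
}

#' Binarize a softmax probability map
#'
#' Per-pixel argmax over the two channels; exact ties (foreground
#' probability 0.5) go to the foreground class.
#'
#' @param prob_map `H x W x 2` (or `H x W x 2 x B`) array of class
#'   probabilities, channel 2 = nucleus.
#' @return Binary `H x W` matrix (or `H x W x B` array).
#' @export
threshold_prediction <- function(prob_map) {
  d <- dim(prob_map)
  if (length(d) == 3L) {
    (prob_map[, , 2L] >= prob_map[, , 1L]) * 1L
  } else {
    out <- (prob_map[, , 2L, ] >= prob_map[, , 1L, ]) * 1L
    array(out, c(d[1], d[2], d[4]))
  }
}

#' Evaluate a network on a patch set
#'
#' Predicts every patch, binarizes, and aggregates confusion counts; by
#' default counts are summed over patches before computing metrics
#' (micro-averaging). `macro = TRUE` instead averages per-patch metric
#' values.
#'
#' @param net A `maunet_network` or fitted `maunet` object.
#' @param patches List of `ada_patch` objects, or a list with elements
#'   `x` (`k x k x 3 x B`, intensities in `[0, 1]`) and `y`
#'   (`k x k x B` binary).
#' @param macro Logical; macro-average per patch instead of pooling counts.
#' @param batch_size Forward-pass batch size.
#' @return A `metrics_report` with the pooled `confusion_counts` attached
#'   as attribute `"confusion"`.
#' @export
evaluate_network <- function(net, patches, macro = FALSE, batch_size = 16L) {
  if (inherits(net, "maunet")) net <- net$network
  data <- if (is.list(patches) && !is.null(patches$x)) patches
          else patches_to_arrays(patches)
  b <- dim(data$x)[4]
  counts <- list()
  reports <- list()
  for (start in seq(1L, b, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, b)
    prob <- network_predict(net, data$x[, , , idx, drop = FALSE])
    pred <- threshold_prediction(prob)
    for (j in seq_along(idx)) {
      cc <- confusion(pred[, , j], data$y[, , idx[j]])
      counts[[length(counts) + 1L]] <- cc
      if (macro) reports[[length(reports) + 1L]] <- compute_metrics(cc)
    }
  }
  pooled <- sum_confusion(counts)
  rep <- if (macro) {
    avg <- lapply(setNames(nm = names(reports[[1]])), function(f)
      mean(vapply(reports, `[[`, numeric(1), f)))
    structure(avg, class = "metrics_report")
  } else {
    compute_metrics(pooled)
  }
  attr(rep, "confusion") <- pooled
  rep
}

#' Convert a patch list to dense training arrays
#'
#' Intensities are scaled from `[0, 255]` to `[0, 1]`.
#'
#' @param patches List of `ada_patch` objects (equal sizes).
#' @return List with `x` (`k x k x 3 x B`) and `y` (`k x k x B`).
#' @export
patches_to_arrays <- function(patches) {
  if (!length(patches)) stop_input("empty patch list")
  k <- nrow(patches[[1]]$mask)
  b <- length(patches)
  x <- array(0, c(k, k, 3L, b))
  y <- array(0L, c(k, k, b))
  for (i in seq_len(b)) {
    x[, , , i] <- patches[[i]]$image / 255
    y[, , i] <- patches[[i]]$mask
  }
  list(x = x, y = y)
}
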