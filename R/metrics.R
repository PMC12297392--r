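#' Pixelwise confusion counts
#'
#' @param pred,truth binary matrices of the same shape.
#' @return list with `tp`, `fp`, `fn`, `tn` (their sum equals the pixel
#'   count).
#' @export
confusion <- function(pred, truth) {
  check_same_shape(pred, truth)
  pred <- unclass_mat(as.matrix(pred)); truth <- unclass_mat(as.matrix(truth))
  if (!all(pred %in% c(0, 1))) stop("pred must be binary; threshold first")
  if (!all(truth %in% c(0, 1))) stop("truth must be binary")
  list(tp = sum(pred == 1 & truth == 1),
       fp = sum(pred == 1 & truth == 0),
       fn = sum(pred == 0 & truth == 1),
       tn = sum(pred == 0 & truth == 0))
}

#' Area under the ROC curve (trapezoidal)
#'
#' Builds the ROC from every distinct probability cut point and integrates
#' by trapezoids; equal to the normalized Mann-Whitney U statistic. When the
#' truth contains a single class the AUC is undefined and `NaN` is returned
#' with a warning.
#'
#' @param prob numeric vector/matrix of scores.
#' @param truth binary vector/matrix of the same length.
#' @return scalar AUC in `[0, 1]`, or `NaN`.
#' @export
roc_auc <- function(prob, truth) {
  p <- as.vector(unclass_mat(as.matrix(prob)))
  y <- as.vector(unclass_mat(as.matrix(truth)))
  if (length(p) != length(y)) stop("length mismatch")
  np <- sum(y == 1); nn <- sum(y == 0)
  if (np == 0 || nn == 0) {
    warning("AUC undefined: truth contains a single class")
    return(NaN)
  }
  ord <- order(p, decreasing = TRUE)
  ys <- y[ord]; ps <- p[ord]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  keep <- c(ps[-length(ps)] != ps[-1], TRUE)  # last index of each tie group
  tpr <- c(0, tp[keep] / np)
  fpr <- c(0, fp[keep] / nn)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' Average precision (area under the precision-recall curve)
#'
#' Step-interpolated PR area `sum_k (R_k - R_{k-1}) * P_k` over distinct
#' score cut points; the package's documented pixelwise reading of "mAP"
#' for binary segmentation.
#'
#' @inheritParams roc_auc
#' @return scalar in `[0, 1]`, or `NaN` when no positives exist.
#' @export
average_precision <- function(prob, truth) {
  p <- as.vector(unclass_mat(as.matrix(prob)))
  y <- as.vector(unclass_mat(as.matrix(truth)))
  np <- sum(y == 1)
  if (np == 0) {
    warning("average precision undefined: no positive pixels")
    return(NaN)
  }
  ord <- order(p, decreasing = TRUE)
  ys <- y[ord]; ps <- p[ord]
  tp <- cumsum(ys)
  k <- seq_along(ys)
  keep <- c(ps[-length(ps)] != ps[-1], TRUE)
  prec <- tp[keep] / k[keep]
  rec <- tp[keep] / np
  sum(diff(c(0, rec)) * prec)
}

#' Evaluate a probability map against a ground-truth mask
#'
#' Hard metrics (accuracy, sensitivity, specificity, Dice, IoU, F1) are
#' computed from the confusion counts at `threshold`; AUC and average
#' precision are threshold-free; `loss` is the Banerjee compound loss on
#' the soft prediction.
#'
#' @param prob probability matrix in `[0, 1]`.
#' @param truth binary matrix of the same shape.
#' @param threshold hard-decision cut in `(0, 1)` (default 0.5).
#' @param params [loss_params()] used for the reported loss.
#' @return list of class `tatha_metrics` with fields `accuracy`, `dice`,
#'   `iou`, `auc`, `sensitivity`, `specificity`, `f1`,
#'   `average_precision`, `loss`.
#' @export
evaluate <- function(prob, truth, threshold = 0.5, params = loss_params()) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  check_same_shape(prob, truth)
  prob <- unclass_mat(as.matrix(prob)); truth <- unclass_mat(as.matrix(truth))
  hard <- (prob >= threshold) * 1
  cm <- confusion(hard, truth)
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  dice <- if (cm$tp + cm$fp + cm$fn == 0) 1 else
    2 * cm$tp / (2 * cm$tp + cm$fp + cm$fn)
  iou <- if (cm$tp + cm$fp + cm$fn == 0) 1 else
    cm$tp / (cm$tp + cm$fp + cm$fn)
  structure(list(
    accuracy = (cm$tp + cm$tn) / total,
    dice = dice,
    iou = iou,
    auc = suppressWarnings(roc_auc(prob, truth)),
    sensitivity = if (cm$tp + cm$fn == 0) NaN else cm$tp / (cm$tp + cm$fn),
    specificity = if (cm$tn + cm$fp == 0) NaN else cm$tn / (cm$tn + cm$fp),
    f1 = dice,
    average_precision = suppressWarnings(average_precision(prob, truth)),
    loss = banerjee_loss(prob, truth, params)
  ), class = "tatha_metrics")
}

#' @export
print.tatha_metrics <- function(x, ...) {
  v <- unlist(x)
  cat("segmentation metrics:\n")
  print(round(v, 4))
  invisible(x)
}

#' Write per-image metric reports
#'
#' @param reports list of `tatha_metrics` (or a single one).
#' @param path output file; format chosen by extension (`.csv` or `.json`).
#' @param ids optional row identifiers.
#' @return the data frame written, invisibly.
#' @export
write_metrics <- function(reports, path, ids = NULL) {
  if (inherits(reports, "tatha_metrics")) reports <- list(reports)
  df <- do.call(rbind, lapply(reports, function(r) as.data.frame(unclass(r))))
  if (!is.null(ids)) df <- cbind(id = ids, df)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(df, path, digits = NA, auto_unbox = TRUE)
  } else {
    write.csv(df, path, row.names = FALSE)
  }
  invisible(df)
}
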