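# Confusion-matrix segmentation metrics: accuracy, precision, recall, F1,
# Dice similarity coefficient and intersection-over-union. For binary masks
# F1 equals DSC and IOU = DSC / (2 - DSC).

#' Pixel confusion counts between two binary masks
#'
#' @param pred_mask,gt_mask Binary matrices/arrays of identical shape
#'   (values in {0, 1}).
#' @return Named list tp, fp, tn, fn.
#' @export
seg_confusion <- function(pred_mask, gt_mask) {
  p <- as.numeric(pred_mask); g <- as.numeric(gt_mask)
  if (length(p) != length(g) || !identical(dim(pred_mask), dim(gt_mask))) {
    stop("mask shapes differ", call. = FALSE)
  }
  if (!all(p %in% c(0, 1)) || !all(g %in% c(0, 1))) {
    stop("masks must be binary (0/1)", call. = FALSE)
  }
  list(tp = sum(p == 1 & g == 1), fp = sum(p == 1 & g == 0),
       tn = sum(p == 0 & g == 0), fn = sum(p == 0 & g == 1))
}

#' Evaluate a predicted mask against ground truth
#'
#' Conventions at degenerate inputs: an empty union gives dsc = iou = 1 (and
#' precision = recall = 1); an empty prediction against a nonempty truth
#' gives precision 0.
#'
#' @inheritParams seg_confusion
#' @return List of class `seg_evaluation` with the confusion counts and
#'   accuracy, precision, recall, f1, dsc, iou.
#' @export
seg_evaluate <- function(pred_mask, gt_mask) {
  cf <- seg_confusion(pred_mask, gt_mask)
  tp <- cf$tp; fp <- cf$fp; tn <- cf$tn; fn <- cf$fn
  total <- tp + fp + tn + fn
  accuracy <- (tp + tn) / total
  precision <- if (tp + fp > 0) tp / (tp + fp) else if (fn == 0) 1 else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else if (fp == 0) 1 else 0
  dsc <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 1
  # 2PR/(P+R) simplifies to 2tp/(2tp+fp+fn): evaluating F1 in the count form
  # keeps the F1 = DSC set identity exact in floating point too
  f1 <- dsc
  iou <- if (tp + fp + fn > 0) tp / (tp + fp + fn) else 1
  structure(c(cf, list(accuracy = accuracy, precision = precision,
                       recall = recall, f1 = f1, dsc = dsc, iou = iou)),
            class = "seg_evaluation")
}

#' @export
print.seg_evaluation <- function(x, ...) {
  cat(sprintf("seg_evaluation: acc=%.4f pre=%.4f rec=%.4f f1=%.4f dsc=%.4f iou=%.4f\n",
              x$accuracy, x$precision, x$recall, x$f1, x$dsc, x$iou))
  invisible(x)
}

#' Binarize a 2-channel probability map into a mask
#'
#' Argmax over the two class channels (equivalently, tumor probability
#' thresholded at 0.5).
#'
#' @param prob Array 2 x H x W (channel 1 background, channel 2 tumor) or a
#'   tumor probability matrix.
#' @return Binary matrix.
#' @export
binarize_prediction <- function(prob) {
  prob <- ag_value(prob)
  if (is.matrix(prob)) return((prob > 0.5) * 1)
  stopifnot(length(dim(prob)) == 3, dim(prob)[1] == 2)
  (prob[2, , ] > prob[1, , ]) * 1
}

#' Evaluate a set of predicted/ground-truth mask pairs
#'
#' @param pred_masks,gt_masks Lists of binary matrices.
#' @param ids Optional character ids (one per pair).
#' @return List: `per_image` data frame (one row per pair) and `summary`
#'   (macro mean and sd of each metric).
#' @export
evaluate_masks <- function(pred_masks, gt_masks, ids = NULL) {
  stopifnot(length(pred_masks) == length(gt_masks))
  ids <- ids %||% sprintf("sample_%03d", seq_along(pred_masks))
  rows <- lapply(seq_along(pred_masks), function(i) {
    ev <- seg_evaluate(pred_masks[[i]], gt_masks[[i]])
    data.frame(id = ids[i], tp = ev$tp, fp = ev$fp, tn = ev$tn, fn = ev$fn,
               accuracy = ev$accuracy, precision = ev$precision,
               recall = ev$recall, f1 = ev$f1, dsc = ev$dsc, iou = ev$iou,
               stringsAsFactors = FALSE)
  })
  per_image <- do.call(rbind, rows)
  mets <- c("accuracy", "precision", "recall", "f1", "dsc", "iou")
  summary <- list(
    mean = as.list(colMeans(per_image[mets])),
    sd = as.list(vapply(per_image[mets], stats::sd, numeric(1))),
    n = nrow(per_image)
  )
  list(per_image = per_image, summary = summary)
}
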