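# Compound loss: weighted segmentation focal loss plus a weighted boundary
# focal loss on Canny-extracted boundaries, combined as
# Loss = FL_seg + beta * FL_boundary.
#
# Canny is not differentiable, so during training the prediction boundary
# uses a differentiable surrogate: the min-max-normalized Sobel gradient
# magnitude of the tumor probability channel. True Canny is used for the
# ground-truth boundary (no gradient needed) and is available for
# evaluation-mode boundary maps.

#' Loss configuration
#'
#' @param alpha Class-balance weight in (0, 1), or "auto" to use the
#'   background-pixel ratio of the batch.
#' @param gamma Focusing exponent.
#' @param beta Weight of the boundary term.
#' @param canny_low,canny_high Hysteresis thresholds for boundary
#'   extraction.
#' @param sharpen_threshold Threshold for sharpening the normalized
#'   ground-truth boundary into a binary map.
#' @export
loss_config <- function(alpha = "auto", gamma = 1.25, beta = 0.2,
                        canny_low = 0.1, canny_high = 0.3,
                        sharpen_threshold = 0.5) {
  stopifnot(identical(alpha, "auto") || (is.numeric(alpha) && alpha > 0 && alpha < 1),
            gamma >= 0, beta >= 0)
  structure(list(alpha = alpha, gamma = gamma, beta = beta,
                 canny_low = canny_low, canny_high = canny_high,
                 sharpen_threshold = sharpen_threshold),
            class = "loss_config")
}

#' Class-balance weight from the batch background ratio
#'
#' alpha = (background pixels) / (total pixels), clamped to [0.05, 0.95];
#' a rare tumor class therefore gets the larger weight.
#'
#' @param masks A binary mask, or list of binary masks.
#' @return Numeric alpha.
#' @export
auto_alpha <- function(masks) {
  if (!is.list(masks)) masks <- list(masks)
  if (length(masks) == 0) stop("empty batch", call. = FALSE)
  tot <- sum(vapply(masks, length, numeric(1)))
  fg <- sum(vapply(masks, function(m) sum(m > 0), numeric(1)))
  min(max((tot - fg) / tot, 0.05), 0.95)
}

#' Weighted focal loss between a probability map and a binary target
#'
#' FL = mean(-alpha y (1-p)^gamma log p - (1-alpha)(1-y) p^gamma log(1-p)),
#' with p clamped to [1e-7, 1 - 1e-7]. Used for both the segmentation and
#' the boundary terms.
#'
#' @param y_pred Probability map (`ag` node or numeric array/matrix).
#' @param y_gt Binary target of the same shape (numeric).
#' @param alpha Class-balance weight.
#' @param gamma Focusing exponent.
#' @return Scalar `ag` node (nonnegative).
#' @export
focal_seg <- function(y_pred, y_gt, alpha, gamma) {
  y_gt <- ag_value(y_gt)
  if (!identical(dim2(ag_value(y_pred)), dim2(y_gt))) {
    stop("prediction and target shapes differ", call. = FALSE)
  }
  p <- ag_clamp(if (is_ag(y_pred)) y_pred else ag(y_pred), 1e-7, 1 - 1e-7)
  pos <- ag_mul_const(ag_mul(ag_pow(ag_sub(1, p), gamma), ag_log(p)),
                      -alpha * (y_gt > 0))
  neg <- ag_mul_const(ag_mul(ag_pow(p, gamma), ag_log(ag_sub(1, p))),
                      -(1 - alpha) * (y_gt <= 0))
  ag_mean(ag_add(pos, neg))
}

dim2 <- function(x) { d <- dim(x); if (is.null(d)) length(x) else d }

#' Weighted boundary focal loss
#'
#' Same functional form as [focal_seg()], applied to boundary maps.
#'
#' @param b_pred Predicted boundary map in [0, 1] (`ag` or numeric).
#' @param b_gt_sharp Sharpened binary ground-truth boundary.
#' @inheritParams focal_seg
#' @return Scalar `ag` node.
#' @export
focal_boundary <- function(b_pred, b_gt_sharp, alpha, gamma) {
  focal_seg(b_pred, b_gt_sharp, alpha, gamma)
}

#' Extract a boundary map by the Canny operator
#'
#' For ground-truth masks the edge map is normalized and sharpened at the
#' configured threshold, yielding a binary boundary.
#'
#' @param map 2-D numeric matrix (mask or probability map).
#' @param cfg [loss_config()].
#' @param sharpen Threshold the normalized edge map into a binary boundary.
#' @return Numeric matrix in {0, 1} (sharpened) or [0, 1].
#' @export
extract_boundary <- function(map, cfg = loss_config(), sharpen = TRUE) {
  stopifnot(is.matrix(map))
  b <- canny_edges(map, low = cfg$canny_low, high = cfg$canny_high)
  mx <- max(b)
  if (mx > 0) b <- b / mx
  if (sharpen) b <- (b >= cfg$sharpen_threshold) * 1
  b
}

#' Differentiable boundary surrogate of a probability map
#'
#' Min-max-normalized Sobel gradient magnitude of the (tumor) probability
#' channel; the normalizing maximum is treated as a constant.
#'
#' @param y_pred `ag` node or numeric, 1 x H x W or matrix.
#' @return `ag` node, 1 x H x W in [0, 1].
#' @export
boundary_surrogate <- function(y_pred) {
  p <- if (is_ag(y_pred)) y_pred else ag(y_pred)
  v <- ag_value(p)
  if (is.matrix(v)) p <- ag_reshape(p, c(1, nrow(v), ncol(v)))
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  wx <- array(0, dim = c(1, 1, 3, 3)); wx[1, 1, , ] <- kx
  wy <- array(0, dim = c(1, 1, 3, 3)); wy[1, 1, , ] <- t(kx)
  gx <- ag_conv2d(p, ag(wx), pad = 1)
  gy <- ag_conv2d(p, ag(wy), pad = 1)
  mag <- ag_sqrt(ag_add(ag_add(ag_mul(gx, gx), ag_mul(gy, gy)), 1e-12))
  mx <- max(ag_value(mag))
  if (mx <= 0) mx <- 1
  ag_mul_const(mag, 1 / mx)
}

#' Compound segmentation + boundary loss
#'
#' Loss = FL_seg + beta * FL_boundary. The boundary term compares the
#' differentiable Sobel surrogate of the prediction against the sharpened
#' Canny boundary of the ground truth, each focal term using its own
#' batch-ratio alpha when `cfg$alpha == "auto"`.
#'
#' @param y_pred Tumor probability map (`ag` node or numeric), 1 x H x W or
#'   matrix.
#' @param y_gt Binary ground-truth mask, same spatial shape.
#' @param cfg [loss_config()].
#' @param b_gt Optional precomputed sharpened ground-truth boundary (as from
#'   [extract_boundary()]); avoids re-running Canny when the same mask is
#'   used across epochs.
#' @return List: `loss` (scalar `ag`), `seg` and `boundary` (numeric
#'   component values).
#' @export
compound_loss <- function(y_pred, y_gt, cfg = loss_config(), b_gt = NULL) {
  y_gt_m <- if (is.matrix(y_gt)) y_gt else matrix(y_gt, dim(y_gt)[2], dim(y_gt)[3])
  p <- if (is_ag(y_pred)) y_pred else ag(y_pred)
  pv <- ag_value(p)
  if (is.matrix(pv)) p <- ag_reshape(p, c(1, nrow(pv), ncol(pv)))
  gt_arr <- array(y_gt_m, dim = dim(ag_value(p)))

  a_seg <- if (identical(cfg$alpha, "auto")) auto_alpha(y_gt_m) else cfg$alpha
  fl_seg <- focal_seg(p, gt_arr, a_seg, cfg$gamma)

  if (is.null(b_gt)) b_gt <- extract_boundary(y_gt_m, cfg, sharpen = TRUE)
  b_pred <- boundary_surrogate(p)
  a_b <- if (identical(cfg$alpha, "auto")) auto_alpha(b_gt) else cfg$alpha
  fl_b <- focal_boundary(b_pred, array(b_gt, dim = dim(ag_value(b_pred))),
                         a_b, cfg$gamma)

  total <- ag_add(fl_seg, ag_mul_const(fl_b, cfg$beta))
  list(loss = total, seg = as.numeric(ag_value(fl_seg)),
       boundary = as.numeric(ag_value(fl_b)))
}
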