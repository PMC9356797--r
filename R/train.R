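# Training loop: Adam with a polynomial learning-rate decay, the compound
# focal + boundary loss, per-epoch logging of loss components and train
# Dice, and best-Dice checkpointing.

#' Polynomial learning-rate decay
#'
#' lr(epoch) = base_lr * (1 - epoch/total_epochs)^power.
#'
#' @param base_lr Base learning rate.
#' @param epoch Zero-based epoch index.
#' @param total_epochs Total number of epochs.
#' @param power Decay exponent.
#' @export
poly_lr <- function(base_lr, epoch, total_epochs, power = 0.9) {
  base_lr * (1 - epoch / total_epochs)^power
}

#' Training configuration
#'
#' @param epochs Number of epochs.
#' @param base_lr Base learning rate for Adam.
#' @param optimizer Only "adam" is provided.
#' @param lr_power Polynomial decay exponent.
#' @param batch_size Minibatch size.
#' @param seed Seed controlling initialization and batch shuffling.
#' @param loss [loss_config()].
#' @param model [model_config()].
#' @export
train_config <- function(epochs = 200, base_lr = 1e-4, optimizer = "adam",
                         lr_power = 0.9, batch_size = 4, seed = 1,
                         loss = loss_config(), model = model_config()) {
  stopifnot(optimizer == "adam", epochs >= 1, base_lr > 0, batch_size >= 1)
  structure(list(epochs = as.integer(epochs), base_lr = base_lr,
                 optimizer = optimizer, lr_power = lr_power,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 loss = loss, model = model),
            class = "train_config")
}

#' Train a model on a list of samples
#'
#' @param samples List of sample pairs (image in [0, 1], binary mask).
#' @param config [train_config()].
#' @param model Optional pre-built model (otherwise built from
#'   `config$model` with `config$seed`).
#' @param checkpoint_path Optional path; the best-train-Dice model is saved
#'   there whenever the Dice improves.
#' @param verbose Print one key=value log line per epoch.
#' @return List: `model`, `history` (data frame epoch/lr/loss/seg/boundary/
#'   dsc, where dsc is the running estimate over the epoch's minibatch
#'   predictions), `best_dsc` (best running estimate, used for
#'   checkpointing), and `final_dsc` (clean evaluation of the final model on
#'   the training samples; this is what a later evaluation of the returned
#'   model reproduces).
#' @export
train_model <- function(samples, config = train_config(), model = NULL,
                        checkpoint_path = NULL, verbose = FALSE) {
  stopifnot(length(samples) >= 1)
  if (is.null(model)) model <- build_model(config$model, seed = config$seed)
  params <- model$params
  opt <- adam_init(params)
  n <- length(samples)
  hist <- vector("list", config$epochs)
  best <- -Inf
  order_seed <- derive_seed(config$seed, 777)
  # ground-truth boundaries are fixed across epochs; extract them once
  b_gts <- lapply(samples, function(s) extract_boundary(s$mask, config$loss))
  for (epoch in seq_len(config$epochs) - 1L) {
    lr <- poly_lr(config$base_lr, epoch, config$epochs, config$lr_power)
    idx <- with_local_seed(derive_seed(order_seed, epoch), sample(n))
    ep_loss <- 0; ep_seg <- 0; ep_b <- 0; ep_dsc <- 0; nb <- 0; ns <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      batch <- idx[start:min(start + config$batch_size - 1L, n)]
      ag_zero_grad(params)
      total <- NULL
      for (k in batch) {
        smp <- samples[[k]]
        # degenerate-texture warnings (all-zero activations after ReLU) are
        # routine during early training; non-finite values still abort below
        out <- suppressWarnings(model_forward(model, smp$image))
        tumor <- ag_slice(out$probabilities, 1, 2)
        cl <- suppressWarnings(compound_loss(tumor, smp$mask, config$loss,
                                             b_gt = b_gts[[k]]))
        if (!is.finite(ag_value(cl$loss))) {
          stop("non-finite loss at epoch ", epoch, call. = FALSE)
        }
        total <- if (is.null(total)) cl$loss else ag_add(total, cl$loss)
        ep_seg <- ep_seg + cl$seg; ep_b <- ep_b + cl$boundary
        ep_dsc <- ep_dsc + seg_evaluate(out$mask, smp$mask)$dsc
        ns <- ns + 1
      }
      total <- ag_mul_const(total, 1 / length(batch))
      ag_backward(total)
      opt <- adam_step(opt, params, lr)
      ep_loss <- ep_loss + ag_value(total); nb <- nb + 1
    }
    row <- data.frame(epoch = epoch, lr = lr, loss = ep_loss / nb,
                      seg = ep_seg / ns, boundary = ep_b / ns, dsc = ep_dsc / ns)
    hist[[epoch + 1L]] <- row
    if (verbose) {
      message(sprintf("epoch=%d lr=%.3e loss=%.4f seg=%.4f boundary=%.4f train_dsc=%.4f",
                      epoch, lr, row$loss, row$seg, row$boundary, row$dsc))
    }
    if (row$dsc > best) {
      best <- row$dsc
      if (!is.null(checkpoint_path)) save_checkpoint(model, checkpoint_path)
    }
  }
  final_dsc <- mean(suppressWarnings(evaluate_model(model, samples))$per_image$dsc)
  list(model = model, history = do.call(rbind, hist), best_dsc = best,
       final_dsc = final_dsc)
}

#' Evaluate a model over a list of samples
#'
#' @param model A `seg_model`.
#' @param samples List of sample pairs.
#' @return As [evaluate_masks()]: per-image data frame plus macro summary.
#' @export
evaluate_model <- function(model, samples) {
  preds <- lapply(samples, function(s) model_forward(model, s$image)$mask)
  evaluate_masks(preds, lapply(samples, `[[`, "mask"),
                 ids = vapply(samples, `[[`, character(1), "id"))
}

#' Predict a tumor mask for one image
#'
#' @param model A `seg_model`.
#' @param image Matrix in [0, 1].
#' @param boundary Also return the Canny boundary of the predicted mask.
#' @return List: `mask` (binary matrix), `prob` (tumor probability matrix),
#'   `boundary` (binary matrix or NULL).
#' @export
predict_mask <- function(model, image, boundary = FALSE) {
  out <- model_forward(model, image)
  prob <- ag_value(out$probabilities)[2, , ]
  list(mask = out$mask, prob = prob,
       boundary = if (boundary) canny_edges(out$mask) else NULL)
}
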