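# Full model assembly: a dilated-residual backbone (layer norm instead of
# batch norm), grid contextual attention after the residual stages, a
# low-level branch into the statistical texture learning block, channel
# fusion with the high-level features, and the spatial transformer
# prediction head.

#' Backbone configuration
#'
#' The default follows the dilated residual network D-22 layout: two plain
#' conv stages followed by six basic-residual-block stages, downsampling at
#' stages 2-4 (output stride 8) and dilated convolutions in the last two
#' stages.
#'
#' @param arch Architecture tag.
#' @param stage_channels Output channels of the 8 stages.
#' @param blocks Residual blocks per stage (stages 1-2 are single convs).
#' @param strides Stride of each stage's first conv.
#' @param dilations Dilation of each stage's convs.
#' @param norm "layer" (whole-map statistics per sample) or "batch"
#'   (per-channel statistics; single-sample equivalent of batch norm).
#' @param gca_stages Stages after which a GCA block is inserted.
#' @param low_level_stages Stages feeding the low-level texture branch.
#' @export
backbone_config <- function(arch = "drn_d_22",
                            stage_channels = c(16, 32, 64, 128, 256, 512, 512, 512),
                            blocks = c(1, 1, 2, 2, 2, 2, 1, 1),
                            strides = c(1, 2, 2, 2, 1, 1, 1, 1),
                            dilations = c(1, 1, 1, 1, 1, 1, 2, 4),
                            norm = "layer",
                            gca_stages = 3:8,
                            low_level_stages = c(1, 2)) {
  stopifnot(length(stage_channels) == 8, length(blocks) == 8,
            length(strides) == 8, length(dilations) == 8,
            norm %in% c("layer", "batch"),
            all(gca_stages > 2), all(low_level_stages %in% 1:2))
  structure(list(arch = arch, stage_channels = as.integer(stage_channels),
                 blocks = as.integer(blocks), strides = as.integer(strides),
                 dilations = as.integer(dilations), norm = norm,
                 gca_stages = as.integer(gca_stages),
                 low_level_stages = as.integer(low_level_stages)),
            class = "backbone_config")
}

#' Full model configuration
#'
#' @param backbone [backbone_config()].
#' @param gca [gca_config()].
#' @param stlb [stlb_config()].
#' @param stb [stb_config()].
#' @param use_gca,use_stlb,use_stb Enable/disable each block (the ablation
#'   lattice).
#' @param low_width Channels of the fused low-level branch.
#' @param fuse_width Channels after high/low fusion, input to the head.
#' @param head_stride Resolution of the fused features and prediction head
#'   relative to the input (4 recovers more boundary detail than the
#'   backbone's output stride 8).
#' @export
model_config <- function(backbone = backbone_config(), gca = gca_config(),
                         stlb = stlb_config(), stb = stb_config(),
                         use_gca = TRUE, use_stlb = TRUE, use_stb = TRUE,
                         low_width = 32, fuse_width = 512, head_stride = 4) {
  structure(list(backbone = backbone, gca = gca, stlb = stlb, stb = stb,
                 use_gca = isTRUE(use_gca), use_stlb = isTRUE(use_stlb),
                 use_stb = isTRUE(use_stb), low_width = as.integer(low_width),
                 fuse_width = as.integer(fuse_width),
                 head_stride = as.integer(head_stride)),
            class = "model_config")
}

#' Reduced-width configuration for desk-scale training and tests
#'
#' Same topology as the default model with narrow stages, fewer quantization
#' levels and a two-scale pyramid; small enough to train on the CPU.
#'
#' @param n_levels Quantization levels for the texture block.
#' @param ... Overrides passed to [model_config()].
#' @export
model_config_small <- function(n_levels = 8, ...) {
  model_config(
    backbone = backbone_config(stage_channels = c(8, 8, 16, 16, 32, 32, 32, 32),
                               blocks = rep(1L, 8), gca_stages = c(4, 6, 8)),
    gca = gca_config(patch_h = 4, patch_w = 4, reduction = 2),
    stlb = stlb_config(n_levels = n_levels, scales = c(1, 2), c1_lift = 4,
                       c_prime = 16, d_attn = 8, out_channels = 16),
    stb = stb_config(widths = c(16, 16, 16), fc = 16),
    low_width = 16, fuse_width = 32, head_stride = 2, ...)
}

#' Build a model with deterministic initialization
#'
#' All conv and linear weights use kaiming-uniform initialization except the
#' spatial transformer regression head, which starts at zero weights with
#' identity bias. Two builds with the same seed are bit-identical.
#'
#' @param cfg [model_config()].
#' @param seed Integer seed.
#' @return List of class `seg_model`: `cfg`, `params` (named `ag` leaves),
#'   `seed`.
#' @export
build_model <- function(cfg = model_config(), seed = 1) {
  bb <- cfg$backbone
  store <- new_param_store()
  with_local_seed(seed, {
    cin <- 1L
    for (s in 1:8) {
      cout <- bb$stage_channels[s]
      pre <- sprintf("stage%d", s)
      if (s <= 2) {
        make_conv_params(store, paste0(pre, ".conv"), cout, cin, 3, 3)
        make_norm_params(store, paste0(pre, ".norm"), cout)
      } else {
        for (b in seq_len(bb$blocks[s])) {
          bcin <- if (b == 1) cin else cout
          bp <- sprintf("%s.block%d", pre, b)
          make_conv_params(store, paste0(bp, ".conv1"), cout, bcin, 3, 3)
          make_norm_params(store, paste0(bp, ".norm1"), cout)
          make_conv_params(store, paste0(bp, ".conv2"), cout, cout, 3, 3)
          make_norm_params(store, paste0(bp, ".norm2"), cout)
          if (bcin != cout || (b == 1 && bb$strides[s] > 1)) {
            make_conv_params(store, paste0(bp, ".skip"), cout, bcin, 1, 1)
          }
        }
      }
      if (cfg$use_gca && s %in% bb$gca_stages) {
        make_gca_params(store, sprintf("gca%d", s), cout, cfg$gca$reduction)
      }
      cin <- cout
    }
    low_in <- sum(bb$stage_channels[bb$low_level_stages])
    make_conv_params(store, "lowfuse", cfg$low_width, low_in, 1, 1)
    make_norm_params(store, "lowfuse.norm", cfg$low_width)
    if (cfg$use_stlb) {
      make_stlb_params(store, "stlb", cfg$low_width, cfg$stlb)
    }
    fuse_in <- bb$stage_channels[8] + cfg$low_width +
      if (cfg$use_stlb) cfg$stlb$out_channels else 0L
    make_conv_params(store, "fuse", cfg$fuse_width, fuse_in, 1, 1)
    make_norm_params(store, "fuse.norm", cfg$fuse_width)
    if (cfg$use_stb) {
      make_stb_params(store, "stb", cfg$fuse_width, cfg$stb)
    } else {
      make_conv_params(store, "head.pred", 2, cfg$fuse_width, 1, 1)
    }
  })
  structure(list(cfg = cfg, params = store$params, seed = as.integer(seed)),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat("<seg_model ", x$cfg$backbone$arch, ", ",
      format(count_parameters(x)$total, big.mark = ","), " parameters>\n", sep = "")
  invisible(x)
}

pget <- function(model, name) {
  p <- model$params[[name]]
  if (is.null(p)) stop("missing parameter '", name, "' (channel plumbing)", call. = FALSE)
  p
}

conv_of <- function(model, name) list(w = pget(model, paste0(name, ".w")),
                                      b = model$params[[paste0(name, ".b")]])
norm_of <- function(model, name) list(gamma = pget(model, paste0(name, ".gamma")),
                                      beta = pget(model, paste0(name, ".beta")))

apply_norm <- function(x, np, norm) {
  ag_layer_norm(x, np$gamma, np$beta, per_channel = (norm == "batch"))
}

# collect a sub-block's parameters back into the structured lists the block
# forward functions expect
gca_params_of <- function(model, s) {
  pre <- sprintf("gca%d", s)
  list(ex1 = conv_of(model, paste0(pre, ".ex1")),
       ex2 = conv_of(model, paste0(pre, ".ex2")),
       comp = conv_of(model, paste0(pre, ".comp")),
       norm = norm_of(model, paste0(pre, ".norm")),
       exp_h = conv_of(model, paste0(pre, ".exp_h")),
       exp_w = conv_of(model, paste0(pre, ".exp_w")))
}

lin_of <- function(model, name) list(w = pget(model, paste0(name, ".w")),
                                     b = model$params[[paste0(name, ".b")]])

stlb_params_of <- function(model) {
  c2 <- model$cfg$stlb$c2 %||% model$cfg$low_width
  list(
    tem = list(up = lin_of(model, "stlb.tem.up"), q = lin_of(model, "stlb.tem.q"),
               k = lin_of(model, "stlb.tem.k"), v = lin_of(model, "stlb.tem.v"),
               c2 = c2),
    ptfem = list(up = lin_of(model, "stlb.ptfem.up"), mlp = lin_of(model, "stlb.ptfem.mlp")),
    proj = conv_of(model, "stlb.proj"))
}

stb_params_of <- function(model) {
  n_down <- length(model$cfg$stb$widths)
  list(down = lapply(seq_len(n_down), function(i) conv_of(model, sprintf("stb.down%d", i))),
       fc1 = lin_of(model, "stb.fc1"), fc2 = lin_of(model, "stb.fc2"),
       pred = conv_of(model, "stb.pred"))
}

#' Model forward pass
#'
#' @param model A built `seg_model`.
#' @param image H x W matrix in [0, 1] (or 1 x H x W array), H, W >= 32.
#' @return List of class `model_output`: `probabilities` (`ag`, 2 x H x W,
#'   per-pixel channel sums 1), `logits` (`ag`, 2 x head-resolution),
#'   `boundary_pred` (`ag`, Sobel boundary surrogate of the tumor channel),
#'   `affine` (`ag` 2 x 3, identity when the spatial transformer is
#'   disabled), `mask` (binary matrix from argmax).
#' @export
model_forward <- function(model, image) {
  cfg <- model$cfg; bb <- cfg$backbone
  img <- ag_value(image)
  if (is.matrix(img)) img <- array(img, dim = c(1L, nrow(img), ncol(img)))
  d <- dim(img)
  if (d[2] < 32 || d[3] < 32) stop("input spatial size must be >= 32", call. = FALSE)
  if (min(img) < -1e-8 || max(img) > 1 + 1e-8) stop("image values must lie in [0, 1]", call. = FALSE)
  H <- d[2]; W <- d[3]
  x <- ag(img)
  stage_out <- vector("list", 8)
  for (s in 1:8) {
    pre <- sprintf("stage%d", s)
    if (s <= 2) {
      cv <- conv_of(model, paste0(pre, ".conv"))
      x <- ag_relu(apply_norm(ag_conv2d(x, cv$w, cv$b, stride = bb$strides[s],
                                        pad = bb$dilations[s], dil = bb$dilations[s]),
                              norm_of(model, paste0(pre, ".norm")), bb$norm))
    } else {
      for (b in seq_len(bb$blocks[s])) {
        bp <- sprintf("%s.block%d", pre, b)
        stride <- if (b == 1) bb$strides[s] else 1L
        c1 <- conv_of(model, paste0(bp, ".conv1"))
        h <- ag_relu(apply_norm(ag_conv2d(x, c1$w, c1$b, stride = stride,
                                          pad = bb$dilations[s], dil = bb$dilations[s]),
                                norm_of(model, paste0(bp, ".norm1")), bb$norm))
        c2 <- conv_of(model, paste0(bp, ".conv2"))
        h <- apply_norm(ag_conv2d(h, c2$w, c2$b, pad = bb$dilations[s],
                                  dil = bb$dilations[s]),
                        norm_of(model, paste0(bp, ".norm2")), bb$norm)
        skip_name <- paste0(bp, ".skip.w")
        sk <- if (!is.null(model$params[[skip_name]])) {
          sc <- conv_of(model, paste0(bp, ".skip"))
          ag_conv2d(x, sc$w, sc$b, stride = stride)
        } else x
        x <- ag_relu(ag_add(h, sk))
      }
    }
    if (cfg$use_gca && s %in% bb$gca_stages) {
      x <- gca_forward(x, cfg$gca, gca_params_of(model, s))
    }
    check_finite(x, pre)
    stage_out[[s]] <- x
  }

  # low-level branch at the resolution of the deepest low-level stage
  low_size <- dim(ag_value(stage_out[[max(bb$low_level_stages)]]))[2:3]
  lows <- lapply(bb$low_level_stages, function(s)
    ag_resize_bilinear(stage_out[[s]], low_size[1], low_size[2]))
  lf <- conv_of(model, "lowfuse")
  low <- ag_relu(apply_norm(ag_conv2d(ag_concat(lows, dim = 1), lf$w, lf$b),
                            norm_of(model, "lowfuse.norm"), bb$norm))
  check_finite(low, "lowfuse")

  head_h <- max(1L, H %/% cfg$head_stride)
  head_w <- max(1L, W %/% cfg$head_stride)
  feats <- list(ag_resize_bilinear(stage_out[[8]], head_h, head_w),
                ag_resize_bilinear(low, head_h, head_w))
  if (cfg$use_stlb) {
    tex <- stlb_forward(low, stlb_params_of(model), cfg$stlb, c(head_h, head_w))
    feats <- c(feats, list(tex))
  }
  fu <- conv_of(model, "fuse")
  fused <- ag_relu(apply_norm(ag_conv2d(ag_concat(feats, dim = 1), fu$w, fu$b),
                              norm_of(model, "fuse.norm"), bb$norm))
  check_finite(fused, "fuse")

  if (cfg$use_stb) {
    stb <- stb_forward(fused, stb_params_of(model), out_size = NULL)
    pred <- stb$prediction
    logits <- stb$initial
    affine <- stb$affine
  } else {
    hp <- conv_of(model, "head.pred")
    logits <- ag_conv2d(fused, hp$w, hp$b)
    pred <- ag_softmax_channels(logits)
    affine <- ag(matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE))
  }

  up <- ag_resize_bilinear(pred, H, W)
  # renormalize per pixel (warping can shed mass at the borders)
  ssum <- ag_sum_channels(up)
  probs <- ag_mul_bcast(up, ag_pow(ag_clamp(ssum, 1e-6, Inf), -1))
  check_finite(probs, "head.probabilities")
  tumor <- ag_slice(probs, 1, 2)
  structure(list(probabilities = probs, logits = logits,
                 boundary_pred = boundary_surrogate(tumor),
                 affine = affine,
                 mask = binarize_prediction(ag_value(probs))),
            class = "model_output")
}

#' Count trainable parameters
#'
#' @param model A built `seg_model`.
#' @return List: `total` and `by_module` (named numeric, grouped by the
#'   top-level prefix of each parameter name, GCA blocks reported
#'   separately).
#' @export
count_parameters <- function(model) {
  sizes <- vapply(model$params, function(p) length(ag_value(p)), numeric(1))
  group <- sub("\\..*$", "", names(sizes))
  by_module <- tapply(sizes, group, sum)
  list(total = sum(sizes), by_module = as.list(by_module))
}

#' Save a model checkpoint
#'
#' Stores the configuration, named parameter values and seed in a single
#' RDS archive.
#'
#' @param model A `seg_model`.
#' @param path Output file.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(cfg = model$cfg, values = lapply(model$params, ag_value),
               seed = model$seed), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path Checkpoint file from [save_checkpoint()].
#' @param expect_cfg Optional configuration to validate against; a mismatch
#'   is a hard error.
#' @return A `seg_model`.
#' @export
load_checkpoint <- function(path, expect_cfg = NULL) {
  ck <- readRDS(path)
  if (!is.list(ck) || is.null(ck$cfg) || is.null(ck$values)) {
    stop("not a model checkpoint: ", path, call. = FALSE)
  }
  if (!is.null(expect_cfg) && !identical(ck$cfg, expect_cfg)) {
    stop("checkpoint configuration does not match the expected configuration",
         call. = FALSE)
  }
  params <- lapply(ck$values, function(v) ag(v, requires_grad = TRUE))
  structure(list(cfg = ck$cfg, params = params, seed = ck$seed),
            class = "seg_model")
}
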