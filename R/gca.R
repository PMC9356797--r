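# Grid contextual attention (GCA).
#
# The block splits a C x H x W feature map into a grid of patches, pools each
# patch along the height and width directions (local directional attention),
# multiplies the pooled maps with global directional attention obtained from
# whole-map pooling, passes everything through a shared compression conv and
# per-direction sigmoid expansions, and finally reweights each patch by the
# outer product of its two directional attention vectors. A padding-crop pair
# makes any patch size applicable to any map size.

#' GCA configuration
#'
#' @param patch_h,patch_w Patch size (grid cell) in pixels.
#' @param reduction Channel compression divisor for the shared conv.
#' @param residual Add the input map to the reweighted map (residual strategy).
#' @return A list of class `gca_config`.
#' @export
gca_config <- function(patch_h = 8, patch_w = 8, reduction = 4, residual = TRUE) {
  stopifnot(patch_h >= 1, patch_w >= 1, reduction >= 1)
  structure(list(patch_h = as.integer(patch_h), patch_w = as.integer(patch_w),
                 reduction = as.integer(reduction), residual = isTRUE(residual)),
            class = "gca_config")
}

#' Pad a feature map so its spatial size is a multiple of the patch grid
#'
#' Replicate-edge padding on the bottom/right; the returned record inverts
#' the operation exactly via [crop_from_grid()].
#'
#' @param x Array C x H x W or `ag` node.
#' @param patch_h,patch_w Patch size.
#' @return List with `map` (padded, same type as input) and `pad`
#'   (c(pad_h, pad_w)).
#' @export
pad_to_grid <- function(x, patch_h, patch_w) {
  d <- dim(ag_value(x))
  pad_h <- (patch_h - d[2] %% patch_h) %% patch_h
  pad_w <- (patch_w - d[3] %% patch_w) %% patch_w
  map <- if (pad_h == 0 && pad_w == 0) x
         else if (is_ag(x)) ag_pad_replicate(x, pad_h, pad_w)
         else ag_value(ag_pad_replicate(ag(x), pad_h, pad_w))
  list(map = map, pad = c(pad_h = pad_h, pad_w = pad_w))
}

#' Crop a padded feature map back to its original size
#' @param x Array or `ag` node, C x Hp x Wp.
#' @param pad Padding record from [pad_to_grid()].
#' @export
crop_from_grid <- function(x, pad) {
  d <- dim(ag_value(x))
  H <- d[2] - pad[[1]]; W <- d[3] - pad[[2]]
  if (is_ag(x)) ag_crop(x, H, W) else ag_value(x)[, seq_len(H), seq_len(W), drop = FALSE]
}

#' Split a feature map into an indexed patch grid
#'
#' @param x Array C x H x W with H, W divisible by the patch size.
#' @param patch_h,patch_w Patch size.
#' @return 5-D array C x patch_h x patch_w x (H/patch_h) x (W/patch_w);
#'   element `[, , , i, j]` is patch (i, j).
#' @export
split_patches <- function(x, patch_h, patch_w) {
  d <- dim(x)
  if (d[2] %% patch_h != 0 || d[3] %% patch_w != 0) {
    stop("spatial size not divisible by patch size; pad first", call. = FALSE)
  }
  nI <- d[2] %/% patch_h; nJ <- d[3] %/% patch_w
  v <- array(x, dim = c(d[1], patch_h, nI, patch_w, nJ))
  aperm(v, c(1, 2, 4, 3, 5))
}

#' Reassemble a patch grid into a feature map (inverse of [split_patches()])
#' @param p 5-D patch array from [split_patches()].
#' @export
merge_patches <- function(p) {
  d <- dim(p)
  v <- aperm(p, c(1, 2, 4, 3, 5))
  array(v, dim = c(d[1], d[2] * d[4], d[3] * d[5]))
}

# parameters: shared excitation convs (global attention), shared compression
# conv + norm, and per-direction expansion convs
make_gca_params <- function(store, prefix, C, reduction) {
  Cr <- max(1L, C %/% reduction)
  list(
    ex1 = make_conv_params(store, paste0(prefix, ".ex1"), Cr, C, 1, 1),
    ex2 = make_conv_params(store, paste0(prefix, ".ex2"), C, Cr, 1, 1),
    comp = make_conv_params(store, paste0(prefix, ".comp"), Cr, C, 1, 1),
    norm = make_norm_params(store, paste0(prefix, ".norm"), Cr),
    exp_h = make_conv_params(store, paste0(prefix, ".exp_h"), C, Cr, 1, 1),
    exp_w = make_conv_params(store, paste0(prefix, ".exp_w"), C, Cr, 1, 1)
  )
}

# activation transformation: ReLU -> 1x1 conv -> sigmoid -> 1x1 conv
gca_excit <- function(x, params) {
  ag_conv2d(ag_sigmoid(ag_conv2d(ag_relu(x), params$ex1$w, params$ex1$b)),
            params$ex2$w, params$ex2$b)
}

#' Global directional attention of a feature map
#'
#' Average-pools the map over the width (height) direction and passes the
#' result through the excitation transform, giving one attention profile per
#' direction.
#'
#' @param x Array or `ag` node, C x H x W.
#' @param params GCA parameter list (from a built model) containing `ex1`,
#'   `ex2` conv parameters.
#' @return List with `height_attn` (C x H x 1) and `width_attn` (C x 1 x W)
#'   `ag` nodes.
#' @export
gca_global_attention <- function(x, params) {
  x <- if (is_ag(x)) x else ag(x)
  list(height_attn = gca_excit(ag_avg_w(x), params),
       width_attn = gca_excit(ag_avg_h(x), params))
}

#' Grid contextual attention forward pass
#'
#' @param x Array or `ag` node, C x H x W.
#' @param cfg [gca_config()].
#' @param params GCA parameters from [make_gca_params] via a built model.
#' @param bypass_attention Replace the final attention map by all-ones
#'   (testing aid: the block becomes the identity, or doubling in residual
#'   mode).
#' @return `ag` node with the same shape as the input.
#' @export
gca_forward <- function(x, cfg, params, bypass_attention = FALSE) {
  x <- if (is_ag(x)) x else ag(x)
  d <- dim(ag_value(x)); C <- d[1]; H <- d[2]; W <- d[3]
  Ph <- cfg$patch_h; Pw <- cfg$patch_w
  pg <- pad_to_grid(x, Ph, Pw)
  xp <- pg$map
  dp <- dim(ag_value(xp)); Hp <- dp[2]; Wp <- dp[3]
  nI <- Hp %/% Ph; nJ <- Wp %/% Pw

  if (bypass_attention) {
    rew <- xp
  } else {
    glob <- gca_global_attention(xp, params)
    check_finite(glob$height_attn, "gca.global_attention")
    # local directional pooling per patch, already concatenated by block index
    loc_h <- ag_avg_pool_w(xp, Pw)               # C x Hp x nJ
    loc_w <- ag_avg_pool_h(xp, Ph)               # C x nI x Wp
    th <- ag_mul_bcast(loc_h, glob$height_attn)  # fuse local with global
    tw <- ag_mul_bcast(loc_w, glob$width_attn)
    # shared compression over the concatenated directional sequences
    seq_h <- ag_reshape(th, c(C, Hp * nJ, 1))
    seq_w <- ag_reshape(tw, c(C, nI * Wp, 1))
    sq <- ag_concat(list(seq_h, seq_w), dim = 2)
    comp <- ag_relu(ag_layer_norm(ag_conv2d(sq, params$comp$w, params$comp$b),
                                  params$norm$gamma, params$norm$beta))
    check_finite(comp, "gca.compress")
    Cr <- dim(ag_value(comp))[1]
    ch <- ag_reshape(ag_slice(comp, 2, seq_len(Hp * nJ)), c(Cr, Hp, nJ))
    cw <- ag_reshape(ag_slice(comp, 2, Hp * nJ + seq_len(nI * Wp)), c(Cr, nI, Wp))
    # per-direction expansion back to C channels, squashed to (0,1)
    eh <- ag_sigmoid(ag_conv2d(ch, params$exp_h$w, params$exp_h$b))  # C x Hp x nJ
    ew <- ag_sigmoid(ag_conv2d(cw, params$exp_w$w, params$exp_w$b))  # C x nI x Wp
    # per-patch outer product, expressed as two gathered full-size maps
    jmap <- rep(seq_len(nJ), each = Pw)
    imap <- rep(seq_len(nI), each = Ph)
    a_full <- ag_mul(ag_expand_w(eh, jmap), ag_expand_h(ew, imap))
    check_finite(a_full, "gca.attention_map")
    rew <- ag_mul(a_full, xp)
  }
  out <- crop_from_grid(rew, pg$pad)
  if (cfg$residual) out <- ag_add(x, out)
  check_finite(out, "gca.output")
  out
}
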