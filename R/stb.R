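# Spatial transformer block (STB): a localization branch regresses a 2x3
# affine matrix from the fused features, a 1x1 conv + softmax branch forms
# the initial class-probability map, and a bilinear sampler resamples the
# initial map through the affine transform. The regression head is
# initialized with zero weights and identity bias [1, 0, 0, 0, 1, 0], so an
# untrained block is exactly the identity on the prediction map.
#
# Coordinate convention: normalized target coordinates x, y in [-1, 1] with
# pixel centers at -1 + (2k - 1)/size. Internally the affine map is composed
# into pixel space so that the identity matrix reproduces integer pixel
# coordinates exactly (bit-exact identity warp). Out-of-bounds samples
# contribute zero.

#' STB configuration
#' @param widths Channels of the three stride-2 localization convs.
#' @param fc Hidden width of the regression head.
#' @export
stb_config <- function(widths = c(32, 32, 32), fc = 32) {
  structure(list(widths = as.integer(widths), fc = as.integer(fc)),
            class = "stb_config")
}

make_stb_params <- function(store, prefix, C, cfg) {
  widths <- cfg$widths
  down <- vector("list", length(widths))
  cin <- C
  for (i in seq_along(widths)) {
    down[[i]] <- make_conv_params(store, paste0(prefix, ".down", i),
                                  widths[i], cin, 3, 3)
    cin <- widths[i]
  }
  list(
    down = down,
    fc1 = make_linear_params(store, paste0(prefix, ".fc1"), cfg$fc, cin),
    fc2 = make_linear_params(store, paste0(prefix, ".fc2"), 6, cfg$fc,
                             zero = TRUE, bias_init = c(1, 0, 0, 0, 1, 0)),
    pred = make_conv_params(store, paste0(prefix, ".pred"), 2, C, 1, 1)
  )
}

#' Localization branch: regress an affine matrix from features
#'
#' Three stride-2 convs with ReLU, global average pooling, and two fully
#' connected layers whose final weights start at zero with identity bias, so
#' a freshly initialized head outputs the identity transform for any input.
#'
#' @param x Array or `ag` node, C x H x W.
#' @param params STB parameter list.
#' @return `ag` node, 2 x 3 affine matrix (rows: target-to-source x and y).
#' @export
stb_localize <- function(x, params) {
  x <- if (is_ag(x)) x else ag(x)
  h <- x
  for (cv in params$down) {
    h <- ag_relu(ag_conv2d(h, cv$w, cv$b, stride = 2, pad = 1))
  }
  v <- ag_reshape(ag_global_avg(h), dim(ag_value(h))[1])
  h1 <- ag_relu(ag_linear(v, params$fc1$w, params$fc1$b))
  th <- ag_linear(h1, params$fc2$w, params$fc2$b)    # (a11,a12,a13,a21,a22,a23)
  ag_t(ag_reshape(th, c(3, 2)))
}

#' Initial prediction branch: per-pixel class probabilities
#'
#' @param x Array or `ag` node, C x H x W.
#' @param params STB parameter list (uses the `pred` 1x1 conv).
#' @return `ag` node, 2 x H x W softmax map (channel 1 background,
#'   channel 2 tumor); per-pixel channel sums are 1.
#' @export
stb_initial_prediction <- function(x, params) {
  x <- if (is_ag(x)) x else ag(x)
  ag_softmax_channels(ag_conv2d(x, params$pred$w, params$pred$b))
}

#' Resample a prediction map through an affine transform
#'
#' Source coordinates are the affine image of each target pixel; the output
#' is the bilinear interpolation of the input at those points, with zero
#' contribution from samples outside the map. Differentiable in both the map
#' and the affine matrix.
#'
#' @param pred Array or `ag` node, C x H x W.
#' @param theta `ag` node or 2 x 3 matrix (target-to-source, normalized
#'   coordinates).
#' @return `ag` node, C x H x W.
#' @export
ag_warp_affine <- function(pred, theta) {
  pred <- if (is_ag(pred)) pred else ag(pred)
  vp <- ag_value(pred); d <- dim(vp)
  C <- d[1]; H <- d[2]; W <- d[3]
  th <- ag_value(theta)
  a11 <- th[1, 1]; a12 <- th[1, 2]; a13 <- th[1, 3]
  a21 <- th[2, 1]; a22 <- th[2, 2]; a23 <- th[2, 3]
  it <- matrix(seq_len(H), H, W)
  jt <- matrix(seq_len(W), H, W, byrow = TRUE)
  # pixel-space composition of the normalized-coordinate affine map; the
  # grouping makes the identity matrix give js == jt, is == it exactly
  js <- a11 * (jt - 0.5) + a12 * (it - 0.5) * (W / H) +
    (a13 - a11 - a12 + 1) * (W / 2) + 0.5
  is <- a21 * (jt - 0.5) * (H / W) + a22 * (it - 0.5) +
    (a23 - a21 - a22 + 1) * (H / 2) + 0.5
  j0 <- floor(js); i0 <- floor(is)
  fj <- js - j0; fi <- is - i0

  corner <- function(ii, jj) {
    valid <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
    idx <- pmin(pmax(ii, 1), H) + H * (pmin(pmax(jj, 1), W) - 1)
    list(valid = valid, idx = idx)
  }
  cs <- list(c00 = corner(i0, j0), c01 = corner(i0, j0 + 1),
             c10 = corner(i0 + 1, j0), c11 = corner(i0 + 1, j0 + 1))
  wts <- list(c00 = (1 - fi) * (1 - fj), c01 = (1 - fi) * fj,
              c10 = fi * (1 - fj), c11 = fi * fj)

  out <- array(0, dim = d)
  for (c in seq_len(C)) {
    pc <- vp[c, , ]
    acc <- matrix(0, H, W)
    for (k in names(cs)) {
      acc <- acc + wts[[k]] * cs[[k]]$valid * pc[cs[[k]]$idx]
    }
    out[c, , ] <- acc
  }

  ag_node(out, list(pred, theta), function(g) {
    gp <- NULL
    if (is_ag(pred) && pred$requires) {
      gp <- array(0, dim = d)
      for (c in seq_len(C)) {
        gc <- g[c, , ]
        dpc <- numeric(H * W)
        for (k in names(cs)) {
          vals <- as.numeric(wts[[k]] * cs[[k]]$valid * gc)
          keep <- vals != 0
          if (any(keep)) {
            s <- rowsum(vals[keep], as.numeric(cs[[k]]$idx)[keep])
            ii <- as.integer(rownames(s))
            dpc[ii] <- dpc[ii] + s[, 1]
          }
        }
        gp[c, , ] <- matrix(dpc, H, W)
      }
    }
    gt <- NULL
    if (is_ag(theta) && theta$requires) {
      gj <- matrix(0, H, W); gi <- matrix(0, H, W)
      for (c in seq_len(C)) {
        pc <- vp[c, , ]
        gc <- g[c, , ]
        v00 <- cs$c00$valid * pc[cs$c00$idx]; v01 <- cs$c01$valid * pc[cs$c01$idx]
        v10 <- cs$c10$valid * pc[cs$c10$idx]; v11 <- cs$c11$valid * pc[cs$c11$idx]
        gj <- gj + gc * ((1 - fi) * (v01 - v00) + fi * (v11 - v10))
        gi <- gi + gc * ((1 - fj) * (v10 - v00) + fj * (v11 - v01))
      }
      gt <- matrix(0, 2, 3)
      gt[1, 1] <- sum(gj * ((jt - 0.5) - W / 2))
      gt[1, 2] <- sum(gj * ((it - 0.5) * (W / H) - W / 2))
      gt[1, 3] <- sum(gj) * (W / 2)
      gt[2, 1] <- sum(gi * ((jt - 0.5) * (H / W) - H / 2))
      gt[2, 2] <- sum(gi * ((it - 0.5) - H / 2))
      gt[2, 3] <- sum(gi) * (H / 2)
    }
    list(gp, gt)
  })
}

#' STB forward pass
#'
#' Warps the initial prediction by the regressed affine matrix; optionally
#' bilinearly resizes the result to an output resolution.
#'
#' @param x Array or `ag` node of fused features, C x H x W.
#' @param params STB parameter list from a built model.
#' @param out_size Optional c(H, W) for the final bilinear upsample; NULL
#'   keeps the feature resolution.
#' @return List: `prediction` (`ag`, 2 x H x W), `initial` (`ag`), `affine`
#'   (`ag`, 2 x 3).
#' @export
stb_forward <- function(x, params, out_size = NULL) {
  x <- if (is_ag(x)) x else ag(x)
  pred0 <- stb_initial_prediction(x, params)
  theta <- stb_localize(x, params)
  check_finite(theta, "stb.localize")
  warped <- ag_warp_affine(pred0, theta)
  check_finite(warped, "stb.warp")
  out <- if (is.null(out_size)) warped
         else ag_resize_bilinear(warped, out_size[1], out_size[2])
  list(prediction = out, initial = pred0, affine = theta)
}
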