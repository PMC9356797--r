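# Network primitives built on the autograd core: 2-D convolution (im2col in
# compiled code), directional/global average pooling, bilinear resizing,
# layer/instance normalization, fully connected layers, weight init and Adam.

#' 2-D convolution of a C x H x W tensor
#'
#' @param x `ag` node, array Cin x H x W.
#' @param w `ag` node, weight array Cout x Cin x kh x kw.
#' @param b `ag` node of length Cout, or NULL.
#' @param stride,pad,dil Stride, zero-padding and dilation (scalars).
#' @return `ag` node, array Cout x Ho x Wo.
#' @export
ag_conv2d <- function(x, w, b = NULL, stride = 1, pad = 0, dil = 1) {
  vx <- ag_value(x); vw <- ag_value(w)
  d <- dim(vx); dw <- dim(vw)
  stopifnot(length(d) == 3, length(dw) == 4, d[1] == dw[2])
  C <- d[1]; H <- d[2]; W <- d[3]
  Cout <- dw[1]; kh <- dw[3]; kw <- dw[4]
  cols <- im2col_cpp(as.numeric(vx), C, H, W, kh, kw, stride, pad, dil)
  Wmat <- matrix(vw, nrow = Cout)
  outm <- Wmat %*% cols
  if (!is.null(b)) outm <- outm + ag_value(b)
  Ho <- (H + 2 * pad - dil * (kh - 1) - 1) %/% stride + 1
  Wo <- (W + 2 * pad - dil * (kw - 1) - 1) %/% stride + 1
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(array(outm, dim = c(Cout, Ho, Wo)), parents, function(g) {
    gmat <- matrix(g, nrow = Cout)
    gx <- if (is_ag(x)) array(col2im_cpp(t(Wmat) %*% gmat, C, H, W, kh, kw, stride, pad, dil), dim = d) else NULL
    gw <- array(gmat %*% t(cols), dim = dw)
    if (is.null(b)) list(gx, gw) else list(gx, gw, rowSums(gmat))
  })
}

#' Global average pooling to a C x 1 x 1 tensor
#' @param x `ag` node, C x H x W.
#' @export
ag_global_avg <- function(x) {
  vx <- ag_value(x); d <- dim(vx); n <- d[2] * d[3]
  v <- array(rowMeans(matrix(vx, nrow = d[1])), dim = c(d[1], 1, 1))
  ag_node(v, list(x), function(g) {
    list(array(rep(as.numeric(g) / n, n), dim = d))
  })
}

#' Average pooling over the width direction (C x H x W -> C x H x 1)
#' @param x `ag` node.
#' @export
ag_avg_w <- function(x) {
  vx <- ag_value(x); d <- dim(vx)
  v <- array(rowMeans(matrix(vx, nrow = d[1] * d[2])), dim = c(d[1], d[2], 1))
  ag_node(v, list(x), function(g) {
    list(array(rep(as.numeric(g), d[3]) / d[3], dim = d))
  })
}

#' Average pooling over the height direction (C x H x W -> C x 1 x W)
#' @param x `ag` node.
#' @export
ag_avg_h <- function(x) {
  vx <- ag_value(x); d <- dim(vx)
  m <- matrix(aperm(vx, c(2, 1, 3)), nrow = d[2])     # H x (C*W)
  v <- array(colMeans(m), dim = c(d[1], 1, d[3]))
  ag_node(v, list(x), function(g) {
    gg <- aperm(array(as.numeric(g) / d[2], dim = c(d[1], d[3], d[2])), c(1, 3, 2))
    list(gg)
  })
}

#' Non-overlapping average pooling by an integer factor
#' @param x `ag` node, C x H x W with H, W divisible by `k`.
#' @param k Pooling factor.
#' @export
ag_avg_pool <- function(x, k) {
  vx <- ag_value(x); d <- dim(vx)
  stopifnot(d[2] %% k == 0, d[3] %% k == 0)
  Ho <- d[2] %/% k; Wo <- d[3] %/% k
  v5 <- array(vx, dim = c(d[1], k, Ho, k, Wo))
  v <- apply(v5, c(1, 3, 5), mean)
  ag_node(array(v, dim = c(d[1], Ho, Wo)), list(x), function(g) {
    g5 <- array(0, dim = c(d[1], k, Ho, k, Wo))
    gb <- array(as.numeric(g) / (k * k), dim = c(d[1], Ho, Wo))
    for (a_ in seq_len(k)) for (b_ in seq_len(k)) g5[, a_, , b_, ] <- gb
    list(array(g5, dim = d))
  })
}

# Interpolation matrix mapping n_in samples to n_out samples with pixel-center
# alignment; rows sum to 1, edges clamped.
interp_matrix <- function(n_out, n_in) {
  R <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * n_in / n_out - 0.5   # 0-based source coordinate
    j0 <- floor(src); fr <- src - j0
    j0c <- min(max(j0, 0), n_in - 1); j1c <- min(max(j0 + 1, 0), n_in - 1)
    R[i, j0c + 1] <- R[i, j0c + 1] + (1 - fr)
    R[i, j1c + 1] <- R[i, j1c + 1] + fr
  }
  R
}

resize_apply <- function(v, Rh, Rw) {
  d <- dim(v)
  m <- matrix(aperm(v, c(2, 1, 3)), nrow = d[2])          # H x (C*W)
  y <- Rh %*% m                                            # Ho x (C*W)
  v2 <- aperm(array(y, dim = c(nrow(Rh), d[1], d[3])), c(2, 1, 3))
  m2 <- matrix(aperm(v2, c(3, 1, 2)), nrow = d[3])         # W x (C*Ho)
  y2 <- Rw %*% m2
  aperm(array(y2, dim = c(nrow(Rw), d[1], nrow(Rh))), c(2, 3, 1))
}

#' Bilinear resize of a C x H x W tensor
#' @param x `ag` node.
#' @param Ho,Wo Target spatial size.
#' @export
ag_resize_bilinear <- function(x, Ho, Wo) {
  vx <- ag_value(x); d <- dim(vx)
  if (Ho == d[2] && Wo == d[3]) return(if (is_ag(x)) ag_node(vx, list(x), function(g) list(g)) else ag(vx))
  Rh <- interp_matrix(Ho, d[2]); Rw <- interp_matrix(Wo, d[3])
  ag_node(resize_apply(vx, Rh, Rw), list(x), function(g) {
    list(resize_apply(array(g, dim = c(d[1], Ho, Wo)), t(Rh), t(Rw)))
  })
}

#' Layer normalization over all of (C, H, W) with per-channel affine
#'
#' Normalizes each sample's whole feature map to zero mean / unit variance,
#' then applies a learned per-channel gain and bias. With `per_channel = TRUE`
#' statistics are instead computed per channel over (H, W), the single-sample
#' equivalent of batch normalization.
#'
#' @param x `ag` node, C x H x W.
#' @param gamma,beta `ag` nodes of length C.
#' @param eps Variance floor.
#' @param per_channel Normalize each channel separately.
#' @export
ag_layer_norm <- function(x, gamma, beta, eps = 1e-5, per_channel = FALSE) {
  vx <- ag_value(x); d <- dim(vx)
  vg <- ag_value(gamma); vb <- ag_value(beta)
  if (per_channel) {
    m <- matrix(vx, nrow = d[1])
    mu <- rowMeans(m); va <- rowMeans((m - mu)^2)
    n <- d[2] * d[3]
    istd <- 1 / sqrt(va + eps)
    xhat <- (m - mu) * istd
    y <- array(xhat * vg + vb, dim = d)
    ag_node(y, list(x, gamma, beta), function(g) {
      gm <- matrix(g, nrow = d[1])
      dgamma <- rowSums(gm * xhat); dbeta <- rowSums(gm)
      dxh <- gm * vg
      gx <- istd * (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat))
      list(array(gx, dim = d), dgamma, dbeta)
    })
  } else {
    n <- length(vx)
    mu <- mean(vx); va <- mean((vx - mu)^2)
    istd <- 1 / sqrt(va + eps)
    xhat <- (vx - mu) * istd
    gch <- rep(vg, d[2] * d[3]); bch <- rep(vb, d[2] * d[3])
    y <- array(xhat * gch + bch, dim = d)
    ag_node(y, list(x, gamma, beta), function(g) {
      gv <- as.numeric(g)
      dgamma <- rowSums(matrix(gv * xhat, nrow = d[1]))
      dbeta <- rowSums(matrix(gv, nrow = d[1]))
      dxh <- gv * gch
      gx <- istd * (dxh - mean(dxh) - xhat * mean(dxh * xhat))
      list(array(gx, dim = d), dgamma, dbeta)
    })
  }
}

#' Fully connected layer y = W x + b
#' @param x `ag` node, numeric vector (treated as a column).
#' @param w `ag` node, out x in matrix.
#' @param b `ag` node of length out, or NULL.
#' @export
ag_linear <- function(x, w, b = NULL) {
  vx <- as.numeric(ag_value(x)); vw <- ag_value(w)
  v <- as.numeric(vw %*% vx)
  if (!is.null(b)) v <- v + ag_value(b)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(v, parents, function(g) {
    g <- as.numeric(g)
    gx <- same_shape(as.numeric(t(vw) %*% g), ag_value(x))
    gw <- outer(g, vx)
    if (is.null(b)) list(gx, gw) else list(gx, gw, g)
  })
}

# ---- parameter store, init, optimizer --------------------------------------

new_param_store <- function() {
  e <- new.env(parent = emptyenv())
  e$params <- list()
  e
}

add_param <- function(store, name, value) {
  p <- ag(value, requires_grad = TRUE)
  store$params[[name]] <- p
  p
}

#' Kaiming-uniform weight initialization
#'
#' Draws from U(-sqrt(6/fan_in), sqrt(6/fan_in)); the standard fan-in rule
#' for ReLU networks. Consumes the current RNG stream.
#'
#' @param dims Dimension vector of the weight array.
#' @param fan_in Fan-in; defaults to prod(dims[-1]).
#' @return Numeric array.
#' @export
kaiming_uniform <- function(dims, fan_in = prod(dims[-1])) {
  bound <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -bound, bound), dim = dims)
}

# conv parameter pair; bias initialized to zero
make_conv_params <- function(store, name, Cout, Cin, kh, kw, bias = TRUE) {
  w <- add_param(store, paste0(name, ".w"), kaiming_uniform(c(Cout, Cin, kh, kw)))
  b <- if (bias) add_param(store, paste0(name, ".b"), numeric(Cout)) else NULL
  list(w = w, b = b)
}

make_linear_params <- function(store, name, n_out, n_in, bias = TRUE,
                               zero = FALSE, bias_init = NULL) {
  wv <- if (zero) matrix(0, n_out, n_in) else matrix(kaiming_uniform(c(n_out, n_in), n_in), n_out, n_in)
  w <- add_param(store, paste0(name, ".w"), wv)
  b <- NULL
  if (bias) {
    bv <- if (is.null(bias_init)) numeric(n_out) else bias_init
    b <- add_param(store, paste0(name, ".b"), bv)
  }
  list(w = w, b = b)
}

make_norm_params <- function(store, name, C) {
  list(gamma = add_param(store, paste0(name, ".gamma"), rep(1, C)),
       beta = add_param(store, paste0(name, ".beta"), numeric(C)))
}

#' Initialize Adam optimizer state
#' @param params Named list of `ag` leaf parameters.
#' @export
adam_init <- function(params) {
  list(m = lapply(params, function(p) 0 * ag_value(p)),
       v = lapply(params, function(p) 0 * ag_value(p)),
       t = 0L)
}

#' One Adam update step (in place on the parameter values)
#' @param state State from [adam_init()].
#' @param params Named list of `ag` parameters with accumulated gradients.
#' @param lr Learning rate.
#' @param beta1,beta2,eps Adam moment decays and denominator floor.
#' @return Updated state.
#' @export
adam_step <- function(state, params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    p <- params[[nm]]
    g <- p$grad
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1; vhat <- state$v[[nm]] / bc2
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

# abort with the stage name if a forward intermediate goes non-finite
check_finite <- function(x, stage) {
  if (!all(is.finite(ag_value(x)))) {
    stop("non-finite values at stage '", stage, "'", call. = FALSE)
  }
  x
}
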