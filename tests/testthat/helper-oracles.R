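# Independent straight-loop oracles used to cross-check the vectorized
# implementations. These are deliberately naive: per-pixel / per-patch
# loops written directly from the operator definitions, sharing no code
# with the package internals beyond parameter values.

# 1-d quantization-counting oracle: per-pixel cosine similarity to the mean
# feature, min-max normalization, levels, soft encoding, histogram counting.
qco1d_oracle <- function(x, N) {
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  a <- numeric(C)
  for (c in 1:C) a[c] <- mean(x[c, , ])
  S <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    v <- x[, i, j]
    S[i, j] <- sum(a * v) / (sqrt(sum(a^2)) * sqrt(sum(v^2)))
  }
  S <- (S - min(S)) / (max(S) - min(S))
  L <- (1:N) / N * (max(S) - min(S)) + min(S)
  E <- matrix(0, N, H * W)
  idx <- 0
  for (j in 1:W) for (i in 1:H) {   # column-major pixel order (h fastest)
    idx <- idx + 1
    for (n in 1:N) {
      d <- L[n] - S[i, j]
      if (d >= -0.5 / N && d < 0.5 / N) E[n, idx] <- 1 - abs(d)
    }
  }
  counts <- rowSums(E)
  if (sum(counts) > 0) counts <- counts / sum(counts)
  list(S = S, levels = L, E = E, counts = counts)
}

# 2-d co-occurrence oracle: loops over all width-adjacent pixel pairs and
# accumulates the outer products of their encodings.
qco2d_oracle <- function(x, N) {
  o <- qco1d_oracle(x, N)
  H <- dim(x)[2]; W <- dim(x)[3]
  M <- matrix(0, N, N)
  for (j in 1:(W - 1)) for (i in 1:H) {
    el <- o$E[, i + H * (j - 1)]
    er <- o$E[, i + H * j]
    M <- M + outer(el, er)
  }
  if (sum(M) > 0) M <- M / sum(M)
  list(E = o$E, counts2 = M, levels = o$levels)
}

# grid contextual attention oracle: per-patch loops over the published
# pipeline with the same weights as a built block.
gca_oracle <- function(x, cfg, params) {
  val <- function(p) gcaseg::ag_value(p)
  C <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  Ph <- cfg$patch_h; Pw <- cfg$patch_w
  stopifnot(H %% Ph == 0, W %% Pw == 0)
  nI <- H / Ph; nJ <- W / Pw
  w_ex1 <- val(params$ex1$w); b_ex1 <- val(params$ex1$b)
  w_ex2 <- val(params$ex2$w); b_ex2 <- val(params$ex2$b)
  excit <- function(v) {
    u <- pmax(v, 0)
    u <- as.numeric(matrix(w_ex1, nrow = dim(w_ex1)[1]) %*% u) + b_ex1
    u <- 1 / (1 + exp(-u))
    as.numeric(matrix(w_ex2, nrow = dim(w_ex2)[1]) %*% u) + b_ex2
  }
  # global directional attention
  Ah <- matrix(0, C, H); Aw <- matrix(0, C, W)
  for (h in 1:H) Ah[, h] <- excit(rowMeans(x[, h, , drop = FALSE][, 1, ]))
  for (w in 1:W) Aw[, w] <- excit(rowMeans(x[, , w, drop = FALSE][, , 1]))
  # local directional attention per patch, fused with the global profiles
  th <- array(0, dim = c(C, H, nJ))   # column block j holds A_j^h
  tw <- array(0, dim = c(C, nI, W))
  for (j in 1:nJ) for (h in 1:H) {
    cols <- (j - 1) * Pw + 1:Pw
    th[, h, j] <- rowMeans(x[, h, cols, drop = FALSE][, 1, ]) * Ah[, h]
  }
  for (i in 1:nI) for (w in 1:W) {
    rows <- (i - 1) * Ph + 1:Ph
    tw[, i, w] <- rowMeans(x[, rows, w, drop = FALSE][, , 1]) * Aw[, w]
  }
  # shared compression conv, then joint layer norm over the whole sequence,
  # ReLU, then per-direction sigmoid expansion
  w_c <- matrix(val(params$comp$w), nrow = dim(val(params$comp$w))[1])
  b_c <- val(params$comp$b)
  Cr <- nrow(w_c)
  seq_list <- list()
  for (j in 1:nJ) for (h in 1:H) seq_list[[length(seq_list) + 1]] <- th[, h, j]
  n_h <- length(seq_list)
  for (w in 1:W) for (i in 1:nI) seq_list[[length(seq_list) + 1]] <- tw[, i, w]
  comp <- matrix(sapply(seq_list, function(v) as.numeric(w_c %*% v) + b_c),
                 nrow = Cr)  # Cr x L
  mu <- mean(comp); sd2 <- mean((comp - mu)^2)
  gam <- val(params$norm$gamma); bet <- val(params$norm$beta)
  comp <- (comp - mu) / sqrt(sd2 + 1e-5) * gam + bet
  comp <- pmax(comp, 0)
  w_eh <- matrix(val(params$exp_h$w), nrow = C); b_eh <- val(params$exp_h$b)
  w_ew <- matrix(val(params$exp_w$w), nrow = C); b_ew <- val(params$exp_w$b)
  eh <- array(0, dim = c(C, H, nJ)); ew <- array(0, dim = c(C, nI, W))
  k <- 0
  for (j in 1:nJ) for (h in 1:H) {
    k <- k + 1
    eh[, h, j] <- 1 / (1 + exp(-(as.numeric(w_eh %*% comp[, k]) + b_eh)))
  }
  for (w in 1:W) for (i in 1:nI) {
    k <- k + 1
    ew[, i, w] <- 1 / (1 + exp(-(as.numeric(w_ew %*% comp[, k]) + b_ew)))
  }
  # per-patch outer product and reweighting
  out <- array(0, dim = dim(x))
  for (i in 1:nI) for (j in 1:nJ) {
    rows <- (i - 1) * Ph + 1:Ph; cols <- (j - 1) * Pw + 1:Pw
    for (c in 1:C) {
      Am <- outer(eh[c, rows, j], ew[c, i, cols])
      out[c, rows, cols] <- Am * x[c, rows, cols]
    }
  }
  if (cfg$residual) out <- out + x
  out
}

# affine resampling oracle: the full bilinear-kernel double sum per output
# pixel, in normalized coordinates.
warp_oracle <- function(pred, M) {
  C <- dim(pred)[1]; H <- dim(pred)[2]; W <- dim(pred)[3]
  out <- array(0, dim = dim(pred))
  for (ot in 1:H) for (jt in 1:W) {
    xt <- -1 + (2 * jt - 1) / W
    yt <- -1 + (2 * ot - 1) / H
    xs <- M[1, 1] * xt + M[1, 2] * yt + M[1, 3]
    ys <- M[2, 1] * xt + M[2, 2] * yt + M[2, 3]
    js <- (xs + 1) * W / 2 + 0.5
    is <- (ys + 1) * H / 2 + 0.5
    for (c in 1:C) {
      acc <- 0
      for (i in 1:H) for (j in 1:W) {
        acc <- acc + pred[c, i, j] * max(0, 1 - abs(js - j)) * max(0, 1 - abs(is - i))
      }
      out[c, ot, jt] <- acc
    }
  }
  out
}

# small helpers shared by the tests -----------------------------------------

rand_map <- function(C, H, W, seed = 1) {
  withr::with_seed(seed, array(stats::rnorm(C * H * W), dim = c(C, H, W)))
}

rand_mask <- function(H, W, p = 0.3, seed = 1) {
  withr::with_seed(seed, matrix((stats::runif(H * W) < p) * 1, H, W))
}

# a parameter set for a standalone block outside a full model
block_params <- function(maker, ..., seed = 1) {
  store <- gcaseg:::new_param_store()
  withr::with_seed(seed, maker(store, "t", ...))
}
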