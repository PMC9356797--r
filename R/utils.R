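# Small shared helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

# run `expr` under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# derive a bounded child seed from a master seed (keeps values < 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 10007) %% 2147483629)
}

as_cHW <- function(x) {
  if (is.matrix(x)) array(x, dim = c(1L, nrow(x), ncol(x))) else x
}

# ---- additional broadcast / indexing autograd ops used by the blocks ------

#' Multiply with broadcasting over singleton dimensions of `b`
#' @param a `ag` node, 3-D array.
#' @param b `ag` node, 3-D array whose dims equal a's or 1.
#' @export
ag_mul_bcast <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  da <- dim(va); db <- dim(vb)
  stopifnot(all(db == da | db == 1L))
  rep_idx <- lapply(1:3, function(k) if (db[k] == 1L) rep(1L, da[k]) else seq_len(da[k]))
  vbe <- vb[rep_idx[[1]], rep_idx[[2]], rep_idx[[3]], drop = FALSE]
  sum_dim <- function(x, k) {
    d <- dim(x)
    switch(k,
      array(colSums(matrix(x, nrow = d[1])), dim = c(1L, d[2], d[3])),
      {
        m <- matrix(aperm(x, c(2, 1, 3)), nrow = d[2])
        array(colSums(m), dim = c(d[1], 1L, d[3]))
      },
      array(rowSums(matrix(x, nrow = d[1] * d[2])), dim = c(d[1], d[2], 1L)))
  }
  ag_node(va * vbe, list(a, b), function(g) {
    gb <- g * va
    for (k in 3:1) if (db[k] == 1L) gb <- sum_dim(gb, k)
    list(if (is_ag(a)) g * vbe else NULL, if (is_ag(b)) gb else NULL)
  })
}

#' Sum over the channel dimension (C x H x W -> 1 x H x W)
#' @param a `ag` node.
#' @export
ag_sum_channels <- function(a) {
  va <- ag_value(a); d <- dim(va)
  v <- array(colSums(matrix(va, nrow = d[1])), dim = c(1L, d[2], d[3]))
  ag_node(v, list(a), function(g) {
    list(array(rep(as.numeric(g), each = d[1]), dim = d))
  })
}

#' Gather along the third dimension with a fixed index map
#' @param a `ag` node, C x H x n.
#' @param idx Integer vector of length W with values in 1..n.
#' @export
ag_expand_w <- function(a, idx) {
  va <- ag_value(a); d <- dim(va)
  ag_node(va[, , idx, drop = FALSE], list(a), function(g) {
    gg <- array(0, dim = d)
    for (k in seq_len(d[3])) {
      sel <- which(idx == k)
      if (length(sel)) {
        gg[, , k] <- rowSums(matrix(g[, , sel, drop = FALSE], nrow = d[1] * d[2]))
      }
    }
    list(gg)
  })
}

#' Gather along the second dimension with a fixed index map
#' @param a `ag` node, C x n x W.
#' @param idx Integer vector of length H with values in 1..n.
#' @export
ag_expand_h <- function(a, idx) {
  va <- ag_value(a); d <- dim(va)
  ag_node(va[, idx, , drop = FALSE], list(a), function(g) {
    gg <- array(0, dim = d)
    for (k in seq_len(d[2])) {
      sel <- which(idx == k)
      if (length(sel)) {
        m <- matrix(aperm(g[, sel, , drop = FALSE], c(2, 1, 3)), nrow = length(sel))
        gg[, k, ] <- colSums(m)
      }
    }
    list(gg)
  })
}

#' Column-block average pooling (C x H x W -> C x H x W/k)
#' @param a `ag` node; W divisible by k.
#' @param k Block width.
#' @export
ag_avg_pool_w <- function(a, k) {
  va <- ag_value(a); d <- dim(va)
  stopifnot(d[3] %% k == 0)
  n <- d[3] %/% k
  v4 <- array(va, dim = c(d[1], d[2], k, n))
  m <- matrix(aperm(v4, c(3, 1, 2, 4)), nrow = k)
  v <- colMeans(m)
  ag_node(array(v, dim = c(d[1], d[2], n)), list(a), function(g) {
    g4 <- array(rep(as.numeric(g) / k, 1), dim = c(d[1], d[2], n))
    gg <- array(0, dim = c(d[1], d[2], k, n))
    for (j in seq_len(k)) gg[, , j, ] <- g4
    list(array(gg, dim = d))
  })
}

#' Row-block average pooling (C x H x W -> C x H/k x W)
#' @param a `ag` node; H divisible by k.
#' @param k Block height.
#' @export
ag_avg_pool_h <- function(a, k) {
  va <- ag_value(a); d <- dim(va)
  stopifnot(d[2] %% k == 0)
  n <- d[2] %/% k
  v4 <- array(va, dim = c(d[1], k, n, d[3]))
  m <- matrix(aperm(v4, c(2, 1, 3, 4)), nrow = k)
  v <- colMeans(m)
  ag_node(array(v, dim = c(d[1], n, d[3])), list(a), function(g) {
    g3 <- array(as.numeric(g) / k, dim = c(d[1], n, d[3]))
    gg <- array(0, dim = c(d[1], k, n, d[3]))
    for (j in seq_len(k)) gg[, j, , ] <- g3
    list(array(gg, dim = d))
  })
}

#' Bind matrices column-wise in the autograd graph
#' @param xs List of `ag` nodes / matrices with equal row counts.
#' @export
ag_cbind <- function(xs) {
  vals <- lapply(xs, ag_value)
  ncols <- vapply(vals, ncol, integer(1))
  out <- do.call(cbind, vals)
  ag_node(out, xs, function(g) {
    res <- vector("list", length(xs)); idx <- 0L
    for (i in seq_along(xs)) {
      res[[i]] <- g[, idx + seq_len(ncols[i]), drop = FALSE]
      idx <- idx + ncols[i]
    }
    res
  })
}

#' Select matrix columns in the autograd graph
#' @param a `ag` node, matrix.
#' @param idx Column indices.
#' @export
ag_cols <- function(a, idx) {
  va <- ag_value(a)
  ag_node(va[, idx, drop = FALSE], list(a), function(g) {
    gg <- matrix(0, nrow(va), ncol(va))
    gg[, idx] <- gg[, idx] + g
    list(gg)
  })
}

#' Repeat a vector as N identical matrix rows
#' @param a `ag` node, numeric vector.
#' @param n Number of rows.
#' @export
ag_rep_rows <- function(a, n) {
  va <- as.numeric(ag_value(a))
  ag_node(matrix(va, nrow = n, ncol = length(va), byrow = TRUE), list(a),
          function(g) list(same_shape(colSums(g), ag_value(a))))
}

#' Broadcast a vector spatially to a C x H x W map
#' @param a `ag` node, numeric vector (length C).
#' @param H,W Spatial size.
#' @export
ag_rep_spatial <- function(a, H, W) {
  va <- as.numeric(ag_value(a)); C <- length(va)
  ag_node(array(va, dim = c(C, H, W)), list(a), function(g) {
    list(same_shape(rowSums(matrix(g, nrow = C)), ag_value(a)))
  })
}

#' Column means of a matrix in the autograd graph
#' @param a `ag` node, matrix.
#' @export
ag_colmeans <- function(a) {
  va <- ag_value(a); n <- nrow(va)
  ag_node(colMeans(va), list(a), function(g) {
    list(matrix(as.numeric(g) / n, nrow = n, ncol = ncol(va), byrow = TRUE))
  })
}

#' Row sums of a matrix in the autograd graph
#' @param a `ag` node, matrix.
#' @export
ag_rowsums <- function(a) {
  va <- ag_value(a)
  ag_node(rowSums(va), list(a), function(g) {
    list(matrix(as.numeric(g), nrow = nrow(va), ncol = ncol(va)))
  })
}
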