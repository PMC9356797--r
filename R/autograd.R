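# Reverse-mode automatic differentiation over dense numeric arrays.
#
# Every tensor in the network is an `ag` node: an environment holding the
# forward value (an R numeric vector/matrix/array), the parent nodes it was
# computed from, and a closure that maps the incoming gradient to gradients
# for each parent. Calling ag_backward() on a scalar node topologically
# sorts the graph and accumulates gradients into every node created with
# requires_grad = TRUE. The graph is define-by-run: each forward pass builds
# a fresh graph, so control flow in model code is plain R control flow.

.ag_env <- new.env(parent = emptyenv())
.ag_env$counter <- 0L

#' Create an autograd tensor
#'
#' Wraps a numeric vector, matrix or array as a node of the automatic
#' differentiation graph used by the network blocks.
#'
#' @param value Numeric vector, matrix or array.
#' @param requires_grad Should gradients be accumulated into this node?
#' @return An object of class `ag`.
#' @export
ag <- function(value, requires_grad = FALSE) {
  if (!is.numeric(value)) stop("ag tensors hold numeric data", call. = FALSE)
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- list()
  e$backfn <- NULL
  e$requires <- isTRUE(requires_grad)
  .ag_env$counter <- .ag_env$counter + 1L
  e$id <- .ag_env$counter
  class(e) <- "ag"
  e
}

#' @export
print.ag <- function(x, ...) {
  d <- dim(x$value)
  cat("<ag tensor ", if (is.null(d)) length(x$value) else paste(d, collapse = "x"),
      if (x$requires) " grad" else "", ">\n", sep = "")
  invisible(x)
}

is_ag <- function(x) inherits(x, "ag")

#' Extract the forward value of an autograd tensor
#' @param x An `ag` node or plain numeric (returned as-is).
#' @return The underlying numeric array.
#' @export
ag_value <- function(x) if (is_ag(x)) x$value else x

# Internal node constructor. `backfn(g)` must return a list with one gradient
# (same shape as the parent's value, or NULL) per parent.
ag_node <- function(value, parents, backfn) {
  parents <- parents[vapply(parents, is_ag, logical(1))]
  req <- any(vapply(parents, function(p) p$requires, logical(1)))
  out <- ag(value)
  if (req) {
    out$parents <- parents
    out$backfn <- backfn
    out$requires <- TRUE
  }
  out
}

#' Backpropagate gradients from a scalar loss
#'
#' @param loss An `ag` node holding a length-1 value.
#' @export
ag_backward <- function(loss) {
  stopifnot(is_ag(loss), length(loss$value) == 1L)
  # Topological order by iterative depth-first search.
  order <- vector("list", 64L); n_ord <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = loss, stage = 0L)); n_st <- 1L
  while (n_st > 0L) {
    fr <- stack[[n_st]]
    nd <- fr$node
    key <- as.character(nd$id)
    if (fr$stage == 0L) {
      if (!is.null(seen[[key]])) { n_st <- n_st - 1L; next }
      seen[[key]] <- TRUE
      stack[[n_st]] <- list(node = nd, stage = 1L)
      for (p in nd$parents) {
        if (p$requires && is.null(seen[[as.character(p$id)]])) {
          n_st <- n_st + 1L
          stack[[n_st]] <- list(node = p, stage = 0L)
        }
      }
    } else {
      n_st <- n_st - 1L
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- nd
    }
  }
  grads <- new.env(parent = emptyenv())
  assign(as.character(loss$id), array(1, dim = c(1L)), envir = grads)
  for (k in seq(n_ord, 1L)) {
    nd <- order[[k]]
    g <- get0(as.character(nd$id), envir = grads)
    if (is.null(g)) next
    if (nd$requires && is.null(nd$backfn)) {
      # leaf with requires_grad
      nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
    }
    if (!is.null(nd$backfn)) {
      pg <- nd$backfn(g)
      for (i in seq_along(nd$parents)) {
        p <- nd$parents[[i]]
        if (!p$requires || is.null(pg[[i]])) next
        key <- as.character(p$id)
        old <- get0(key, envir = grads)
        assign(key, if (is.null(old)) pg[[i]] else old + pg[[i]], envir = grads)
      }
      rm(list = as.character(nd$id), envir = grads)
    }
  }
  invisible(loss)
}

#' Clear accumulated gradients on a list of parameters
#' @param params List of `ag` leaf nodes.
#' @export
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

same_shape <- function(g, ref) {
  dg <- dim(ref); if (is.null(dg)) g else array(g, dim = dg)
}

# ---- elementwise arithmetic ------------------------------------------------

#' Elementwise sum of two tensors (or tensor and scalar)
#' @param a,b `ag` nodes or numerics of identical shape (or scalar).
#' @return `ag` node.
#' @export
ag_add <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  ag_node(va + vb, list(a, b), function(g) {
    list(if (is_ag(a)) reduce_like(g, va) else NULL,
         if (is_ag(b)) reduce_like(g, vb) else NULL)
  })
}

# collapse gradient of a broadcast scalar back to length 1
reduce_like <- function(g, v) if (length(v) == 1L) sum(g) else same_shape(g, v)

#' Elementwise difference
#' @inheritParams ag_add
#' @export
ag_sub <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  ag_node(va - vb, list(a, b), function(g) {
    list(if (is_ag(a)) reduce_like(g, va) else NULL,
         if (is_ag(b)) reduce_like(-g, vb) else NULL)
  })
}

#' Elementwise product
#' @inheritParams ag_add
#' @export
ag_mul <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  ag_node(va * vb, list(a, b), function(g) {
    list(if (is_ag(a)) reduce_like(g * vb, va) else NULL,
         if (is_ag(b)) reduce_like(g * va, vb) else NULL)
  })
}

#' Elementwise quotient
#' @inheritParams ag_add
#' @export
ag_div <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  ag_node(va / vb, list(a, b), function(g) {
    list(if (is_ag(a)) reduce_like(g / vb, va) else NULL,
         if (is_ag(b)) reduce_like(-g * va / (vb * vb), vb) else NULL)
  })
}

#' Elementwise negation
#' @param a `ag` node.
#' @export
ag_neg <- function(a) ag_node(-ag_value(a), list(a), function(g) list(same_shape(-g, ag_value(a))))

#' Natural logarithm (elementwise)
#' @param a `ag` node with strictly positive values.
#' @export
ag_log <- function(a) {
  va <- ag_value(a)
  ag_node(log(va), list(a), function(g) list(same_shape(g / va, va)))
}

#' Square root (elementwise)
#' @param a `ag` node with nonnegative values.
#' @export
ag_sqrt <- function(a) {
  va <- ag_value(a); s <- sqrt(va)
  ag_node(s, list(a), function(g) list(same_shape(g / (2 * s), va)))
}

#' Raise to a fixed scalar power (elementwise)
#' @param a `ag` node (nonnegative values required for fractional `p`).
#' @param p Scalar exponent (not differentiated).
#' @export
ag_pow <- function(a, p) {
  va <- ag_value(a)
  ag_node(va^p, list(a), function(g) {
    d <- va^(p - 1)
    d[!is.finite(d)] <- 0   # subgradient 0 at the origin for p < 1
    list(same_shape(g * p * d, va))
  })
}

#' Absolute value (elementwise, subgradient 0 at 0)
#' @param a `ag` node.
#' @export
ag_abs <- function(a) {
  va <- ag_value(a)
  ag_node(abs(va), list(a), function(g) list(same_shape(g * sign(va), va)))
}

#' Clamp values to a range; gradient passes only inside the range
#' @param a `ag` node.
#' @param lo,hi Bounds.
#' @export
ag_clamp <- function(a, lo, hi) {
  va <- ag_value(a)
  v <- pmin(pmax(va, lo), hi)
  ag_node(same_shape(v, va), list(a), function(g) {
    list(same_shape(g * (va >= lo & va <= hi), va))
  })
}

#' Multiply by a fixed (non-differentiated) mask or constant array
#' @param a `ag` node.
#' @param m Numeric constant of the same shape (or scalar).
#' @export
ag_mul_const <- function(a, m) {
  va <- ag_value(a)
  ag_node(same_shape(va * m, va), list(a), function(g) list(same_shape(g * m, va)))
}

# ---- activations -----------------------------------------------------------

#' Rectified linear unit
#' @param a `ag` node.
#' @export
ag_relu <- function(a) {
  va <- ag_value(a)
  ag_node(same_shape(pmax(va, 0), va), list(a), function(g) list(same_shape(g * (va > 0), va)))
}

#' Logistic sigmoid
#' @param a `ag` node.
#' @export
ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-ag_value(a)))
  ag_node(same_shape(s, ag_value(a)), list(a), function(g) list(same_shape(g * s * (1 - s), ag_value(a))))
}

#' Softmax along the first dimension of a 3-D array (class channels)
#' @param a `ag` node, array C x H x W.
#' @export
ag_softmax_channels <- function(a) {
  va <- ag_value(a); d <- dim(va)
  m <- matrix(va, nrow = d[1])
  mx <- m[1, ]
  if (d[1] > 1) for (c in 2:d[1]) mx <- pmax(mx, m[c, ])
  ex <- exp(m - rep(mx, each = d[1]))
  s <- ex / rep(colSums(ex), each = d[1])
  ag_node(array(s, dim = d), list(a), function(g) {
    gm <- matrix(g, nrow = d[1])
    dot <- colSums(gm * s)
    list(array(s * (gm - rep(dot, each = d[1])), dim = d))
  })
}

#' Row-wise softmax of a matrix
#' @param a `ag` node, matrix.
#' @export
ag_softmax_rows <- function(a) {
  va <- ag_value(a)
  m <- apply(va, 1, max)
  ex <- exp(va - m)
  s <- ex / rowSums(ex)
  ag_node(s, list(a), function(g) {
    dot <- rowSums(g * s)
    list(s * (g - dot))
  })
}

# ---- reductions ------------------------------------------------------------

#' Sum all elements to a scalar
#' @param a `ag` node.
#' @export
ag_sum <- function(a) {
  va <- ag_value(a)
  ag_node(sum(va), list(a), function(g) list(same_shape(rep(as.numeric(g), length(va)), va)))
}

#' Mean of all elements
#' @param a `ag` node.
#' @export
ag_mean <- function(a) {
  va <- ag_value(a); n <- length(va)
  ag_node(mean(va), list(a), function(g) list(same_shape(rep(as.numeric(g) / n, n), va)))
}

# ---- linear algebra --------------------------------------------------------

#' Matrix product of two 2-D tensors
#' @param a,b `ag` nodes or matrices with conforming dimensions.
#' @export
ag_matmul <- function(a, b) {
  va <- ag_value(a); vb <- ag_value(b)
  ag_node(va %*% vb, list(a, b), function(g) {
    list(if (is_ag(a)) g %*% t(vb) else NULL,
         if (is_ag(b)) t(va) %*% g else NULL)
  })
}

#' Matrix transpose
#' @param a `ag` node, matrix.
#' @export
ag_t <- function(a) ag_node(t(ag_value(a)), list(a), function(g) list(t(g)))

#' Reshape without changing element order
#' @param a `ag` node.
#' @param dims New dimensions.
#' @export
ag_reshape <- function(a, dims) {
  va <- ag_value(a)
  stopifnot(prod(dims) == length(va))
  ag_node(array(va, dim = dims), list(a), function(g) list(same_shape(g, va)))
}

# ---- structural ops on C x H x W arrays ------------------------------------

#' Concatenate 3-D tensors along a dimension
#' @param xs List of `ag` nodes, arrays agreeing on the other two dims.
#' @param dim Dimension index (1, 2 or 3).
#' @export
ag_concat <- function(xs, dim = 1) {
  vals <- lapply(xs, ag_value)
  dims <- lapply(vals, dim)
  sizes <- vapply(dims, `[`, integer(1), dim)
  outdim <- dims[[1]]; outdim[dim] <- sum(sizes)
  out <- array(0, dim = outdim)
  idx <- 0L
  for (i in seq_along(vals)) {
    sl <- idx + seq_len(sizes[i]); idx <- idx + sizes[i]
    if (dim == 1) out[sl, , ] <- vals[[i]]
    else if (dim == 2) out[, sl, ] <- vals[[i]]
    else out[, , sl] <- vals[[i]]
  }
  ag_node(out, xs, function(g) {
    res <- vector("list", length(xs)); idx <- 0L
    for (i in seq_along(xs)) {
      sl <- idx + seq_len(sizes[i]); idx <- idx + sizes[i]
      gi <- if (dim == 1) g[sl, , , drop = FALSE]
            else if (dim == 2) g[, sl, , drop = FALSE]
            else g[, , sl, drop = FALSE]
      res[[i]] <- array(gi, dim = dims[[i]])
    }
    res
  })
}

#' Slice a 3-D tensor along one dimension
#' @param a `ag` node, 3-D array.
#' @param dim Dimension index.
#' @param idx Integer indices to keep.
#' @export
ag_slice <- function(a, dim, idx) {
  va <- ag_value(a); d <- dim(va)
  v <- if (dim == 1) va[idx, , , drop = FALSE]
       else if (dim == 2) va[, idx, , drop = FALSE]
       else va[, , idx, drop = FALSE]
  ag_node(v, list(a), function(g) {
    gg <- array(0, dim = d)
    if (dim == 1) gg[idx, , ] <- g else if (dim == 2) gg[, idx, ] <- g else gg[, , idx] <- g
    list(gg)
  })
}

#' Replicate-edge padding of a C x H x W tensor
#' @param a `ag` node.
#' @param pad_h,pad_w Rows/columns to append at the bottom/right edges.
#' @export
ag_pad_replicate <- function(a, pad_h, pad_w) {
  va <- ag_value(a); d <- dim(va)
  ridx <- c(seq_len(d[2]), rep(d[2], pad_h))
  cidx <- c(seq_len(d[3]), rep(d[3], pad_w))
  ag_node(va[, ridx, cidx, drop = FALSE], list(a), function(g) {
    gg <- g[, seq_len(d[2]), seq_len(d[3]), drop = FALSE]
    if (pad_h > 0) gg[, d[2], ] <- gg[, d[2], ] + apply(g[, d[2] + seq_len(pad_h), seq_len(d[3]), drop = FALSE], c(1, 3), sum)
    if (pad_w > 0) gg[, , d[3]] <- gg[, , d[3]] + apply(g[, seq_len(d[2]), d[3] + seq_len(pad_w), drop = FALSE], c(1, 2), sum)
    if (pad_h > 0 && pad_w > 0) gg[, d[2], d[3]] <- gg[, d[2], d[3]] + apply(g[, d[2] + seq_len(pad_h), d[3] + seq_len(pad_w), drop = FALSE], 1, sum)
    list(gg)
  })
}

#' Crop a C x H x W tensor to its top-left H x W window
#' @param a `ag` node.
#' @param H,W Target spatial size.
#' @export
ag_crop <- function(a, H, W) {
  va <- ag_value(a); d <- dim(va)
  ag_node(va[, seq_len(H), seq_len(W), drop = FALSE], list(a), function(g) {
    gg <- array(0, dim = d)
    gg[, seq_len(H), seq_len(W)] <- g
    list(gg)
  })
}
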