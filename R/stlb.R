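# Statistical texture learning block (STLB): the texture enhancement module
# (TEM, graph reasoning over 1-d QCO level statistics) followed by the
# pyramid texture feature extraction module (PTFEM, multi-scale 2-d QCO with
# a shared MLP and level-wise averaging), fused into a texture feature map
# aligned with the high-level features.

#' STLB configuration
#'
#' @param n_levels Quantization levels N shared by the operators.
#' @param scales Pyramid grid sizes; scale s partitions the map into s x s
#'   regions.
#' @param c1_lift Width of the learned lift of the counting map (the
#'   statistical feature has c1_lift + C columns).
#' @param c2 TEM output channels.
#' @param c_prime PTFEM texture descriptor width per scale.
#' @param d_attn Width of the graph-reasoning query/key projections.
#' @param out_channels Channels of the fused texture feature map.
#' @param centered_levels Use full-coverage levels (n - 0.5)/N.
#' @export
stlb_config <- function(n_levels = 128, scales = c(1, 2, 4), c1_lift = 32,
                        c2 = NULL, c_prime = 64, d_attn = 16,
                        out_channels = 64, centered_levels = FALSE) {
  structure(list(n_levels = as.integer(n_levels), scales = as.integer(scales),
                 c1_lift = as.integer(c1_lift), c2 = c2,
                 c_prime = as.integer(c_prime), d_attn = as.integer(d_attn),
                 out_channels = as.integer(out_channels),
                 centered_levels = isTRUE(centered_levels)),
            class = "stlb_config")
}

make_tem_params <- function(store, prefix, C, cfg) {
  c1 <- cfg$c1_lift + C
  c2 <- cfg$c2 %||% C
  list(
    up = make_linear_params(store, paste0(prefix, ".up"), cfg$c1_lift, 2),
    q = make_linear_params(store, paste0(prefix, ".q"), cfg$d_attn, c1, bias = FALSE),
    k = make_linear_params(store, paste0(prefix, ".k"), cfg$d_attn, c1, bias = FALSE),
    v = make_linear_params(store, paste0(prefix, ".v"), c2, c1, bias = FALSE),
    c2 = c2
  )
}

make_ptfem_params <- function(store, prefix, C, cfg) {
  c1 <- cfg$c1_lift + C
  list(
    up = make_linear_params(store, paste0(prefix, ".up"), cfg$c1_lift, 3),
    mlp = make_linear_params(store, paste0(prefix, ".mlp"), cfg$c_prime, c1)
  )
}

make_stlb_params <- function(store, prefix, C, cfg) {
  c2 <- cfg$c2 %||% C
  tem <- make_tem_params(store, paste0(prefix, ".tem"), C, cfg)
  ptfem <- make_ptfem_params(store, paste0(prefix, ".ptfem"), c2, cfg)
  proj <- make_conv_params(store, paste0(prefix, ".proj"), cfg$out_channels,
                           c2 + cfg$c_prime * length(cfg$scales), 1, 1)
  list(tem = tem, ptfem = ptfem, proj = proj)
}

#' Texture enhancement module forward pass
#'
#' Runs the 1-d QCO, builds a graph adjacency over the level statistics
#' (row-softmax of projected query/key products), reconstructs the levels
#' through it, and decodes back to a spatial map through the encoding.
#'
#' @param x Array or `ag` node, C x H x W.
#' @param params TEM parameter list.
#' @param n_levels Quantization levels N.
#' @param centered_levels Use full-coverage levels.
#' @return `ag` node, C2 x H x W.
#' @export
tem_forward <- function(x, params, n_levels, centered_levels = FALSE) {
  x <- if (is_ag(x)) x else ag(x)
  d <- dim(ag_value(x))
  q <- qco_1d(x, n_levels, params = params, centered_levels = centered_levels)
  Pt <- ag_t(q$P)                                     # C1 x N
  qm <- ag_matmul(params$q$w, Pt)                     # D x N
  km <- ag_matmul(params$k$w, Pt)
  G <- ag_softmax_rows(ag_matmul(ag_t(qm), km))       # N x N, rows sum to 1
  vm <- ag_matmul(params$v$w, Pt)                     # C2 x N
  Lp <- ag_matmul(vm, G)                              # reconstructed levels
  out <- ag_matmul(Lp, q$encoding)                    # C2 x HW
  check_finite(out, "stlb.tem")
  ag_reshape(out, c(params$c2, d[2], d[3]))
}

#' Pyramid texture feature extraction forward pass
#'
#' For each pyramid scale s the map is partitioned into s x s regions
#' (replicate-padded to divisibility first); each region goes through the
#' 2-d QCO, a shared single-layer MLP lifts the statistical feature to
#' c_prime channels, and a level-wise average produces one descriptor per
#' region; descriptors are averaged over regions and concatenated across
#' scales.
#'
#' @param x Array or `ag` node, C x H x W.
#' @param params PTFEM parameter list.
#' @param n_levels Quantization levels N.
#' @param scales Integer vector of pyramid grid sizes.
#' @param centered_levels Use full-coverage levels.
#' @return `ag` node, vector of length c_prime * length(scales).
#' @export
ptfem_forward <- function(x, params, n_levels, scales = c(1, 2, 4),
                          centered_levels = FALSE) {
  x <- if (is_ag(x)) x else ag(x)
  d <- dim(ag_value(x))
  per_scale <- vector("list", length(scales))
  for (si in seq_along(scales)) {
    s <- scales[si]
    if (d[2] %/% s < 1 || d[3] %/% s < 2) {
      stop("pyramid scale ", s, " too large for a ", d[2], "x", d[3], " map",
           call. = FALSE)
    }
    ph <- (s - d[2] %% s) %% s; pw <- (s - d[3] %% s) %% s
    xs <- if (ph > 0 || pw > 0) ag_pad_replicate(x, ph, pw) else x
    ds <- dim(ag_value(xs))
    rh <- ds[2] %/% s; rw <- ds[3] %/% s
    acc <- NULL
    for (i in seq_len(s)) {
      for (j in seq_len(s)) {
        xr <- ag_slice(ag_slice(xs, 2, (i - 1) * rh + seq_len(rh)),
                       3, (j - 1) * rw + seq_len(rw))
        q2 <- qco_2d(xr, n_levels, params = params, centered_levels = centered_levels)
        pp <- ag_matmul(q2$P, ag_t(params$mlp$w))
        if (!is.null(params$mlp$b)) pp <- ag_add(pp, ag_rep_rows(params$mlp$b, n_levels^2))
        tr <- ag_colmeans(pp)                   # level-wise average, length c_prime
        acc <- if (is.null(acc)) tr else ag_add(acc, tr)
      }
    }
    per_scale[[si]] <- ag_mul_const(acc, 1 / (s * s))
  }
  out <- ag_reshape(ag_cbind(lapply(per_scale, function(v)
    ag_reshape(v, c(length(ag_value(v)), 1)))),
    sum(vapply(per_scale, function(v) length(ag_value(v)), integer(1))))
  check_finite(out, "stlb.ptfem")
  out
}

#' STLB forward pass
#'
#' TEM output feeds PTFEM; the pyramid descriptor is broadcast spatially,
#' concatenated with the TEM map, projected by a 1x1 conv and bilinearly
#' resized to the requested spatial size.
#'
#' @param low Array or `ag` node of low-level features, C x H x W.
#' @param params STLB parameter list from a built model.
#' @param cfg [stlb_config()].
#' @param out_size Target spatial size c(H2, W2) for alignment with the
#'   high-level features.
#' @return `ag` node, out_channels x H2 x W2.
#' @export
stlb_forward <- function(low, params, cfg, out_size) {
  low <- if (is_ag(low)) low else ag(low)
  d <- dim(ag_value(low))
  o <- tem_forward(low, params$tem, cfg$n_levels, cfg$centered_levels)
  tvec <- ptfem_forward(o, params$ptfem, cfg$n_levels, cfg$scales, cfg$centered_levels)
  tmap <- ag_rep_spatial(tvec, d[2], d[3])
  fused <- ag_relu(ag_conv2d(ag_concat(list(o, tmap), dim = 1),
                             params$proj$w, params$proj$b))
  out <- ag_resize_bilinear(fused, out_size[1], out_size[2])
  check_finite(out, "stlb.output")
  out
}
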