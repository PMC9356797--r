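# Grid contextual attention: pad/crop and split/merge contracts, the
# bypass identity, hand-evaluated global attention with identity weights,
# and equivalence with the per-patch loop oracle.

test_that("pad_to_grid reaches the next multiple and crop inverts it exactly", {
  x <- rand_map(2, 15, 14, seed = 1)
  pg <- pad_to_grid(x, 4, 4)
  expect_equal(dim(pg$map)[2:3], c(16, 16))
  expect_equal(unname(pg$pad), c(1, 2))
  expect_identical(crop_from_grid(pg$map, pg$pad), x)
  # already aligned: no padding
  x16 <- rand_map(1, 16, 16, seed = 2)
  expect_equal(unname(pad_to_grid(x16, 4, 4)$pad), c(0, 0))
})

test_that("split_patches indexes row/column blocks and merge inverts it", {
  # 1 x 4 x 4 map holding 0..15 in row-major reading order
  x <- array(0, dim = c(1, 4, 4))
  for (i in 1:4) for (j in 1:4) x[1, i, j] <- (i - 1) * 4 + (j - 1)
  p <- split_patches(x, 2, 2)
  expect_equal(p[1, , , 1, 2], matrix(c(2, 3, 6, 7), 2, 2, byrow = TRUE))
  expect_identical(merge_patches(p), x)
  # degenerate grid: one patch equal to the input
  p1 <- split_patches(x, 4, 4)
  expect_equal(array(p1[, , , 1, 1], dim = dim(x)), x)
  expect_error(split_patches(x, 3, 2), "divisible")
})

test_that("bypass attention reduces the block to the identity (or doubling)", {
  x <- rand_map(3, 10, 9, seed = 3)
  params <- block_params(gcaseg:::make_gca_params, 3, 2)
  out <- gca_forward(x, gca_config(4, 4, 2, residual = FALSE), params,
                     bypass_attention = TRUE)
  expect_equal(ag_value(out), x)
  out2 <- gca_forward(x, gca_config(4, 4, 2, residual = TRUE), params,
                      bypass_attention = TRUE)
  expect_equal(ag_value(out2), 2 * x)
})

test_that("global attention applies the excitation transform to pooled profiles", {
  params <- block_params(gcaseg:::make_gca_params, 1, 1)
  # freeze both excitation convs to the 1x1 identity
  params$ex1$w$value <- array(1, dim = c(1, 1, 1, 1)); params$ex1$b$value <- 0
  params$ex2$w$value <- array(1, dim = c(1, 1, 1, 1)); params$ex2$b$value <- 0
  x <- array(c(1, 5, 3, 7), dim = c(1, 2, 2))   # rows (1,3), (5,7)
  att <- gca_global_attention(x, params)
  sig <- function(z) 1 / (1 + exp(-z))
  expect_equal(as.numeric(ag_value(att$height_attn)), sig(c(2, 6)), tolerance = 1e-12)
  expect_equal(as.numeric(ag_value(att$width_attn)), sig(c(3, 5)), tolerance = 1e-12)
  expect_equal(dim(ag_value(att$height_attn)), c(1, 2, 1))
  expect_equal(dim(ag_value(att$width_attn)), c(1, 1, 2))
})

test_that("shapes and constant-map symmetry of global attention hold", {
  x <- array(rep(seq_len(8), each = 1), dim = c(8, 1, 1))[, 1, 1]
  xc <- array(rep(x, times = 16 * 12), dim = c(8, 16, 12))
  params <- block_params(gcaseg:::make_gca_params, 8, 4)
  att <- gca_global_attention(xc, params)
  h <- ag_value(att$height_attn); w <- ag_value(att$width_attn)
  expect_equal(dim(h), c(8, 16, 1))
  expect_equal(dim(w), c(8, 1, 12))
  # constant per channel: profiles constant along their direction
  expect_lt(max(apply(h[, , 1], 1, stats::sd)), 1e-12)
  expect_lt(max(apply(w[, 1, ], 1, stats::sd)), 1e-12)
})

test_that("vectorized forward equals the per-patch loop oracle", {
  cfgs <- list(gca_config(4, 4, 2, residual = FALSE),
               gca_config(4, 4, 2, residual = TRUE),
               gca_config(2, 4, 1, residual = FALSE))
  for (ci in seq_along(cfgs)) {
    for (seed in 1:2) {
      x <- rand_map(2, 8, 8, seed = 30 + seed)
      params <- block_params(gcaseg:::make_gca_params, 2, cfgs[[ci]]$reduction,
                             seed = 40 + ci)
      got <- ag_value(gca_forward(x, cfgs[[ci]], params))
      want <- gca_oracle(x, cfgs[[ci]], params)
      expect_lt(max(abs(got - want)), 1e-6)
    }
  }
})

test_that("attention keeps the pre-residual output bounded by the input", {
  x <- rand_map(3, 12, 12, seed = 50)
  params <- block_params(gcaseg:::make_gca_params, 3, 2)
  out <- ag_value(gca_forward(x, gca_config(4, 4, 2, residual = FALSE), params))
  expect_true(all(abs(out) <= abs(x) + 1e-12))
})

test_that("output shape equals input shape for non-divisible sizes", {
  x <- rand_map(2, 13, 11, seed = 60)
  params <- block_params(gcaseg:::make_gca_params, 2, 2)
  out <- gca_forward(x, gca_config(8, 8, 2), params)
  expect_equal(dim(ag_value(out)), dim(x))
})

test_that("single-patch grid reduces local pooling to the global profile", {
  # with P_h = H, P_w = W the patch-pooled statistics equal the global ones
  x <- rand_map(2, 6, 6, seed = 70)
  lh <- ag_value(ag_avg_pool_w(ag(x), 6))   # C x H x 1
  gh <- apply(x, c(1, 2), mean)
  expect_equal(lh[, , 1], gh, tolerance = 1e-12)
  lw <- ag_value(ag_avg_pool_h(ag(x), 6))
  gw <- apply(x, c(1, 3), mean)
  expect_equal(lw[, 1, ], gw, tolerance = 1e-12)
})

test_that("channel permutation of input and weights permutes the output", {
  x <- rand_map(3, 8, 8, seed = 80)
  params <- block_params(gcaseg:::make_gca_params, 3, 1, seed = 81)
  cfg <- gca_config(4, 4, 1, residual = TRUE)
  out <- ag_value(gca_forward(x, cfg, params))
  perm <- c(3, 1, 2)
  pp <- block_params(gcaseg:::make_gca_params, 3, 1, seed = 81)
  permute_conv <- function(cv, pin = NULL, pout = NULL) {
    w <- ag_value(cv$w)
    if (!is.null(pout)) { w <- w[pout, , , , drop = FALSE]; cv$b$value <- ag_value(cv$b)[pout] }
    if (!is.null(pin)) w <- w[, pin, , , drop = FALSE]
    cv$w$value <- w
    cv
  }
  pp$ex1 <- permute_conv(pp$ex1, pin = perm)
  pp$ex2 <- permute_conv(pp$ex2, pout = perm)
  pp$comp <- permute_conv(pp$comp, pin = perm)
  pp$exp_h <- permute_conv(pp$exp_h, pout = perm)
  pp$exp_w <- permute_conv(pp$exp_w, pout = perm)
  out_p <- ag_value(gca_forward(x[perm, , , drop = FALSE], cfg, pp))
  expect_equal(out_p, out[perm, , , drop = FALSE], tolerance = 1e-10)
})
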