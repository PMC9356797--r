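# Spatial transformer head: identity initialization, warp exactness against
# the bilinear-kernel loop oracle, linearity, translation composition, and
# the out-of-bounds zero-padding contract.

stb_test_params <- function(C = 3, seed = 1) {
  block_params(gcaseg:::make_stb_params, C, stb_config(widths = c(8, 8, 8), fc = 8),
               seed = seed)
}

test_that("freshly initialized localization returns the identity for any input", {
  params <- stb_test_params()
  for (seed in 1:3) {
    x <- rand_map(3, 16, 16, seed = seed)
    th <- ag_value(stb_localize(x, params))
    expect_identical(dim(th), c(2L, 3L))
    expect_identical(th, matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE))
  }
})

test_that("perturbing the last bias entry shifts a23 by exactly that amount", {
  params <- stb_test_params()
  x <- rand_map(3, 16, 16, seed = 4)
  delta <- 0.37
  params$fc2$b$value[6] <- params$fc2$b$value[6] + delta
  th <- ag_value(stb_localize(x, params))
  expect_equal(th[2, 3], delta)
  expect_equal(th[1, 1], 1)
})

test_that("initial prediction is a per-pixel softmax with hand-checked logits", {
  params <- stb_test_params()
  x <- rand_map(3, 8, 8, seed = 5)
  pred <- ag_value(stb_initial_prediction(x, params))
  expect_equal(dim(pred), c(2, 8, 8))
  expect_lt(max(abs(apply(pred, c(2, 3), sum) - 1)), 1e-12)
  # zero conv: equal logits, 0.5 everywhere
  params$pred$w$value <- params$pred$w$value * 0
  params$pred$b$value <- params$pred$b$value * 0
  p0 <- ag_value(stb_initial_prediction(x, params))
  expect_true(all(p0 == 0.5))
  # logits (2, 0) at a pixel
  params$pred$b$value <- c(2, 0)
  p2 <- ag_value(stb_initial_prediction(x * 0, params))
  expect_equal(p2[, 1, 1], c(exp(2), 1) / (exp(2) + 1), tolerance = 1e-12)
})

test_that("identity warp is bit-exact and stb_forward reduces to the initial map", {
  params <- stb_test_params()
  x <- rand_map(3, 12, 12, seed = 6)
  id <- matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE)
  p <- rand_map(2, 7, 9, seed = 7)
  expect_identical(ag_value(ag_warp_affine(p, ag(id))), p)
  out <- stb_forward(x, params)
  expect_identical(ag_value(out$prediction), ag_value(out$initial))
})

test_that("warp matches the bilinear-kernel loop oracle on small maps", {
  thetas <- list(
    matrix(c(1, 0, -2 / 3, 0, 1, 0), 2, 3, byrow = TRUE),      # 1-px x shift
    matrix(c(1, 0, 0, 0, 1, 2 / 3), 2, 3, byrow = TRUE),       # 1-px y shift
    matrix(c(0.8, 0.1, 0.05, -0.2, 1.1, -0.3), 2, 3, byrow = TRUE),
    matrix(c(2, 0, 0, 0, 2, 0), 2, 3, byrow = TRUE))           # zoom out
  for (th in thetas) {
    p <- rand_map(2, 3, 3, seed = 8)
    got <- ag_value(ag_warp_affine(p, ag(th)))
    expect_lt(max(abs(got - warp_oracle(p, th))), 1e-6)
  }
})

test_that("integer-pixel translation moves a one-hot pixel by one cell", {
  p <- array(0, dim = c(1, 3, 3)); p[1, 2, 2] <- 1
  th <- matrix(c(1, 0, -2 / 3, 0, 1, 0), 2, 3, byrow = TRUE)
  got <- ag_value(ag_warp_affine(p, ag(th)))[1, , ]
  want <- warp_oracle(p, th)[1, , ]
  expect_lt(max(abs(got - want)), 1e-6)
  expect_equal(got[2, 3], 1, tolerance = 1e-6)
  expect_lt(sum(got) - 1, 1e-6)
})

test_that("warp is linear in the prediction map", {
  th <- matrix(c(0.9, 0.2, 0.1, -0.1, 1.05, -0.2), 2, 3, byrow = TRUE)
  p <- rand_map(2, 5, 5, seed = 9); q <- rand_map(2, 5, 5, seed = 10)
  a <- 0.3; b <- -1.7
  lhs <- ag_value(ag_warp_affine(a * p + b * q, ag(th)))
  rhs <- a * ag_value(ag_warp_affine(p, ag(th))) + b * ag_value(ag_warp_affine(q, ag(th)))
  expect_lt(max(abs(lhs - rhs)), 1e-10)
})

test_that("composing two integer-pixel translations equals the summed translation", {
  H <- 8
  t1 <- matrix(c(1, 0, 2 / H, 0, 1, 0), 2, 3, byrow = TRUE)
  t2 <- matrix(c(1, 0, 4 / H, 0, 1, 2 / H), 2, 3, byrow = TRUE)
  t12 <- matrix(c(1, 0, 6 / H, 0, 1, 2 / H), 2, 3, byrow = TRUE)
  p <- array(0, dim = c(1, H, H)); p[1, 4, 6] <- 1; p[1, 5, 5] <- 0.5
  step <- ag_value(ag_warp_affine(ag_value(ag_warp_affine(p, ag(t1))), ag(t2)))
  once <- ag_value(ag_warp_affine(p, ag(t12)))
  expect_lt(max(abs(step - once)), 1e-6)
})

test_that("zoom-out warps pad out-of-bounds samples with zeros", {
  p <- array(1, dim = c(1, 6, 6))
  th <- matrix(c(2, 0, 0, 0, 2, 0), 2, 3, byrow = TRUE)
  got <- ag_value(ag_warp_affine(p, ag(th)))[1, , ]
  expect_equal(got[1, 1], 0)       # corner samples fall outside
  expect_equal(got[4, 4], 1)       # center remains covered
})

test_that("warped channel sums stay within [0, 1] for a softmax input", {
  params <- stb_test_params()
  x <- rand_map(3, 16, 16, seed = 11)
  pred <- stb_initial_prediction(x, params)
  th <- matrix(c(1.2, 0.1, 0.3, 0, 0.9, -0.2), 2, 3, byrow = TRUE)
  w <- ag_value(ag_warp_affine(pred, ag(th)))
  sums <- apply(w, c(2, 3), sum)
  expect_true(all(sums >= -1e-9 & sums <= 1 + 1e-9))
})
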