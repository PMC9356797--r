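# Compound loss: closed-form focal values, the cross-entropy limit,
# boundary extraction topology, and the composition rule.

test_that("focal loss reproduces hand-computed values", {
  # y_gt = 1, p = 0.5, alpha = 0.5, gamma = 0: 0.5 ln 2
  l0 <- ag_value(focal_seg(matrix(0.5), matrix(1), 0.5, 0))
  expect_equal(l0, 0.5 * log(2), tolerance = 1e-9)
  # gamma = 1.25 adds the modulation 0.5^1.25
  l1 <- ag_value(focal_seg(matrix(0.5), matrix(1), 0.5, 1.25))
  expect_equal(l1, 0.5 * 0.5^1.25 * log(2), tolerance = 1e-9)
  expect_equal(l1, 0.1458, tolerance = 1e-3)
  # perfect prediction: loss vanishes up to the clamp
  lp <- ag_value(focal_seg(matrix(c(1, 0)), matrix(c(1, 0)), 0.5, 1.25))
  expect_lt(lp, 1e-5)
  expect_error(focal_seg(matrix(0.5, 2, 2), matrix(1, 3, 3), 0.5, 0), "shapes")
})

test_that("gamma = 0, alpha = 0.5 recovers half the binary cross-entropy", {
  for (seed in 1:5) {
    p <- withr::with_seed(seed, matrix(stats::runif(100, 0.01, 0.99), 10, 10))
    y <- rand_mask(10, 10, seed = seed + 50)
    fl <- ag_value(focal_seg(p, y, 0.5, 0))
    bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
    expect_equal(fl, 0.5 * bce, tolerance = 1e-9)
  }
})

test_that("focal loss decreases monotonically in p for a positive target", {
  ps <- seq(0.05, 0.95, by = 0.05)
  ls <- vapply(ps, function(p) ag_value(focal_seg(matrix(p), matrix(1), 0.5, 1.25)),
               numeric(1))
  expect_true(all(diff(ls) < 0))
})

test_that("boundary focal loss matches the per-pixel hand case and symmetry", {
  # one boundary pixel predicted at 0.5, the rest perfect, alpha = 0.5, gamma = 0
  b_gt <- matrix(0, 5, 5); b_gt[3, 3] <- 1
  b_pred <- b_gt; b_pred[3, 3] <- 0.5
  l <- ag_value(focal_boundary(b_pred, b_gt, 0.5, 0))
  # the probability clamp at 1 - 1e-7 adds ~1e-8 per perfect pixel
  expect_equal(l, 0.5 * log(2) / 25, tolerance = 1e-5)
  # swapping (b_gt, alpha) with (1 - b_gt, 1 - alpha) and p with 1 - p is a symmetry
  a <- 0.3
  p <- withr::with_seed(3, matrix(stats::runif(25, 0.05, 0.95), 5, 5))
  l1 <- ag_value(focal_boundary(p, b_gt, a, 1.25))
  l2 <- ag_value(focal_boundary(1 - p, 1 - b_gt, 1 - a, 1.25))
  expect_equal(l1, l2, tolerance = 1e-9)
})

test_that("auto alpha is the clamped background ratio", {
  m10 <- matrix(0, 10, 10); m10[1, 1:10] <- 1          # 10% tumor
  expect_equal(auto_alpha(m10), 0.9)
  expect_equal(auto_alpha(matrix(0, 4, 4)), 0.95)      # clamped
  m50 <- matrix(rep(c(0, 1), 8), 4, 4)
  expect_equal(auto_alpha(m50), 0.5)
  expect_error(auto_alpha(list()), "empty")
})

test_that("Canny boundary of a filled square is a thin closed ring", {
  m <- matrix(0, 24, 24); m[7:18, 7:18] <- 1
  b <- extract_boundary(m)
  expect_true(all(b %in% c(0, 1)))
  # interior stays empty, some boundary pixels exist near the contour
  expect_equal(sum(b[10:15, 10:15]), 0)
  expect_gt(sum(b), 20)
  # edge pixels hug the square's contour (within 2 px)
  on <- which(b > 0, arr.ind = TRUE)
  d_contour <- pmin(abs(on[, 1] - 7), abs(on[, 1] - 18),
                    abs(on[, 2] - 7), abs(on[, 2] - 18))
  expect_true(all(d_contour <= 2))
  # the background enclosed by the ring is disconnected from the frame:
  # ring forms a closed curve
  inv <- 1 - b
  lab <- label_components(inv)
  expect_gt(max(lab), 1)
  # degenerate inputs
  expect_equal(sum(extract_boundary(matrix(0, 16, 16))), 0)
  expect_equal(sum(extract_boundary(matrix(0.7, 16, 16))), 0)
  # sharpening idempotence
  cfg <- loss_config()
  b2 <- extract_boundary(b, cfg)
  expect_identical((b2 >= 0.5) * 1, b2)
})

test_that("compound loss composes the two terms with weight beta", {
  p <- withr::with_seed(5, matrix(stats::runif(16^2, 0.05, 0.95), 16, 16))
  y <- matrix(0, 16, 16); y[5:12, 5:12] <- 1
  cfg0 <- loss_config(beta = 0)
  cl0 <- compound_loss(p, y, cfg0)
  expect_equal(ag_value(cl0$loss), cl0$seg, tolerance = 1e-12)
  cfg <- loss_config(beta = 0.2)
  cl <- compound_loss(p, y, cfg)
  expect_equal(ag_value(cl$loss), cl$seg + 0.2 * cl$boundary, tolerance = 1e-12)
  expect_gte(ag_value(cl$loss), cl$seg)
  # differentiable end to end in y_pred
  pp <- ag(array(p, dim = c(1, 16, 16)), requires_grad = TRUE)
  cl2 <- compound_loss(pp, y, cfg)
  ag_backward(cl2$loss)
  expect_true(all(is.finite(pp$grad)))
  expect_gt(max(abs(pp$grad)), 0)
})

test_that("component arithmetic: seg 0.30 and boundary 0.10 give 0.32 at beta 0.2", {
  expect_equal(0.30 + 0.2 * 0.10, 0.32)
  # realized through the returned components record
  p <- matrix(0.5, 8, 8); y <- matrix(0, 8, 8); y[3:6, 3:6] <- 1
  cl <- compound_loss(p, y, loss_config(beta = 0.2))
  expect_equal(ag_value(cl$loss), cl$seg + 0.2 * cl$boundary, tolerance = 1e-12)
})
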