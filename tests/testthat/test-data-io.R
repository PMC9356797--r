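# I/O, splitting and augmentation: round trips, normalization rules, the
# deterministic 80/20 partition, and the augmentation contracts.

write_png8 <- function(m, path) png::writePNG(m / 255, path)

test_that("loading normalizes intensities min-max and binarizes the mask", {
  td <- withr::local_tempdir()
  img <- matrix(c(0, 128, 255, 0), 2, 2)
  msk <- matrix(c(0, 255, 255, 0), 2, 2)
  write_png8(img, file.path(td, "i.png"))
  write_png8(msk, file.path(td, "m.png"))
  s <- load_sample(file.path(td, "i.png"), file.path(td, "m.png"))
  expect_equal(sort(unique(as.numeric(s$image))), c(0, 128 / 255, 1))
  expect_equal(sort(unique(as.numeric(s$mask))), c(0, 1))
  # all-zero image and mask: degenerate but defined
  write_png8(matrix(0, 2, 2), file.path(td, "z.png"))
  z <- load_sample(file.path(td, "z.png"), file.path(td, "z.png"))
  expect_true(all(z$image == 0) && all(z$mask == 0))
  # shape mismatch is a hard error
  write_png8(matrix(0, 3, 2), file.path(td, "w.png"))
  expect_error(load_sample(file.path(td, "i.png"), file.path(td, "w.png")), "differ")
})

test_that("multi-channel images are averaged with a warning", {
  td <- withr::local_tempdir()
  rgb <- array(withr::with_seed(1, stats::runif(2 * 2 * 3)), dim = c(2, 2, 3))
  png::writePNG(rgb, file.path(td, "rgb.png"))
  write_png8(matrix(c(0, 255, 0, 255), 2, 2), file.path(td, "m.png"))
  expect_warning(s <- load_sample(file.path(td, "rgb.png"), file.path(td, "m.png")),
                 "averaged")
  expect_equal(dim(s$image), c(2, 2))
})

test_that("save-load round trip keeps the mask exact and the image to 8 bits", {
  td <- withr::local_tempdir()
  smp <- generate_sample(synth_spec(size = 48, mode = "easy", seed = 3))
  save_sample(smp, file.path(td, "i.png"), file.path(td, "m.png"))
  back <- load_sample(file.path(td, "i.png"), file.path(td, "m.png"))
  expect_identical(back$mask, smp$mask)
  # min-max renormalization on load can rescale; compare after normalizing both
  a <- smp$image; a <- (a - min(a)) / (max(a) - min(a))
  expect_lt(max(abs(back$image - a)), 1.5 / 255)
})

test_that("TIFF and NIfTI inputs load through the same path", {
  td <- withr::local_tempdir()
  img <- withr::with_seed(4, matrix(stats::runif(64), 8, 8))
  tiff::writeTIFF(img, file.path(td, "i.tif"))
  msk <- matrix(0, 8, 8); msk[3:6, 3:6] <- 1
  png::writePNG(msk, file.path(td, "m.png"))
  s <- load_sample(file.path(td, "i.tif"), file.path(td, "m.png"))
  expect_equal(dim(s$image), c(8, 8))
  expect_equal(range(s$image), c(0, 1))
  RNifti::writeNifti(img, file.path(td, "i.nii.gz"))
  s2 <- load_sample(file.path(td, "i.nii.gz"), file.path(td, "m.png"))
  expect_equal(dim(s2$image), c(8, 8))
})

test_that("split_dataset partitions deterministically at the stated ratio", {
  ids <- sprintf("s%03d", 1:10)
  sp <- split_dataset(ids, 0.8, seed = 7)
  expect_length(sp$train, 8); expect_length(sp$test, 2)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp, split_dataset(ids, 0.8, seed = 7))
  expect_false(identical(sp$train, split_dataset(ids, 0.8, seed = 8)$train))
  # the 204-case split lands at 164/40
  sp204 <- split_dataset(sprintf("c%03d", 1:204), 0.8, seed = 1)
  expect_length(sp204$train, 164); expect_length(sp204$test, 40)
  expect_error(split_dataset(character(0)), "empty")
  # partition property across seeds and sizes
  for (seed in 1:5) {
    n <- 2 + seed * 3
    ids2 <- seq_len(n)
    s2 <- split_dataset(ids2, 0.8, seed = seed)
    expect_setequal(c(s2$train, s2$test), ids2)
    expect_length(intersect(s2$train, s2$test), 0)
  }
})

test_that("geometric augmentations act on image and mask alike", {
  smp <- generate_sample(synth_spec(size = 48, mode = "easy", seed = 9))
  r0 <- augment_sample(smp, "rotate", 0)
  expect_identical(r0$image, smp$image)
  expect_identical(r0$mask, smp$mask)
  # left-right flip is an involution
  f1 <- augment_sample(smp, "flip", "leftright")
  f2 <- augment_sample(f1, "flip", "leftright")
  expect_identical(f2$image, smp$image)
  expect_identical(f2$mask, smp$mask)
  # rotations keep the pair aligned: metrics unchanged under joint transform
  r90 <- augment_sample(smp, "rotate", 90)
  expect_identical(seg_evaluate(r90$mask, r90$mask)$dsc, 1)
  expect_equal(sum(r90$mask), sum(smp$mask))
  expect_error(augment_sample(smp, "rotate", 45), "angle")
  expect_error(augment_sample(smp, "warp"), "unknown")
})

test_that("intensity augmentations never touch the mask and clip the image", {
  smp <- generate_sample(synth_spec(size = 48, mode = "easy", seed = 10))
  for (op in list(list("gaussian_blur", 2), list("gaussian_noise", 0.01),
                  list("salt_pepper", 0.05))) {
    a <- augment_sample(smp, op[[1]], op[[2]], seed = 11)
    expect_identical(a$mask, smp$mask)
    expect_true(all(a$image >= 0 & a$image <= 1))
  }
  expect_error(augment_sample(smp, "gaussian_noise", -0.1), "nonnegative")
})

test_that("salt and pepper corrupts exactly the floor of proportion * pixels", {
  img <- matrix(0.5, 10, 10)
  smp <- list(image = img, mask = img * 0, id = "x", meta = list())
  a <- augment_sample(smp, "salt_pepper", 0.1, seed = 12)
  changed <- sum(a$image != 0.5)
  expect_equal(changed, floor(0.1 * 100))
  expect_true(all(a$image[a$image != 0.5] %in% c(0, 1)))
  # determinism for a fixed seed
  b <- augment_sample(smp, "salt_pepper", 0.1, seed = 12)
  expect_identical(a$image, b$image)
})

test_that("metrics commute with joint geometric augmentation of both masks", {
  pred <- rand_mask(16, 16, seed = 13); gt <- rand_mask(16, 16, seed = 14)
  base <- seg_evaluate(pred, gt)
  wrap <- function(m) list(image = m, mask = m, id = "t", meta = list())
  for (spec in list(c("rotate", 90), c("rotate", 180), c("flip", "updown"))) {
    ap <- augment_sample(wrap(pred), spec[1], spec[2])$mask
    ag_ <- augment_sample(wrap(gt), spec[1], spec[2])$mask
    ev <- seg_evaluate(ap, ag_)
    expect_identical(ev$dsc, base$dsc)
    expect_identical(ev$iou, base$iou)
  }
})
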