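# Model assembly: deterministic builds, parameter accounting across the
# ablation lattice, forward contracts, checkpointing, and norm plumbing.

test_that("two builds with the same seed are bit-identical", {
  m1 <- build_model(model_config_small(), seed = 4)
  m2 <- build_model(model_config_small(), seed = 4)
  expect_identical(names(m1$params), names(m2$params))
  for (nm in names(m1$params)) {
    expect_identical(ag_value(m1$params[[nm]]), ag_value(m2$params[[nm]]))
  }
  m3 <- build_model(model_config_small(), seed = 5)
  expect_false(identical(ag_value(m3$params[["stage3.block1.conv1.w"]]),
                         ag_value(m1$params[["stage3.block1.conv1.w"]])))
})

test_that("default-width model lands in the expected parameter corridor", {
  m <- build_model(model_config(), seed = 1)
  n <- count_parameters(m)$total
  expect_gte(n, 15e6)
  expect_lte(n, 25e6)
})

test_that("parameter breakdown sums to the total and isolates the blocks", {
  m <- build_model(model_config_small(), seed = 1)
  cp <- count_parameters(m)
  expect_equal(sum(unlist(cp$by_module)), cp$total)
  # disabling GCA removes exactly the GCA submodule mass
  m0 <- build_model(model_config_small(use_gca = FALSE), seed = 1)
  cp0 <- count_parameters(m0)
  gca_mass <- sum(unlist(cp$by_module[grepl("^gca", names(cp$by_module))]))
  expect_equal(cp$total - cp0$total, gca_mass)
  # counting is pure: a forward pass does not change it
  smp <- generate_sample(synth_spec(size = 64, mode = "easy", seed = 2))
  invisible(suppressWarnings(model_forward(m, smp$image)))
  expect_identical(count_parameters(m)$total, cp$total)
})

test_that("the ablation lattice builds with strictly increasing parameters", {
  base <- build_model(model_config_small(use_gca = FALSE, use_stlb = FALSE,
                                         use_stb = FALSE), seed = 1)
  g <- build_model(model_config_small(use_stlb = FALSE, use_stb = FALSE), seed = 1)
  gs <- build_model(model_config_small(use_stb = FALSE), seed = 1)
  full <- build_model(model_config_small(), seed = 1)
  counts <- vapply(list(base, g, gs, full), function(m) count_parameters(m)$total,
                   numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("forward output contracts hold at 64x64", {
  m <- build_model(model_config_small(), seed = 1)
  smp <- generate_sample(synth_spec(size = 64, mode = "easy", seed = 3))
  out <- suppressWarnings(model_forward(m, smp$image))
  pr <- ag_value(out$probabilities)
  expect_equal(dim(pr), c(2, 64, 64))
  expect_lt(max(abs(apply(pr, c(2, 3), sum) - 1)), 1e-9)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(dim(ag_value(out$affine)), c(2, 3))
  expect_true(all(out$mask %in% c(0, 1)))
  # evaluation-mode determinism
  out2 <- suppressWarnings(model_forward(m, smp$image))
  expect_identical(pr, ag_value(out2$probabilities))
  # undersized input rejected
  expect_error(model_forward(m, matrix(0.5, 16, 16)), ">= 32")
})

test_that("norm flavor switches without touching non-norm parameters", {
  cfgL <- model_config_small()
  cfgB <- model_config_small()
  cfgB$backbone$norm <- "batch"
  mL <- build_model(cfgL, seed = 9)
  mB <- build_model(cfgB, seed = 9)
  expect_identical(names(mL$params), names(mB$params))
  for (nm in names(mL$params)) {
    expect_identical(ag_value(mL$params[[nm]]), ag_value(mB$params[[nm]]))
  }
  smp <- generate_sample(synth_spec(size = 64, mode = "easy", seed = 10))
  oL <- suppressWarnings(model_forward(mL, smp$image))
  oB <- suppressWarnings(model_forward(mB, smp$image))
  expect_false(identical(ag_value(oL$probabilities), ag_value(oB$probabilities)))
})

test_that("checkpoint round trip restores the model and validates config", {
  td <- withr::local_tempdir()
  m <- build_model(model_config_small(), seed = 6)
  pth <- file.path(td, "ck.rds")
  save_checkpoint(m, pth)
  m2 <- load_checkpoint(pth, expect_cfg = m$cfg)
  for (nm in names(m$params)) {
    expect_identical(ag_value(m$params[[nm]]), ag_value(m2$params[[nm]]))
  }
  smp <- generate_sample(synth_spec(size = 64, mode = "easy", seed = 7))
  o1 <- suppressWarnings(model_forward(m, smp$image))
  o2 <- suppressWarnings(model_forward(m2, smp$image))
  expect_identical(ag_value(o1$probabilities), ag_value(o2$probabilities))
  other <- model_config_small(use_stb = FALSE)
  expect_error(load_checkpoint(pth, expect_cfg = other), "match")
  saveRDS(list(a = 1), file.path(td, "junk.rds"))
  expect_error(load_checkpoint(file.path(td, "junk.rds")), "checkpoint")
})

test_that("STB head at init reduces the network head to the initial softmax", {
  m <- build_model(model_config_small(), seed = 8)
  smp <- generate_sample(synth_spec(size = 64, mode = "easy", seed = 8))
  out <- suppressWarnings(model_forward(m, smp$image))
  expect_identical(ag_value(out$affine),
                   matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE))
})
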