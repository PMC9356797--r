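# Synthetic lesion image generator.
#
# Produces grayscale image/mask pairs that emulate the failure modes that
# make tumor MRI segmentation hard: blurred low-contrast boundaries, very
# small transverse-section lesions, and complex irregular boundaries with
# small interior gaps. Masks are unions of Fourier-perturbed ellipses
# (radial deformation of orders 2-5), which gives smooth, irregular,
# tumor-like outlines with controllable complexity; the image is a smoothed
# noise background plus a contrast-scaled lesion offset, Gaussian-blurred
# and corrupted with additive noise. Everything is deterministic for a fixed
# seed and computed on the integer pixel lattice.

#' Specification of one synthetic sample
#'
#' @param size Square image side in pixels (>= 32).
#' @param mode One of "easy", "blurred_boundary", "small_lesion",
#'   "complex_gaps".
#' @param contrast Lesion-background intensity offset in (0, 1].
#' @param blur_sigma Gaussian blur of the final image, pixels.
#' @param lesion_scale Target lesion area fraction of the image (upper
#'   bound in small_lesion mode).
#' @param n_gaps Number of interior background slits (complex_gaps mode).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return List of class `synth_spec`. Unset parameters take mode-specific
#'   defaults.
#' @export
synth_spec <- function(size = 128, mode = "easy", contrast = NULL,
                       blur_sigma = NULL, lesion_scale = NULL, n_gaps = NULL,
                       noise_sd = NULL, seed = 1) {
  mode <- match.arg(mode, c("easy", "blurred_boundary", "small_lesion", "complex_gaps"))
  stopifnot(size >= 32)
  def <- switch(mode,
    easy = list(contrast = 0.9, blur_sigma = 1, lesion_scale = 0.12,
                n_gaps = 0L, noise_sd = 0.02),
    blurred_boundary = list(contrast = 0.25, blur_sigma = 6, lesion_scale = 0.10,
                            n_gaps = 0L, noise_sd = 0.05),
    small_lesion = list(contrast = 0.6, blur_sigma = 2, lesion_scale = 0.02,
                        n_gaps = 0L, noise_sd = 0.04),
    complex_gaps = list(contrast = 0.6, blur_sigma = 1.5, lesion_scale = 0.12,
                        n_gaps = 3L, noise_sd = 0.04))
  sp <- list(size = as.integer(size), mode = mode,
             contrast = contrast %||% def$contrast,
             blur_sigma = blur_sigma %||% def$blur_sigma,
             lesion_scale = lesion_scale %||% def$lesion_scale,
             n_gaps = as.integer(n_gaps %||% def$n_gaps),
             noise_sd = noise_sd %||% def$noise_sd,
             seed = as.integer(seed))
  stopifnot(sp$contrast > 0, sp$contrast <= 1, sp$lesion_scale > 0,
            sp$lesion_scale < 1, sp$noise_sd >= 0, sp$blur_sigma >= 0)
  structure(sp, class = "synth_spec")
}

# radial Fourier blob mask: r(theta) = r0 (1 + sum_k a_k cos(k theta + phi_k))
fourier_blob <- function(size, cx, cy, r0, amp, orders = 2:5) {
  a <- stats::rnorm(length(orders), 0, amp / orders)
  phi <- stats::runif(length(orders), 0, 2 * pi)
  xs <- matrix(rep(seq_len(size), each = size), size, size)  # column index
  ys <- matrix(rep(seq_len(size), times = size), size, size) # row index
  dx <- xs - cx; dy <- ys - cy
  th <- atan2(dy, dx)
  rad <- sqrt(dx^2 + dy^2)
  rb <- r0 * (1 + Reduce(`+`, lapply(seq_along(orders), function(k)
    a[k] * cos(orders[k] * th + phi[k]))))
  (rad <= pmax(rb, 1)) * 1
}

#' Generate one synthetic image/mask pair
#'
#' @param spec A [synth_spec()].
#' @return A sample pair: list with `image` (matrix in [0, 1]), `mask`
#'   (binary matrix), `id`, `meta`.
#' @export
generate_sample <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$size
  with_local_seed(spec$seed, {
    target_frac <- if (spec$mode == "small_lesion") spec$lesion_scale * 0.7
                   else spec$lesion_scale
    r0 <- sqrt(target_frac * n^2 / pi)
    if (r0 < 2) stop("lesion_scale too small: no blob fits the pixel lattice", call. = FALSE)
    amp <- switch(spec$mode, complex_gaps = 0.45, blurred_boundary = 0.25,
                  small_lesion = 0.2, easy = 0.2)
    n_blobs <- if (spec$mode %in% c("small_lesion", "easy")) 1L else sample(1:2, 1)
    mask <- matrix(0, n, n)
    for (b in seq_len(n_blobs)) {
      margin <- r0 * 1.6 + 2
      cx <- stats::runif(1, margin, n - margin)
      cy <- stats::runif(1, margin, n - margin)
      rb <- if (b == 1) r0 else r0 * stats::runif(1, 0.4, 0.7)
      mask <- pmax(mask, fourier_blob(n, cx, cy, rb, amp))
    }
    if (spec$mode == "small_lesion") {
      # enforce the stated hard cap on lesion area
      while (mean(mask) > spec$lesion_scale) {
        mask <- mask * 0
        r0 <- r0 * 0.9
        if (r0 < 2) stop("lesion_scale too small: no blob fits the pixel lattice", call. = FALSE)
        cx <- stats::runif(1, r0 * 1.6 + 2, n - r0 * 1.6 - 2)
        cy <- stats::runif(1, r0 * 1.6 + 2, n - r0 * 1.6 - 2)
        mask <- fourier_blob(n, cx, cy, r0, amp)
      }
    }
    if (spec$n_gaps > 0 && sum(mask) > 0) {
      # carve thin slits fully interior to the lesion so each becomes an
      # isolated background component
      ys <- which(mask > 0, arr.ind = TRUE)
      cen <- colMeans(ys)
      rad_in <- sqrt(sum(mask) / pi)
      xs <- matrix(rep(seq_len(n), each = n), n, n)
      yy <- matrix(rep(seq_len(n), times = n), n, n)
      for (g in seq_len(spec$n_gaps)) {
        ang <- stats::runif(1, 0, pi)
        off <- stats::runif(1, -0.35, 0.35) * rad_in
        half_len <- rad_in * stats::runif(1, 0.25, 0.45)
        ux <- cos(ang); uy <- sin(ang)
        px <- cen[2] - uy * off; py <- cen[1] + ux * off
        tpar <- (xs - px) * ux + (yy - py) * uy
        dperp <- abs(-(xs - px) * uy + (yy - py) * ux)
        slit <- dperp <= 1 & abs(tpar) <= half_len
        # keep the slit strictly inside the lesion (1-pixel shell preserved)
        interior <- mask > 0 &
          shift2d(mask, 1, 0) > 0 & shift2d(mask, -1, 0) > 0 &
          shift2d(mask, 0, 1) > 0 & shift2d(mask, 0, -1) > 0 &
          shift2d(mask, 1, 1) > 0 & shift2d(mask, -1, -1) > 0 &
          shift2d(mask, 1, -1) > 0 & shift2d(mask, -1, 1) > 0
        mask[slit & interior] <- 0
      }
    }
    bg <- gauss_blur2d(matrix(stats::rnorm(n * n), n, n), 4)
    bg <- 0.35 + 0.10 * bg / max(abs(bg))
    img <- bg + spec$contrast * 0.55 * mask
    img <- gauss_blur2d(img, spec$blur_sigma)
    if (spec$noise_sd > 0) img <- img + stats::rnorm(n * n, 0, spec$noise_sd)
    img <- pmin(pmax(img, 0), 1)
    list(image = img, mask = mask,
         id = sprintf("%s_%06d", spec$mode, spec$seed),
         meta = list(mode = spec$mode, seed = as.character(spec$seed),
                     contrast = as.character(spec$contrast)))
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes n image/mask PNG pairs and a manifest CSV with columns
#' id, image_path, mask_path, split (80/20 split by default).
#'
#' @param n Number of samples.
#' @param mode_mix Named numeric vector of mode proportions (normalized).
#' @param seed Master seed; per-sample seeds are derived from it.
#' @param out_dir Output directory (created if missing).
#' @param size Image side in pixels.
#' @param train_fraction Fraction assigned to the training split.
#' @return Manifest data frame (invisibly also written to
#'   `out_dir/manifest.csv`).
#' @export
generate_dataset <- function(n, mode_mix = c(easy = 1), seed = 1, out_dir,
                             size = 128, train_fraction = 0.8) {
  stopifnot(n >= 1)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir, call. = FALSE)
  mode_mix <- mode_mix / sum(mode_mix)
  modes <- with_local_seed(seed, sample(names(mode_mix), n, replace = TRUE, prob = mode_mix))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- synth_spec(size = size, mode = modes[i], seed = derive_seed(seed, i))
    smp <- generate_sample(sp)
    id <- sprintf("%s_%04d", modes[i], i)
    ip <- file.path(out_dir, paste0(id, "_img.png"))
    mp <- file.path(out_dir, paste0(id, "_mask.png"))
    png::writePNG(smp$image, ip)
    png::writePNG(smp$mask, mp)
    rows[[i]] <- data.frame(id = id, image_path = ip, mask_path = mp,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  if (n >= 2) {
    spl <- split_dataset(manifest$id, fraction = train_fraction, seed = seed)
    manifest$split <- ifelse(manifest$id %in% spl$train, "train", "test")
  } else {
    manifest$split <- "train"
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Generate a list of in-memory synthetic samples
#'
#' Convenience wrapper used by tests and the training smoke runs.
#'
#' @param n Number of samples.
#' @param mode Difficulty mode.
#' @param size Image side.
#' @param seed Master seed.
#' @return List of sample pairs.
#' @export
generate_samples <- function(n, mode = "easy", size = 64, seed = 1) {
  lapply(seq_len(n), function(i)
    generate_sample(synth_spec(size = size, mode = mode, seed = derive_seed(seed, i))))
}
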