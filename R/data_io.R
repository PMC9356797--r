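# Image/mask I/O, dataset splitting, and the augmentation menu: rotations
# (0/90/180), flips (none/up-down/left-right), Gaussian blur, Gaussian
# noise, and salt-and-pepper noise. Geometric operations apply to image and
# mask alike (nearest-neighbor on the mask, which the right-angle rotations
# and flips preserve exactly); intensity operations touch the image only.

read_gray <- function(path) {
  lp <- tolower(path)
  img <- if (grepl("\\.png$", lp)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", lp)) {
    tiff::readTIFF(path)
  } else if (grepl("\\.nii(\\.gz)?$", lp)) {
    v <- RNifti::readNifti(path)
    v <- drop(as.array(v))
    if (length(dim(v)) == 3L && dim(v)[3] == 1L) v <- v[, , 1]
    if (length(dim(v)) != 2L) stop("NIfTI input must be a single slice", call. = FALSE)
    v
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  if (length(dim(img)) == 3L) {
    warning("multi-channel image ", basename(path), "; channels averaged")
    img <- apply(img, c(1, 2), mean)
  }
  img
}

#' Load an image/mask pair as a sample
#'
#' The image is min-max normalized to [0, 1]; the mask is binarized at the
#' midpoint of its value range.
#'
#' @param image_path Grayscale PNG/TIFF or single-slice NIfTI file.
#' @param mask_path Mask PNG (0 = background, 255 = tumor).
#' @param id Optional sample id (defaults to the image file stem).
#' @return Sample pair: list(image, mask, id, meta).
#' @export
load_sample <- function(image_path, mask_path, id = NULL) {
  stopifnot(file.exists(image_path), file.exists(mask_path))
  img <- read_gray(image_path)
  msk <- read_gray(mask_path)
  if (!identical(dim(img), dim(msk))) {
    stop("image and mask shapes differ: ", paste(dim(img), collapse = "x"),
         " vs ", paste(dim(msk), collapse = "x"), call. = FALSE)
  }
  rng <- range(img)
  img <- if (rng[2] > rng[1]) (img - rng[1]) / (rng[2] - rng[1]) else img * 0
  # PNG/TIFF readers scale to [0, 1], so the dtype-range midpoint is 0.5;
  # NIfTI slices are thresholded at the midpoint of their own range
  mid <- if (grepl("\\.nii(\\.gz)?$", tolower(mask_path))) 0.5 * (min(msk) + max(msk)) else 0.5
  msk <- (msk > mid) * 1
  list(image = img, mask = msk,
       id = id %||% sub("\\.[^.]+$", "", basename(image_path)),
       meta = list())
}

#' Save a sample's image and mask as PNGs
#' @param sample Sample pair.
#' @param image_path,mask_path Output paths.
#' @export
save_sample <- function(sample, image_path, mask_path) {
  png::writePNG(sample$image, image_path)
  png::writePNG(sample$mask, mask_path)
  invisible(c(image_path, mask_path))
}

#' Randomly split ids into train and test sets
#'
#' Deterministic for a fixed seed; the split is a partition, and the train
#' share matches `fraction` to within one sample (ceiling rule; 204 ids at
#' 0.8 give 164 train / 40 test).
#'
#' @param ids Character or integer vector of at least 2 distinct ids.
#' @param fraction Train fraction in (0, 1).
#' @param seed Integer seed.
#' @return List: train, test, seed.
#' @export
split_dataset <- function(ids, fraction = 0.8, seed = 1) {
  if (length(ids) == 0) stop("empty id list", call. = FALSE)
  stopifnot(length(ids) >= 2, fraction > 0, fraction < 1)
  n_train <- min(length(ids) - 1L, max(1L, ceiling(fraction * length(ids))))
  perm <- with_local_seed(seed, sample(ids))
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[-seq_len(n_train)]),
       seed = as.integer(seed))
}

rotate_k <- function(m, angle) {
  switch(as.character(angle),
    "0" = m,
    "90" = t(m[nrow(m):1, , drop = FALSE]),
    "180" = m[nrow(m):1, ncol(m):1, drop = FALSE],
    stop("unsupported rotation angle ", angle, call. = FALSE))
}

#' Apply one augmentation operation to a sample
#'
#' Geometric operations (rotate, flip) transform image and mask identically;
#' intensity operations (gaussian_blur, gaussian_noise, salt_pepper) change
#' the image only. The image is clipped back to [0, 1].
#'
#' @param sample Sample pair.
#' @param op Operation name: "rotate", "flip", "gaussian_blur",
#'   "gaussian_noise", "salt_pepper".
#' @param param Operation parameter: angle (0/90/180), flip axis ("none",
#'   "updown", "leftright"), blur sigma, noise variance, or corrupted-pixel
#'   proportion.
#' @param seed Seed for the stochastic operations.
#' @return Augmented sample pair with lineage recorded in `meta`.
#' @export
augment_sample <- function(sample, op, param = NULL, seed = 1) {
  img <- sample$image; msk <- sample$mask
  op <- as.character(op)
  if (op %in% c("gaussian_blur", "gaussian_noise", "salt_pepper") &&
      (!is.numeric(param) || param < 0)) {
    stop("parameter for ", op, " must be a nonnegative number", call. = FALSE)
  }
  if (op == "rotate") {
    img <- rotate_k(img, param); msk <- rotate_k(msk, param)
  } else if (op == "flip") {
    ax <- match.arg(as.character(param), c("none", "updown", "leftright"))
    if (ax == "updown") { img <- img[nrow(img):1, , drop = FALSE]; msk <- msk[nrow(msk):1, , drop = FALSE] }
    if (ax == "leftright") { img <- img[, ncol(img):1, drop = FALSE]; msk <- msk[, ncol(msk):1, drop = FALSE] }
  } else if (op == "gaussian_blur") {
    img <- gauss_blur2d(img, param)
  } else if (op == "gaussian_noise") {
    img <- with_local_seed(seed, img + stats::rnorm(length(img), 0, sqrt(param)))
  } else if (op == "salt_pepper") {
    k <- floor(param * length(img))
    if (k > 0) {
      img <- with_local_seed(seed, {
        idx <- sample(length(img), k)
        img[idx] <- (stats::runif(k) < 0.5) * 1
        img
      })
    }
  } else {
    stop("unknown augmentation op '", op, "'", call. = FALSE)
  }
  img <- pmin(pmax(img, 0), 1)
  meta <- sample$meta
  meta$augment <- paste(c(meta$augment, paste0(op, "(", param %||% "", ")")), collapse = ";")
  list(image = img, mask = msk, id = paste0(sample$id, "_", op), meta = meta)
}

#' Read a dataset manifest CSV
#' @param path CSV with columns id, image_path, mask_path, split.
#' @return Data frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "image_path", "mask_path")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  m
}

#' Load all samples listed in a manifest
#' @param manifest Data frame from [read_manifest()] (or its path).
#' @param split Optional split filter ("train"/"test").
#' @return List of sample pairs.
#' @export
load_manifest_samples <- function(manifest, split = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (!is.null(split) && "split" %in% names(manifest)) {
    manifest <- manifest[manifest$split == split, , drop = FALSE]
  }
  lapply(seq_len(nrow(manifest)), function(i)
    load_sample(manifest$image_path[i], manifest$mask_path[i], id = manifest$id[i]))
}
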