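# Canny edge detection on 2-D arrays in [0, 1]: Gaussian smoothing, Sobel
# gradients, non-maximum suppression along the quantized gradient direction,
# and hysteresis thresholding.

gauss_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur with replicated edges
gauss_blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gauss_kernel_1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  pr <- m[c(rep(1, r), seq_len(H), rep(H, r)), , drop = FALSE]
  tmp <- matrix(0, H, W)
  for (t in seq_along(k)) tmp <- tmp + k[t] * pr[(t - 1) + seq_len(H), , drop = FALSE]
  pc <- tmp[, c(rep(1, r), seq_len(W), rep(W, r)), drop = FALSE]
  out <- matrix(0, H, W)
  for (t in seq_along(k)) out <- out + k[t] * pc[, (t - 1) + seq_len(W), drop = FALSE]
  out
}

shift2d <- function(m, di, dj, fill = 0) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  si <- seq_len(H) - di; sj <- seq_len(W) - dj
  oki <- si >= 1 & si <= H; okj <- sj >= 1 & sj <= W
  out[oki, okj] <- m[si[oki], sj[okj]]
  out
}

# shift with replicated edges so constant images have zero gradient at the
# borders (a zero fill would fabricate frame edges)
shift2d_rep <- function(m, di, dj) {
  H <- nrow(m); W <- ncol(m)
  si <- pmin(pmax(seq_len(H) - di, 1), H)
  sj <- pmin(pmax(seq_len(W) - dj, 1), W)
  m[si, sj, drop = FALSE]
}

sobel_gradients <- function(m) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  gx <- matrix(0, nrow(m), ncol(m)); gy <- gx
  for (a in -1:1) for (b in -1:1) {
    s <- shift2d_rep(m, -a, -b)
    gx <- gx + kx[a + 2, b + 2] * s
    gy <- gy + ky[a + 2, b + 2] * s
  }
  list(gx = gx, gy = gy)
}

#' Canny edge map of a 2-D image
#'
#' @param img Numeric matrix in [0, 1] (binary masks work directly).
#' @param low,high Hysteresis thresholds on the normalized gradient
#'   magnitude.
#' @param sigma Gaussian pre-smoothing standard deviation in pixels.
#' @return Binary matrix (0/1) of edge pixels; a constant image yields all
#'   zeros.
#' @export
canny_edges <- function(img, low = 0.1, high = 0.3, sigma = 1) {
  stopifnot(is.matrix(img))
  sm <- gauss_blur2d(img, sigma)
  g <- sobel_gradients(sm)
  mag <- sqrt(g$gx^2 + g$gy^2)
  mx <- max(mag)
  if (mx <= 0) return(matrix(0, nrow(img), ncol(img)))
  mag <- mag / mx
  ang <- atan2(g$gy, g$gx)
  # quantize direction to 0, 45, 90, 135 degrees
  sector <- (round(ang / (pi / 4)) %% 4)
  offs <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  nms <- matrix(0, nrow(img), ncol(img))
  for (s in 0:3) {
    o <- offs[[as.character(s)]]
    n1 <- shift2d(mag, o[1], o[2]); n2 <- shift2d(mag, -o[1], -o[2])
    sel <- sector == s & mag >= n1 & mag >= n2
    nms[sel] <- mag[sel]
  }
  strong <- nms >= high
  weak <- nms >= low
  # grow strong edges through connected weak pixels (8-neighborhood)
  repeat {
    grown <- strong
    for (a in -1:1) for (b in -1:1) {
      if (a == 0 && b == 0) next
      grown <- grown | (shift2d(strong * 1, a, b) > 0 & weak)
    }
    if (identical(grown, strong)) break
    strong <- grown
  }
  matrix(as.numeric(strong), nrow(img), ncol(img))
}

#' Label 4-connected components of a binary matrix
#'
#' Iterative label-propagation flood fill; small inputs only.
#'
#' @param mask Binary matrix.
#' @return Integer matrix of component labels (0 = off pixels).
#' @export
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(seq_len(H * W), H, W) * (mask > 0)
  repeat {
    nb <- pmax(shift2d(lab, 1, 0), shift2d(lab, -1, 0),
               shift2d(lab, 0, 1), shift2d(lab, 0, -1))
    new <- pmax(lab, nb * (mask > 0))
    if (identical(new, lab)) break
    lab <- new
  }
  u <- sort(unique(lab[lab > 0]))
  matrix(match(lab, u, nomatch = 0L), H, W)
}
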