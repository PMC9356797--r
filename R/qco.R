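# Quantization and counting operators (QCO).
#
# The 1-d operator summarizes a feature map's texture statistics: every pixel
# is scored by cosine similarity to the map's mean feature, the similarity
# range is divided into N quantization levels, each pixel is softly encoded
# against its nearest level, and the per-level encoding mass is counted and
# normalized into a histogram. The 2-d operator does the same for adjacent
# pixel pairs (width-direction neighbors), yielding a soft co-occurrence
# matrix over level pairs.
#
# Before quantization the similarity map is min-max normalized to [0, 1].
# The encoding bins of the quantization rule have absolute half-width 0.5/N,
# which tiles the level spacing only when the similarity range is exactly 1;
# normalization makes the bins and levels align for any input. Values below
# the first level's bin (similarity exactly 0) fall in a dead zone and encode
# to an all-zero row; `centered_levels = TRUE` shifts the levels to
# (n - 0.5)/N for full coverage.

#' Cosine similarity of each pixel to the mean feature
#'
#' @param x Array or `ag` node, C x H x W.
#' @return `ag` node 1 x H x W with values in [-1, 1]; pixels (or a mean
#'   feature) with zero norm get similarity 0 with a warning.
#' @export
cosine_similarity_map <- function(x) {
  x <- if (is_ag(x)) x else ag(x)
  tiny <- 1e-24
  a <- ag_global_avg(x)                                  # C x 1 x 1
  dot <- ag_sum_channels(ag_mul_bcast(x, a))             # 1 x H x W
  na2 <- ag_sum(ag_mul(a, a))
  np2 <- ag_sum_channels(ag_mul(x, x))
  if (ag_value(na2) < tiny || any(ag_value(np2) < tiny)) {
    warning("zero-norm feature encountered; cosine similarity set to 0 there")
  }
  na <- ag_sqrt(ag_add(na2, tiny))
  np <- ag_sqrt(ag_add(np2, tiny))
  denom <- ag_mul_bcast(np, ag_reshape(na, c(1, 1, 1)))
  ag_div(dot, denom)
}

#' Min-max normalize a similarity map to [0, 1]
#'
#' The range endpoints are treated as constants (no gradient through the
#' extrema). A constant map normalizes to all zeros with a warning.
#'
#' @param s `ag` node or array.
#' @return `ag` node of the same shape.
#' @export
normalize_similarity <- function(s) {
  s <- if (is_ag(s)) s else ag(s)
  v <- ag_value(s)
  mn <- min(v); mx <- max(v)
  if (mx - mn < 1e-12) {
    warning("constant similarity map; quantization degenerates")
    return(ag_mul_const(s, 0))
  }
  ag_mul_const(ag_sub(s, mn), 1 / (mx - mn))
}

#' Quantization levels for a similarity map
#'
#' L_n = (n/N) (max S - min S) + min S for n = 1..N.
#'
#' @param s Similarity values (array, `ag` node, or numeric vector).
#' @param n_levels Number of levels N.
#' @return Numeric vector of N levels (constants, not differentiated).
#' @export
quantize_levels <- function(s, n_levels) {
  stopifnot(n_levels >= 1)
  v <- as.numeric(ag_value(s))
  mn <- min(v); mx <- max(v)
  if (mx == mn) warning("constant similarity map; all levels equal its value")
  (seq_len(n_levels) / n_levels) * (mx - mn) + mn
}

#' Soft level encoding of a similarity map
#'
#' E[n, i] = 1 - |L_n - S_i| when -0.5/N <= L_n - S_i < 0.5/N, else 0
#' (half-open bins of absolute half-width 0.5/N).
#'
#' @param s Similarity map (`ag` node, array, or vector); flattened to HW.
#' @param levels Level vector from [quantize_levels()].
#' @return `ag` node, N x HW encoding map.
#' @export
encode_1d <- function(s, levels) {
  s_ag <- if (is_ag(s)) s else ag(s)
  sv <- as.numeric(ag_value(s_ag))
  N <- length(levels)
  h <- 0.5 / N
  D <- outer(levels, sv, "-")                  # N x HW
  mask <- (D >= -h) & (D < h)
  E <- (1 - abs(D)) * mask
  ag_node(E, list(s_ag), function(g) {
    list(same_shape(colSums(g * sign(D) * mask), ag_value(s_ag)))
  })
}

#' Counting operation over a 1-d encoding map
#'
#' @param e Encoding map (`ag` node or matrix), N x HW.
#' @param levels Level vector.
#' @return List: `levels`, `counts` (`ag` node, length N, summing to 1 when
#'   the total encoding mass is positive), and `counting_map` (numeric N x 2
#'   matrix of level value and normalized count).
#' @export
count_1d <- function(e, levels) {
  e <- if (is_ag(e)) e else ag(e)
  raw <- ag_rowsums(e)
  tot <- sum(ag_value(raw))
  if (tot <= 0) {
    warning("zero total encoding mass; normalized counts set to 0")
    counts <- ag_mul_const(raw, 0)
  } else {
    counts <- ag_div(raw, ag_sum(raw))
  }
  list(levels = levels, counts = counts,
       counting_map = cbind(level = levels, count = as.numeric(ag_value(counts))))
}

# statistical feature P = Concat(Up(M), a): a learned lift of the counting
# map, concatenated with the broadcast mean feature (one row per level)
qco_stat_feature <- function(m_mat, a_vec, up) {
  N <- nrow(ag_value(m_mat))
  lift <- ag_matmul(m_mat, ag_t(up$w))
  if (!is.null(up$b)) lift <- ag_add(lift, ag_rep_rows(up$b, N))
  ag_cbind(list(lift, ag_rep_rows(a_vec, N)))
}

#' 1-d quantization-counting operator
#'
#' Composes [cosine_similarity_map()], [normalize_similarity()],
#' [quantize_levels()], [encode_1d()] and [count_1d()]; with parameters it
#' also produces the statistical feature P (one row per level: learned lift
#' of the counting map concatenated with the broadcast mean feature).
#'
#' @param x Array or `ag` node, C x H x W.
#' @param n_levels Number of quantization levels N.
#' @param params Optional list with `up` (linear parameters lifting the N x 2
#'   counting map); P is NULL without it.
#' @param centered_levels Use levels (n - 0.5)/N for full bin coverage.
#' @return List: `similarity` (normalized, 1 x H x W), `levels`, `encoding`
#'   (`ag`, N x HW), `counts` (`ag`, N), `counting_map`, `mean_feature`
#'   (`ag`, length C), `P` (`ag`, N x C1 or NULL).
#' @export
qco_1d <- function(x, n_levels, params = NULL, centered_levels = FALSE) {
  x <- if (is_ag(x)) x else ag(x)
  s <- normalize_similarity(cosine_similarity_map(x))
  levels <- if (centered_levels) (seq_len(n_levels) - 0.5) / n_levels
            else quantize_levels(s, n_levels)
  e <- encode_1d(s, levels)
  cnt <- count_1d(e, levels)
  C <- dim(ag_value(x))[1]
  a_vec <- ag_reshape(ag_global_avg(x), C)
  P <- NULL
  if (!is.null(params)) {
    m_mat <- ag_cbind(list(ag(matrix(levels, ncol = 1)),
                           ag_reshape(cnt$counts, c(n_levels, 1))))
    P <- qco_stat_feature(m_mat, a_vec, params$up)
  }
  list(similarity = s, levels = levels, encoding = e, counts = cnt$counts,
       counting_map = cnt$counting_map, mean_feature = a_vec, P = P)
}

#' 2-d quantization-counting operator (adjacent-pair co-occurrence)
#'
#' Encodes each pixel as in [qco_1d()], then counts the outer products of the
#' encodings of width-direction neighbor pairs (i, j) and (i, j + 1) into a
#' normalized N x N co-occurrence map over level pairs.
#'
#' @inheritParams qco_1d
#' @return List: `similarity`, `levels`, `encoding` (1-d, N x HW), `counts2`
#'   (`ag`, N x N normalized co-occurrence, rows = level of the left pixel),
#'   `level_pairs` (N^2 x 2 matrix, row-major in (m, n) with m fastest),
#'   `mean_feature`, `P` (`ag`, N^2 x C1 or NULL).
#' @export
qco_2d <- function(x, n_levels, params = NULL, centered_levels = FALSE) {
  x <- if (is_ag(x)) x else ag(x)
  d <- dim(ag_value(x)); H <- d[2]; W <- d[3]
  if (W < 2) stop("2-d QCO needs width >= 2 for adjacent pixel pairs", call. = FALSE)
  s <- normalize_similarity(cosine_similarity_map(x))
  levels <- if (centered_levels) (seq_len(n_levels) - 0.5) / n_levels
            else quantize_levels(s, n_levels)
  e <- encode_1d(s, levels)
  # pixel (i, j) flattens to i + H (j - 1); left block = columns 1..H(W-1),
  # right block = the same pixels shifted one column right
  n_pairs <- H * (W - 1)
  e_left <- ag_cols(e, seq_len(n_pairs))
  e_right <- ag_cols(e, H + seq_len(n_pairs))
  raw2 <- ag_matmul(e_left, ag_t(e_right))      # N x N, sum of outer products
  tot <- sum(ag_value(raw2))
  if (tot <= 0) {
    warning("zero total pair-encoding mass; normalized counts set to 0")
    counts2 <- ag_mul_const(raw2, 0)
  } else {
    counts2 <- ag_div(raw2, ag_sum(raw2))
  }
  level_pairs <- cbind(rep(levels, times = n_levels), rep(levels, each = n_levels))
  C <- d[1]
  a_vec <- ag_reshape(ag_global_avg(x), C)
  P <- NULL
  if (!is.null(params)) {
    m_mat <- ag_cbind(list(ag(level_pairs),
                           ag_reshape(counts2, c(n_levels^2, 1))))
    P <- qco_stat_feature(m_mat, a_vec, params$up)
  }
  list(similarity = s, levels = levels, encoding = e, counts2 = counts2,
       level_pairs = level_pairs, mean_feature = a_vec, P = P)
}

#' Materialize the full 2-d pair encoding on a small map
#'
#' Builds the N x N x H x (W - 1) array of outer products of adjacent-pair
#' encodings; intended for small inputs and testing, since the full array is
#' never needed by the forward pass.
#'
#' @param e Encoding map values (N x HW matrix).
#' @param H,W Spatial size of the encoded map.
#' @return Numeric array N x N x H x (W - 1).
#' @export
encode_2d_full <- function(e, H, W) {
  e <- ag_value(e)
  N <- nrow(e)
  out <- array(0, dim = c(N, N, H, W - 1))
  for (j in seq_len(W - 1)) {
    for (i in seq_len(H)) {
      out[, , i, j] <- outer(e[, i + H * (j - 1)], e[, i + H * j])
    }
  }
  out
}
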