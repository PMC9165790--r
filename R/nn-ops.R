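# Internal helpers: feature maps travel as (H, W, C) arrays; single-channel
# matrices are promoted on entry and demoted on exit by the exported 2-D ops.

as_cube <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

conv_same <- function(x, W, b, k, rate = 1L) {
  pad <- rate * (k - 1L) %/% 2L
  cpp_conv_forward(as_cube(x), W, b, as.integer(k), as.integer(rate),
                   as.integer(pad))
}

relu <- function(x) { x[x < 0] <- 0; x }

#' Non-overlapping 2x2 max pooling with stored argmax indices
#'
#' Pools with 2x2 windows at stride 2 and records, per output cell, the
#' position of the window maximum (the "pool index") so the decoder can
#' restore values to their original locations. Ties resolve to the first
#' cell in row-major window order (top-left first). Odd trailing rows or
#' columns are dropped.
#'
#' @param map numeric matrix (or `H x W x C` array) with sides >= 2.
#' @return list of class `pool_index_map`: `pooled` (same rank as input),
#'   `indices` (1-based column-major linear positions into each input
#'   slice), `input_dim`, `output_dim`.
#' @export
max_pool_with_indices <- function(map) {
  if (length(map) == 0L) stop("empty map")
  was_matrix <- is.matrix(map)
  x <- as_cube(map)
  if (nrow(x) < 2L || ncol(x) < 2L) stop("map sides must be >= 2")
  res <- cpp_maxpool(x)
  out_dim <- c(nrow(x) %/% 2L, ncol(x) %/% 2L, dim(x)[3])
  pooled <- res$pooled
  idx <- array(res$indices, dim = out_dim)
  if (was_matrix) { dim(pooled) <- out_dim[1:2]; dim(idx) <- out_dim[1:2] }
  structure(list(pooled = pooled, indices = idx,
                 input_dim = dim(x)[1:2], output_dim = out_dim[1:2]),
            class = "pool_index_map")
}

#' Sparse non-linear upsampling from stored pool indices
#'
#' Places each pooled value back at the position recorded by
#' [max_pool_with_indices()]; every other cell is zero, so exactly one cell
#' per 2x2 window is nonzero.
#'
#' @param pooled pooled matrix/array whose size matches `idx$output_dim`.
#' @param idx a `pool_index_map`.
#' @return sparse map of size `idx$input_dim`.
#' @export
max_unpool <- function(pooled, idx) {
  stopifnot(inherits(idx, "pool_index_map"))
  was_matrix <- is.matrix(pooled)
  p <- as_cube(pooled)
  if (!all(dim(p)[1:2] == idx$output_dim))
    stop("pooled size does not match the index map")
  y <- cpp_unpool(p, as.integer(idx$indices),
                  idx$input_dim[1], idx$input_dim[2])
  if (was_matrix) y[, , 1] else y
}

#' Dense decoding of a sparse unpooled map
#'
#' Convolves the sparse map with a trainable filter (same padding) and adds
#' the sparse map back as a residual:
#' `E' = conv(E, filter) * packet / (packet + 1) + E`. The packet scale
#' tempers the filter contribution; as it grows the filter term approaches
#' full weight, and a zero filter leaves the map unchanged.
#'
#' @param sparse numeric matrix (the unpooled map).
#' @param filter odd-sided square kernel matrix.
#' @param packet positive packet scale (default 4).
#' @return decoded matrix of the same size.
#' @export
dense_decode <- function(sparse, filter, packet = 4) {
  stopifnot(is.matrix(sparse), is.matrix(filter))
  k <- nrow(filter)
  if (k != ncol(filter) || k %% 2L == 0L)
    stop("filter must be square with odd side")
  if (packet <= 0) stop("packet must be positive")
  conv <- conv_same(sparse, matrix(as.numeric(filter), ncol = 1L), 0, k)
  conv[, , 1] * (packet / (packet + 1)) + sparse
}

#' Dilated ("hollow") convolution of a 2-D map
#'
#' Applies a square kernel whose taps are spaced `rate` pixels apart
#' (zero same-padding), enlarging the receptive field to side
#' `rate * (k - 1) + 1` while keeping the number of weights at `k^2`.
#' `rate = 1` is the standard convolution.
#'
#' @param map numeric matrix.
#' @param spec list with `weights` (odd-sided square kernel matrix) and
#'   `rate` (integer dilation factor >= 1); see [dilated_conv_spec()].
#' @return convolved matrix of the same size.
#' @export
dilated_conv <- function(map, spec) {
  w <- spec$weights; r <- spec$rate
  if (is.null(w) || is.null(r)) stop("spec needs weights and rate")
  if (r < 1) stop("dilation rate must be >= 1")
  k <- nrow(w)
  if (k != ncol(w) || k %% 2L == 0L) stop("kernel must be square, odd-sided")
  conv_same(map, matrix(as.numeric(w), ncol = 1L), 0, k, as.integer(r))[, , 1]
}

#' Specification of one dilated convolution
#'
#' @param weights odd-sided square kernel matrix.
#' @param rate integer dilation (void) factor >= 1.
#' @return list of class `dilated_conv_spec`.
#' @export
dilated_conv_spec <- function(weights, rate = 1L) {
  if (rate < 1) stop("dilation rate must be >= 1")
  structure(list(weights = weights, rate = as.integer(rate)),
            class = "dilated_conv_spec")
}

upsample_nearest <- function(map, target_dim) {
  ri <- pmin(ceiling(seq_len(target_dim[1]) / 2), nrow(map))
  ci <- pmin(ceiling(seq_len(target_dim[2]) / 2), ncol(map))
  map[ri, ci, drop = FALSE]
}

#' Top-down fusion of a resolution pyramid
#'
#' Given bottom-up feature maps ordered finest to coarsest (each side half
#' the previous, within rounding), fuses them top-down: the coarsest fused
#' map is itself, and each finer fused map is the bottom-up map plus the
#' 2x nearest-neighbor upsampling of the coarser fused map — pixel-by-pixel
#' superposition across resolutions.
#'
#' @param levels list of numeric matrices, finest first.
#' @return list of fused matrices, one per level, same sizes as the input.
#' @export
fuse_pyramid <- function(levels) {
  L <- length(levels)
  if (L == 0L) stop("empty pyramid")
  for (l in seq_len(L - 1L)) {
    expect <- dim(levels[[l]])[1:2] %/% 2L
    got <- dim(levels[[l + 1L]])[1:2]
    if (any(abs(got - expect) > 1L))
      stop("level ", l + 1L, " is not about half the size of level ", l)
  }
  fused <- vector("list", L)
  fused[[L]] <- levels[[L]]
  if (L > 1L) for (l in (L - 1L):1L) {
    fused[[l]] <- levels[[l]] + upsample_nearest(fused[[l + 1L]],
                                                 dim(levels[[l]]))
  }
  fused
}

#' Dice overlap between two binary masks
#'
#' `Sim(A, B) = 2 |A n B| / (|A| + |B|)`; two empty masks count as a
#' perfect match (similarity 1).
#'
#' @param A,B binary matrices of identical shape (any nonzero is foreground).
#' @return similarity in `[0, 1]`.
#' @export
dice_similarity <- function(A, B) {
  if (!all(dim(A) == dim(B))) stop("mask shapes differ")
  a <- A != 0; b <- B != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Per-pixel class labeling from score maps
#'
#' Applies a per-pixel softmax over the class dimension and returns the
#' argmax label; ties resolve to the lowest class id.
#'
#' @param scores `H x W x C` array of finite class scores.
#' @return list with `labels` (integer matrix, values `1..C`) and `probs`
#'   (`H x W x C` softmax probabilities summing to 1 per pixel).
#' @export
pixel_classify <- function(scores) {
  stopifnot(is.array(scores), length(dim(scores)) == 3L)
  d <- dim(scores)
  flat <- matrix(scores, nrow = d[1] * d[2], ncol = d[3])
  mx <- apply(flat, 1, max)
  e <- exp(flat - mx)
  probs <- e / rowSums(e)
  labels <- max.col(probs, ties.method = "first")
  list(labels = matrix(as.integer(labels), d[1], d[2]),
       probs = array(probs, d))
}
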