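#' Combine per-point feature maps into a normalized feature block
#'
#' Each feature is min-max normalized to `[0, 1]` (a constant feature maps
#' to 0 by convention), features are stacked as columns, and the combined
#' high-dimensional vector is their column-wise concatenation. Feature
#' weights start uniform and sum to 1.
#'
#' @param feature_maps list of numeric vectors of equal length, one value
#'   per edge point.
#' @return an object of class `feature_block`: list with `features`
#'   (`n x p` matrix), `A_v` (length `n * p` concatenation), weights `m`
#'   (length `p`, sums to 1), and slots `h_p`, `h_k`, `F` filled by
#'   [superpixel_similarity()].
#' @export
combine_features <- function(feature_maps) {
  if (!is.list(feature_maps)) feature_maps <- list(feature_maps)
  if (length(feature_maps) < 1L) stop("need at least one feature map")
  n <- length(feature_maps[[1]])
  if (any(vapply(feature_maps, length, integer(1)) != n))
    stop("feature maps must have equal lengths")
  norm1 <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) return(rep(0, length(x)))
    (x - rng[1]) / diff(rng)
  }
  feats <- vapply(feature_maps, norm1, numeric(n))
  feats <- matrix(feats, nrow = n)
  structure(list(features = feats, A_v = as.numeric(feats),
                 m = rep(1 / ncol(feats), ncol(feats)),
                 h_p = NULL, h_k = NULL, F = NULL),
            class = "feature_block")
}

#' Bounded Euclidean similarity between two feature vectors
#'
#' `h_p = 1 / (1 + d)` with `d` the Euclidean distance; equals 1 iff the
#' vectors coincide and decays monotonically with distance.
#'
#' @param a,b numeric vectors of equal length.
#' @return similarity in `(0, 1]`.
#' @export
euclidean_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("feature dimensions differ")
  1 / (1 + sqrt(sum((a - b)^2)))
}

#' Super-pixel similarity of a feature block
#'
#' Builds the pairwise similarity matrix `h_p` from the block's feature
#' rows via [euclidean_similarity()], then smooths it with the
#' row-normalized similarity-measure matrix `F` (`h_k = S h_p S'`,
#' `S = F / rowSums(F)`), and renormalizes so self-similarity is exactly 1
#' (`h_k[i,j] / sqrt(h_k[i,i] * h_k[j,j])`). With `F` the identity,
#' `h_k` equals `h_p`.
#'
#' @param block a `feature_block` from [combine_features()].
#' @param F optional similarity-measure matrix (`n x n`, nonnegative rows
#'   with positive sums); defaults to `h_p` itself.
#' @return the block with `h_p`, `h_k` and `F` filled; `h_k` is symmetric
#'   with unit diagonal and entries in `[0, 1]`.
#' @export
superpixel_similarity <- function(block, F = NULL) {
  stopifnot(inherits(block, "feature_block"))
  n <- nrow(block$features)
  h_p <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) next
    h_p[i, j] <- h_p[j, i] <- euclidean_similarity(block$features[i, ],
                                                   block$features[j, ])
  }
  if (is.null(F)) F <- h_p
  if (!all(dim(F) == c(n, n))) stop("F must be n x n")
  rs <- rowSums(F)
  if (any(rs <= 0)) stop("F rows must have positive sums")
  S <- F / rs
  h_k <- S %*% h_p %*% t(S)
  d <- sqrt(diag(h_k))
  h_k <- h_k / outer(d, d)
  h_k <- pmin(pmax(h_k, 0), 1)
  block$h_p <- h_p
  block$h_k <- h_k
  block$F <- F
  block
}

# Per-point, per-feature similarity: mean bounded similarity of point i to
# the other points under one feature alone (1 when the set has one point).
per_feature_similarity <- function(feats) {
  n <- nrow(feats); p <- ncol(feats)
  H <- matrix(1, n, p)
  if (n < 2L) return(H)
  for (f in seq_len(p)) {
    d <- abs(outer(feats[, f], feats[, f], `-`))
    s <- 1 / (1 + d)
    H[, f] <- (rowSums(s) - 1) / (n - 1)
  }
  H
}

#' Weighted feature proportion per edge point
#'
#' `G_H(i) = sum_f m_f * h_{k,f}(i)` where `h_{k,f}(i)` is point `i`'s mean
#' bounded similarity to the other points under feature `f` alone. Features
#' whose weight falls below `1 / (10 * p)` are treated as irrelevant and
#' contribute 0. Values lie in `[0, 1]`.
#'
#' @param block a `feature_block`; its weights `m` must sum to 1.
#' @param points optional `edge_points` object (recorded for provenance
#'   only; the block's features already correspond to these points).
#' @return numeric vector `G_H`, one value per point.
#' @export
weighted_feature_proportion <- function(block, points = NULL) {
  stopifnot(inherits(block, "feature_block"))
  m <- block$m
  if (abs(sum(m) - 1) > 1e-8) stop("weights m must sum to 1")
  p <- length(m)
  m_eff <- ifelse(m < 1 / (10 * p), 0, m)
  H <- per_feature_similarity(block$features)
  as.numeric(H %*% m_eff)
}

#' Link scored edge points into ordered polylines
#'
#' Per cluster, chains points by greedy nearest-neighbor traversal starting
#' from the highest-scoring point (ties broken by lowest `(row, col)`),
#' yielding one ordered pixel polyline per cluster.
#'
#' @param points an `edge_points` object with clusters assigned.
#' @param scores per-point scores (e.g. `G_H` or the `score` column);
#'   defaults to the `score` column, then to the gradient response.
#' @return list of polylines, each a matrix with columns `row`, `col`;
#'   empty input gives an empty list.
#' @export
link_edge_curve <- function(points, scores = NULL) {
  if (nrow(points) == 0L) return(list())
  if (is.null(scores)) {
    scores <- if (!is.null(points$score) && !all(is.na(points$score)))
      points$score else points$response
  }
  stopifnot(length(scores) == nrow(points))
  live <- which(!points$is_noise & !is.na(points$cluster))
  out <- list()
  for (k in sort(unique(points$cluster[live]))) {
    idx <- live[points$cluster[live] == k]
    r <- points$row[idx]; cc <- points$col[idx]; sc <- scores[idx]
    nc <- length(idx)
    visited <- logical(nc)
    ord_start <- order(-sc, r, cc)
    cur <- ord_start[1]
    path <- integer(nc)
    for (step in seq_len(nc)) {
      path[step] <- cur
      visited[cur] <- TRUE
      if (step == nc) break
      open <- which(!visited)
      d2 <- (r[open] - r[cur])^2 + (cc[open] - cc[cur])^2
      cand <- open[order(d2, r[open], cc[open])]
      cur <- cand[1]
    }
    out[[length(out) + 1L]] <- cbind(row = r[path], col = cc[path])
  }
  out
}
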