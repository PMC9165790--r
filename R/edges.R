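#' Parameters for edge-point extraction and clustering
#'
#' @param f_low,f_high dual gradient thresholds in gray-gradient units
#'   (a unit intensity step has Sobel response 1); `0 < f_low < f_high`.
#' @param f0 noise-rejection cluster-size threshold: clusters with fewer
#'   than `f0` member points are flagged as noise.
#' @param linkage_radius Chebyshev linkage distance in pixels; two candidate
#'   points belong to the same cluster when a chain of points at pairwise
#'   Chebyshev distance `<= linkage_radius` connects them.
#' @param n_clusters maximum number of clusters retained (largest first);
#'   `Inf` keeps all.
#' @return an object of class `edge_params`.
#' @export
edge_params <- function(f_low = 0.1, f_high = 0.3, f0 = 8L,
                        linkage_radius = 2L, n_clusters = Inf) {
  if (!(f_low > 0 && f_low < f_high)) stop("need 0 < f_low < f_high")
  if (f0 < 1) stop("f0 must be >= 1")
  if (linkage_radius < 1) stop("linkage_radius must be >= 1")
  structure(list(f_low = f_low, f_high = f_high, f0 = as.integer(f0),
                 linkage_radius = as.integer(linkage_radius),
                 n_clusters = n_clusters),
            class = "edge_params")
}

# Replicate-padded 3x3 Sobel gradient magnitude, normalized so a unit
# intensity step responds with 1. Replicate padding keeps constant regions
# (including frame borders) at zero response.
sobel_gradient <- function(image) {
  h <- nrow(image); w <- ncol(image)
  padded <- matrix(0, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- image
  padded[1, ] <- padded[2, ]; padded[h + 2L, ] <- padded[h + 1L, ]
  padded[, 1] <- padded[, 2]; padded[, w + 2L] <- padded[, w + 1L]
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)       # d/drow
  x <- array(padded, dim = c(h + 2L, w + 2L, 1L))
  gx <- cpp_conv_forward(x, matrix(as.numeric(kx), ncol = 1L), 0, 3L, 1L, 0L)
  gy <- cpp_conv_forward(x, matrix(as.numeric(t(kx)), ncol = 1L), 0, 3L, 1L, 0L)
  sqrt(gx[, , 1]^2 + gy[, , 1]^2) / 4
}

new_edge_points <- function(df, dim) {
  rownames(df) <- NULL
  structure(df, class = c("edge_points", "data.frame"), image_dim = dim)
}

#' Detect candidate edge points with a dual gradient threshold
#'
#' Computes the Sobel gradient magnitude and keeps every pixel whose
#' magnitude reaches `f_low`. Each point carries its raw gradient, the
#' thresholded response `max(0, gradient - f_low)`, and a `strong` flag for
#' magnitudes reaching `f_high`. Noise rejection by cluster size (`f0`)
#' happens later, in [eliminate_noise_clusters()].
#'
#' @param image numeric matrix with values in `[0, 1]`.
#' @param params an [edge_params()] object.
#' @return an `edge_points` data frame with columns `row`, `col`,
#'   `gradient`, `response`, `strong`, `cluster` (NA until clustered) and
#'   `is_noise`; rows sorted by `(row, col)`. Constant images give zero rows.
#' @export
detect_edge_candidates <- function(image, params = edge_params()) {
  stopifnot(is.matrix(image))
  g <- sobel_gradient(image)
  keep <- which(g >= params$f_low, arr.ind = TRUE)
  df <- data.frame(row = as.integer(keep[, 1]), col = as.integer(keep[, 2]))
  if (nrow(df)) {
    df$gradient <- g[keep]
    df$response <- pmax(0, df$gradient - params$f_low)
    df$strong <- df$gradient >= params$f_high
    df <- df[order(df$row, df$col), ]
  } else {
    df$gradient <- numeric(0); df$response <- numeric(0)
    df$strong <- logical(0)
  }
  df$cluster <- rep(NA_integer_, nrow(df))
  df$is_noise <- rep(FALSE, nrow(df))
  new_edge_points(df, dim(image))
}

#' Cluster edge points by Chebyshev single linkage
#'
#' Two candidate points join the same cluster when their Chebyshev (L-inf)
#' distance is at most `linkage_radius`; clusters are the connected
#' components of that relation (single-linkage agglomeration). Labels are
#' assigned in discovery order over the `(row, col)`-sorted points. The
#' search is bucketed on a grid of cell size `linkage_radius` so only
#' neighboring cells are compared.
#'
#' @param candidates an `edge_points` object from [detect_edge_candidates()].
#' @param params an [edge_params()] object.
#' @return the input with the `cluster` column filled (1-based labels).
#' @export
cluster_edge_points <- function(candidates, params = edge_params()) {
  n <- nrow(candidates)
  if (n == 0L) return(candidates)
  r <- params$linkage_radius
  ord <- order(candidates$row, candidates$col)
  pr <- candidates$row[ord]; pc <- candidates$col[ord]
  cell_r <- pr %/% r; cell_c <- pc %/% r
  key <- paste(cell_r, cell_c)
  buckets <- split(seq_len(n), key)
  parent <- seq_len(n)
  uf_find <- function(i) {            # path-halving find on local parent
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    for (dr in -1:1) for (dc in -1:1) {
      k <- paste(cell_r[i] + dr, cell_c[i] + dc)
      js <- buckets[[k]]
      if (is.null(js)) next
      js <- js[js < i]
      if (!length(js)) next
      near <- js[pmax(abs(pr[js] - pr[i]), abs(pc[js] - pc[i])) <= r]
      for (j in near) {
        ri <- uf_find(i); rj <- uf_find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), uf_find, integer(1))
  labels <- match(roots, unique(roots))   # discovery order over sorted points
  out <- candidates[ord, ]
  out$cluster <- labels
  if (is.finite(params$n_clusters)) {
    sizes <- sort(table(labels), decreasing = TRUE)
    keep <- as.integer(names(sizes))[seq_len(min(params$n_clusters,
                                                 length(sizes)))]
    drop <- !(out$cluster %in% keep)
    out$is_noise[drop] <- TRUE
    out$cluster[drop] <- NA_integer_
  }
  new_edge_points(out, attr(candidates, "image_dim"))
}

#' Flag small clusters as noise and relabel survivors
#'
#' Clusters with fewer than `f0` member points are marked `is_noise` and
#' lose their label; surviving clusters are relabeled densely, preserving
#' their original order. Raising `f0` can only shrink the surviving set.
#'
#' @param clustered an `edge_points` object with clusters assigned.
#' @param params an [edge_params()] object (`f0` is used).
#' @return the relabeled `edge_points` object.
#' @export
eliminate_noise_clusters <- function(clustered, params = edge_params()) {
  if (nrow(clustered) == 0L) return(clustered)
  sizes <- table(clustered$cluster)
  small <- as.integer(names(sizes)[sizes < params$f0])
  noise <- clustered$cluster %in% small | is.na(clustered$cluster)
  out <- clustered
  out$is_noise <- out$is_noise | noise
  out$cluster[noise] <- NA_integer_
  survivors <- unique(out$cluster[!is.na(out$cluster)])
  out$cluster <- match(out$cluster, sort(survivors))
  new_edge_points(out, attr(clustered, "image_dim"))
}

#' Per-point position scores with rank attenuation
#'
#' Scores each surviving point by its thresholded gradient response,
#' normalized against the dual-threshold midpoint and attenuated
#' exponentially by its within-cluster rank:
#' `score = min(1, 2 * response / (f_low + f_high)) * exp(-j / n_c)`,
#' where `j` is the 0-based rank of the point inside its cluster (by
#' decreasing response, ties by `(row, col)`) and `n_c` the cluster size.
#' A single-point cluster therefore scores exactly its normalized response.
#'
#' @param clustered an `edge_points` object after noise elimination.
#' @param params an [edge_params()] object (`f_low`, `f_high`).
#' @param responses optional per-point responses; defaults to the
#'   `response` column.
#' @return the object with a `score` column in `[0, 1]` (NA for noise).
#' @export
locate_edge_positions <- function(clustered, params = edge_params(),
                                  responses = NULL) {
  out <- clustered
  if (is.null(responses)) responses <- out$response
  stopifnot(length(responses) == nrow(out))
  out$score <- NA_real_
  live <- which(!out$is_noise & !is.na(out$cluster))
  base <- pmin(1, 2 * responses / (params$f_low + params$f_high))
  for (k in unique(out$cluster[live])) {
    idx <- live[out$cluster[live] == k]
    nc <- length(idx)
    rank_ord <- order(-responses[idx], out$row[idx], out$col[idx])
    j <- integer(nc); j[rank_ord] <- seq_len(nc) - 1L
    out$score[idx] <- base[idx] * exp(-j / nc)
  }
  new_edge_points(out, attr(clustered, "image_dim"))
}

#' Full edge-integration pass over one image
#'
#' Convenience chain: detect candidates, cluster, eliminate noise clusters,
#' and score positions.
#'
#' @inheritParams detect_edge_candidates
#' @return a scored `edge_points` object.
#' @export
extract_edges <- function(image, params = edge_params()) {
  pts <- detect_edge_candidates(image, params)
  pts <- cluster_edge_points(pts, params)
  pts <- eliminate_noise_clusters(pts, params)
  locate_edge_positions(pts, params)
}
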