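# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementation.

# Sliding-window 2-D convolution by explicit loops; zero padding, odd
# square kernel, optional dilation.
ref_conv2d <- function(x, kern, rate = 1L, pad_same = TRUE) {
  k <- nrow(kern)
  half <- rate * (k - 1L) / 2L
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (ki in seq_len(k)) for (kj in seq_len(k)) {
      ii <- i + rate * (ki - 1L) - half
      jj <- j + rate * (kj - 1L) - half
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w)
        acc <- acc + kern[ki, kj] * x[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# Per-window max-pool scan with row-major tie breaking.
ref_maxpool <- function(x) {
  ho <- nrow(x) %/% 2L; wo <- ncol(x) %/% 2L
  pooled <- matrix(0, ho, wo)
  idx_r <- matrix(0L, ho, wo); idx_c <- matrix(0L, ho, wo)
  for (i in seq_len(ho)) for (j in seq_len(wo)) {
    cand <- rbind(c(2 * i - 1, 2 * j - 1), c(2 * i - 1, 2 * j),
                  c(2 * i, 2 * j - 1), c(2 * i, 2 * j))
    vals <- x[cand]
    b <- which.max(vals)          # first maximum in row-major scan order
    pooled[i, j] <- vals[b]
    idx_r[i, j] <- cand[b, 1]; idx_c[i, j] <- cand[b, 2]
  }
  list(pooled = pooled, idx_r = idx_r, idx_c = idx_c)
}

# O(n^2) union-find over all point pairs under a Chebyshev radius.
ref_cluster <- function(rows, cols, radius) {
  n <- length(rows)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (max(abs(rows[i] - rows[j]), abs(cols[i] - cols[j])) <= radius) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Nearest true-edge distance for each predicted point, by full scan.
ref_nearest_dist <- function(pts, truth) {
  tc <- which(truth != 0, arr.ind = TRUE)
  apply(pts, 1, function(p)
    sqrt(min((tc[, 1] - p[1])^2 + (tc[, 2] - p[2])^2)))
}

# Small helper: easy zero-noise phantom parameters.
easy_params <- function(seed, image_size = 64L, noise = 0.02) {
  phantom_params(image_size = image_size, noise_sigma = noise,
                 lesion_fraction = 0.5, seed = seed)
}
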