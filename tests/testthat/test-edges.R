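test_that("a constant image yields no edge candidates", {
  pts <- detect_edge_candidates(matrix(0.4, 16, 16))
  expect_s3_class(pts, "edge_points")
  expect_equal(nrow(pts), 0L)
})

test_that("a vertical step is detected exactly on its two columns", {
  img <- matrix(0, 8, 8); img[, 5:8] <- 1
  pts <- detect_edge_candidates(img, edge_params(f_low = 0.1))
  expect_setequal(unique(pts$col), c(4L, 5L))
  expect_equal(nrow(pts), 16L)
  # cross-check every candidate against a brute-force Sobel scan
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  padded <- rbind(img[1, ], img, img[8, ])
  padded <- cbind(padded[, 1], padded, padded[, 8])
  gx <- ref_conv2d(padded, kx, pad_same = TRUE)[2:9, 2:9]
  gy <- ref_conv2d(padded, t(kx), pad_same = TRUE)[2:9, 2:9]
  g <- sqrt(gx^2 + gy^2) / 4
  expect_setequal(paste(pts$row, pts$col),
                  paste(which(g >= 0.1, arr.ind = TRUE)[, 1],
                        which(g >= 0.1, arr.ind = TRUE)[, 2]))
})

test_that("an isolated bright pixel raises a ring of candidates", {
  img <- matrix(0, 9, 9); img[5, 5] <- 1
  pts <- detect_edge_candidates(img, edge_params(f_low = 0.1))
  d <- pmax(abs(pts$row - 5), abs(pts$col - 5))
  expect_true(all(d == 1))
  expect_equal(nrow(pts), 8L)
})

test_that("Chebyshev linkage merges points by radius", {
  mk <- function(rows, cols) {
    df <- data.frame(row = rows, col = cols,
                     gradient = 1, response = 1, strong = TRUE,
                     cluster = NA_integer_, is_noise = FALSE)
    structure(df, class = c("edge_points", "data.frame"),
              image_dim = c(64L, 64L))
  }
  close2 <- cluster_edge_points(mk(c(5, 5), c(5, 6)),
                                edge_params(linkage_radius = 1))
  expect_equal(length(unique(close2$cluster)), 1L)
  far2 <- cluster_edge_points(mk(c(5, 5), c(5, 15)),
                              edge_params(linkage_radius = 1))
  expect_equal(length(unique(far2$cluster)), 2L)
})

test_that("clustering matches the O(n^2) union-find oracle", {
  for (sd in 1:4) {
    withr::with_seed(sd, {
      n <- 50L
      rows <- sample.int(40L, n, replace = TRUE)
      cols <- sample.int(40L, n, replace = TRUE)
    })
    df <- structure(
      data.frame(row = rows, col = cols, gradient = 1, response = 1,
                 strong = TRUE, cluster = NA_integer_, is_noise = FALSE),
      class = c("edge_points", "data.frame"), image_dim = c(40L, 40L))
    for (r in c(1L, 2L, 3L)) {
      got <- cluster_edge_points(df, edge_params(linkage_radius = r))
      want <- ref_cluster(got$row, got$col, r)
      # same partition: labels must be a bijection of oracle labels
      expect_equal(length(unique(got$cluster)), length(unique(want)))
      expect_true(all(tapply(want, got$cluster,
                             function(v) length(unique(v)) == 1L)))
    }
  }
})

test_that("noise elimination drops clusters below f0 and is monotone", {
  img <- matrix(0, 32, 32)
  img[8:24, 8] <- 1          # long line: big cluster
  img[16, 20] <- 1           # lone impulse: small clusters
  pts <- cluster_edge_points(detect_edge_candidates(img),
                             edge_params(linkage_radius = 1))
  sizes <- table(pts$cluster)
  expect_gte(length(sizes), 2L)
  kept <- eliminate_noise_clusters(pts, edge_params(f0 = max(sizes)))
  expect_equal(sum(!kept$is_noise), max(sizes))
  all_kept <- eliminate_noise_clusters(pts, edge_params(f0 = 1))
  expect_equal(sum(!all_kept$is_noise), nrow(pts))
  # survivors never increase as f0 rises
  surv <- vapply(c(1L, 3L, 6L, 12L, 40L), function(f0)
    sum(!eliminate_noise_clusters(pts, edge_params(f0 = f0))$is_noise),
    numeric(1))
  expect_true(all(diff(surv) <= 0))
  # surviving clusters are relabeled densely
  lab <- eliminate_noise_clusters(pts, edge_params(f0 = 3))$cluster
  lab <- lab[!is.na(lab)]
  expect_equal(sort(unique(lab)), seq_along(unique(lab)))
})

test_that("position scores follow the rank-attenuated response formula", {
  prm <- edge_params(f_low = 0.1, f_high = 0.3)
  mk <- function(n) structure(
    data.frame(row = seq_len(n), col = rep(1L, n), gradient = 0.3,
               response = 0.15, strong = TRUE, cluster = 1L,
               is_noise = FALSE),
    class = c("edge_points", "data.frame"), image_dim = c(64L, 64L))
  single <- locate_edge_positions(mk(1L), prm)
  expect_equal(single$score, min(1, 2 * 0.15 / 0.4))
  zero <- mk(1L); zero$response <- 0
  expect_equal(locate_edge_positions(zero, prm)$score, 0)
  five <- locate_edge_positions(mk(5L), prm)
  expect_true(all(diff(five$score) < 0))
  # direct evaluation of the stated formula
  expect_equal(five$score, pmin(1, 2 * 0.15 / 0.4) * exp(-(0:4) / 5))
  expect_true(all(five$score >= 0 & five$score <= 1))
})

test_that("cluster-size thresholding removes 1% impulse-noise clusters", {
  # impulses are kept clear of the true boundary so the test isolates the
  # noise-cluster mechanism: an isolated impulse raises a small candidate
  # ring (8 points, pairs up to 16) that f0 = 20 must reject, while the
  # long boundary chains survive untouched
  p <- phantom_params(noise_sigma = 0, n_lesions = 2L, seed = 13)
  s <- generate_phantom(p)
  img <- s$image
  near <- ctedge:::near_edge_mask(s$edge_map, 5L)
  withr::with_seed(99, {
    free <- which(!near)
    hits <- sample(free, round(0.01 * length(img)))
    img[hits] <- ifelse(runif(length(hits)) < 0.5, 0, 1)
  })
  pts <- eliminate_noise_clusters(
    cluster_edge_points(detect_edge_candidates(img), edge_params()),
    edge_params(f0 = 20))
  keep <- !pts$is_noise
  expect_gt(sum(keep), 0)
  d <- ref_nearest_dist(cbind(pts$row[keep], pts$col[keep]), s$edge_map)
  expect_gte(mean(d <= sqrt(2) + 1e-9), 0.9)
})
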