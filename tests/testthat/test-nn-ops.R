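test_that("max pooling keeps window maxima and argmax indices", {
  p <- max_pool_with_indices(matrix(c(1, 3, 2, 4), 2, 2))
  expect_equal(p$pooled, matrix(4, 1, 1))
  expect_equal(as.integer(p$indices), 4L)   # bottom-right of the window
  tie <- max_pool_with_indices(matrix(1, 4, 4))
  # ties resolve to the top-left (first in row-major window order)
  expect_equal(as.integer(tie$indices), c(1L, 3L, 9L, 11L))
  expect_error(max_pool_with_indices(matrix(1, 1, 1)), ">= 2")
})

test_that("max pooling equals the exhaustive per-window scan", {
  withr::with_seed(2, {
    for (rep in 1:5) {
      x <- matrix(rnorm(64), 8, 8)
      got <- max_pool_with_indices(x)
      want <- ref_maxpool(x)
      expect_equal(got$pooled, want$pooled)
      expect_equal(as.integer(got$indices),
                   as.integer(want$idx_r + (want$idx_c - 1L) * 8L))
    }
  })
})

test_that("unpooling restores values sparsely and round-trips", {
  p <- max_pool_with_indices(matrix(c(1, 3, 2, 4), 2, 2))
  up <- max_unpool(p$pooled, p)
  expect_equal(up, matrix(c(0, 0, 0, 4), 2, 2))
  withr::with_seed(6, {
    for (rep in 1:4) {
      x <- matrix(runif(144), 12, 12)
      pm <- max_pool_with_indices(x)
      u <- max_unpool(pm$pooled, pm)
      expect_equal(max_pool_with_indices(u)$pooled, pm$pooled)
      # exactly one nonzero per 2x2 window
      nz <- vapply(seq_len(36), function(q) {
        i <- (q - 1) %% 6; j <- (q - 1) %/% 6
        sum(u[(2 * i + 1):(2 * i + 2), (2 * j + 1):(2 * j + 2)] != 0)
      }, numeric(1))
      expect_true(all(nz <= 1))
      expect_equal(sum(u != 0), sum(pm$pooled != 0))
    }
  })
  expect_error(max_unpool(matrix(1, 3, 3), p), "does not match")
})

test_that("dense decode is a tempered residual convolution", {
  sp <- matrix(0, 6, 6); sp[2, 3] <- 2; sp[5, 5] <- -1
  expect_equal(dense_decode(sp, matrix(0, 3, 3)), sp)
  delta <- matrix(0, 3, 3); delta[2, 2] <- 1
  big <- dense_decode(sp, delta, packet = 1e12)
  expect_equal(big, 2 * sp, tolerance = 1e-9)
  withr::with_seed(9, {
    s2 <- matrix(rnorm(64), 8, 8)
    kern <- matrix(rnorm(9), 3, 3)
  })
  got <- dense_decode(s2, kern, packet = 4)
  want <- ref_conv2d(s2, kern) * 0.8 + s2
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(dense_decode(s2, matrix(0, 2, 2)), "odd")
})

test_that("dilated convolution generalizes standard convolution", {
  withr::with_seed(4, {
    x <- matrix(rnorm(100), 10, 10)
    kern <- matrix(rnorm(9), 3, 3)
  })
  expect_equal(dilated_conv(x, dilated_conv_spec(kern, 1L)),
               ref_conv2d(x, kern), tolerance = 1e-12)
  expect_equal(dilated_conv(x, dilated_conv_spec(kern, 2L)),
               ref_conv2d(x, kern, rate = 2L), tolerance = 1e-12)
  delta <- matrix(0, 3, 3); delta[2, 2] <- 1
  imp <- matrix(0, 7, 7); imp[4, 4] <- 1
  expect_equal(dilated_conv(imp, dilated_conv_spec(delta, 3L)), imp)
  expect_error(dilated_conv(x, dilated_conv_spec(kern, 1L)[c(1)]), "rate")
  expect_error(dilated_conv_spec(kern, 0L), ">= 1")
})

test_that("dilation widens the influence region without new weights", {
  withr::with_seed(7, kern <- matrix(rnorm(9), 3, 3))
  spec2 <- dilated_conv_spec(kern, 2L)
  base <- matrix(0, 11, 11)
  y0 <- dilated_conv(base, spec2)[6, 6]
  influence <- matrix(FALSE, 11, 11)
  for (i in 1:11) for (j in 1:11) {
    x <- base; x[i, j] <- 1
    influence[i, j] <- abs(dilated_conv(x, spec2)[6, 6] - y0) > 1e-12
  }
  hits <- which(influence, arr.ind = TRUE)
  expect_true(all(abs(hits[, 1] - 6) <= 2 & abs(hits[, 2] - 6) <= 2))
  expect_true(any(abs(hits[, 1] - 6) == 2))
  expect_equal(length(spec2$weights), 9L)   # parameter count constant in r
})

test_that("pyramid fusion superimposes resolutions top-down", {
  single <- fuse_pyramid(list(matrix(2, 4, 4)))
  expect_equal(single[[1]], matrix(2, 4, 4))
  two <- fuse_pyramid(list(matrix(1.5, 8, 8), matrix(0.5, 4, 4)))
  expect_equal(two[[1]], matrix(2, 8, 8))
  withr::with_seed(10, levels <- list(matrix(rnorm(64), 8, 8),
                                      matrix(rnorm(16), 4, 4),
                                      matrix(rnorm(4), 2, 2)))
  got <- fuse_pyramid(levels)
  up2 <- function(m, d) m[pmin(ceiling(seq_len(d[1]) / 2), nrow(m)),
                          pmin(ceiling(seq_len(d[2]) / 2), ncol(m)),
                          drop = FALSE]
  f3 <- levels[[3]]
  f2 <- levels[[2]] + up2(f3, c(4, 4))
  f1 <- levels[[1]] + up2(f2, c(8, 8))
  expect_equal(got, list(f1, f2, f3))
  expect_error(fuse_pyramid(list(matrix(0, 8, 8), matrix(0, 2, 2))),
               "half the size")
})

test_that("Dice similarity matches hand counts and conventions", {
  A2 <- matrix(0, 4, 4); A2[1:2, 1:2] <- 1                  # |A| = 4
  B2 <- matrix(0, 4, 4); B2[1:2, 1:3] <- 1; B2[1, 1] <- 0   # |B| = 5
  expect_equal(dice_similarity(A2, B2), 2 * 3 / (4 + 5))    # overlap 3
  expect_equal(dice_similarity(A2, A2), 1)
  disj <- matrix(0, 4, 4); disj[4, 4] <- 1
  expect_equal(dice_similarity(A2, disj), 0)
  expect_equal(dice_similarity(matrix(0, 3, 3), matrix(0, 3, 3)), 1)
  withr::with_seed(11, {
    for (i in 1:5) {
      X <- matrix(rbinom(16, 1, 0.5), 4, 4)
      Y <- matrix(rbinom(16, 1, 0.5), 4, 4)
      expect_equal(dice_similarity(X, Y), dice_similarity(Y, X))
      if (sum(X) + sum(Y) > 0)
        expect_equal(dice_similarity(X, Y),
                     2 * sum(X & Y) / (sum(X) + sum(Y)))
    }
  })
  expect_error(dice_similarity(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes")
})

test_that("pixel classification is softmax argmax with low-id ties", {
  sc <- array(0, dim = c(1, 1, 2))
  expect_equal(pixel_classify(sc)$labels[1, 1], 1L)
  sc[1, 1, ] <- c(-1, 5)
  expect_equal(pixel_classify(sc)$labels[1, 1], 2L)
  withr::with_seed(14, grid <- array(rnorm(16 * 16 * 3), dim = c(16, 16, 3)))
  out <- pixel_classify(grid)
  for (i in 1:16) for (j in 1:16)
    expect_equal(out$labels[i, j], which.max(grid[i, j, ]))
  expect_equal(apply(out$probs, c(1, 2), sum),
               matrix(1, 16, 16), tolerance = 1e-12)
})

test_that("the convolution kernel agrees with an independent library", {
  skip_if_not_installed("EBImage")
  withr::with_seed(15, {
    x <- matrix(runif(256), 16, 16)
    kern <- matrix(rnorm(9), 3, 3)
  })
  got <- dilated_conv(x, dilated_conv_spec(kern, 1L))
  # filter2 is a true convolution (flipped kernel); dilated_conv is a
  # correlation, so flip the kernel by 180 degrees before comparing
  want <- EBImage::imageData(EBImage::filter2(EBImage::Image(x),
                                              kern[3:1, 3:1],
                                              boundary = 0))
  expect_equal(got, want, tolerance = 1e-7)
})
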