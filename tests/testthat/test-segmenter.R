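test_that("segmenter construction validates its architecture", {
  expect_error(build_segmenter(depth = 1L), "depth")
  expect_error(build_segmenter(depth = 3L, channels = c(4L, 8L)), "channel")
  expect_error(build_segmenter(dilation_rates = c(1L, 0L)), "dilation")
  expect_error(build_segmenter(kernel_size = 4L), "odd")
  net <- build_segmenter(seed = 1)
  expect_s3_class(net, "ct_segmenter")
  expect_length(net$enc, 2L)
  expect_length(net$dil, 3L)
})

test_that("the output mask always has the input spatial size", {
  net <- build_segmenter(seed = 2)
  for (side in c(32L, 48L, 64L)) {
    out <- segment_image(net, matrix(runif(side^2), side, side))
    expect_equal(dim(out$mask), c(side, side))
    expect_true(all(out$mask %in% c(0L, 1L)))
    expect_equal(dim(out$probs), c(side, side, 2L))
  }
})

test_that("stacked dilations compound the receptive field to side 15", {
  withr::with_seed(3, kerns <- replicate(3, matrix(rnorm(9), 3, 3),
                                         simplify = FALSE))
  chain <- function(x) {
    x <- dilated_conv(x, dilated_conv_spec(kerns[[1]], 1L))
    x <- dilated_conv(x, dilated_conv_spec(kerns[[2]], 2L))
    dilated_conv(x, dilated_conv_spec(kerns[[3]], 4L))
  }
  base <- matrix(0, 17, 17)
  y0 <- chain(base)[9, 9]
  influence <- matrix(FALSE, 17, 17)
  for (i in 1:17) for (j in 1:17) {
    x <- base; x[i, j] <- 1
    influence[i, j] <- abs(chain(x)[9, 9] - y0) > 1e-12
  }
  hits <- which(influence, arr.ind = TRUE)
  expect_true(all(abs(hits[, 1] - 9) <= 7 & abs(hits[, 2] - 9) <= 7))
  expect_true(any(abs(hits[, 1] - 9) == 7))   # 1+2+4 = radius 7, side 15
})

test_that("analytic gradients match finite differences", {
  net <- build_segmenter(seed = 5)
  withr::with_seed(5, img <- matrix(runif(16 * 16), 16, 16))
  target <- matrix(0L, 16, 16); target[5:9, 7:11] <- 1L
  weight <- matrix(1, 16, 16); weight[target == 1L] <- 4
  loss_at <- function(n) {
    fw <- ctedge:::segmenter_forward(n, img)
    ctedge:::segmenter_loss_grad(fw$scores, target, weight)$loss
  }
  fw <- ctedge:::segmenter_forward(net, img)
  lg <- ctedge:::segmenter_loss_grad(fw$scores, target, weight)
  gr <- ctedge:::segmenter_backward(net, fw$cache, lg$grad)
  eps <- 1e-6
  cases <- list(
    list(g = gr$enc[[1]]$W, set = function(n, i, d) {
      n$enc[[1]]$W[i] <- n$enc[[1]]$W[i] + d; n }),
    list(g = gr$dil[[2]]$W, set = function(n, i, d) {
      n$dil[[2]]$W[i] <- n$dil[[2]]$W[i] + d; n }),
    list(g = gr$dec[[2]]$Wr, set = function(n, i, d) {
      n$dec[[2]]$Wr[i] <- n$dec[[2]]$Wr[i] + d; n }),
    list(g = gr$dec[[1]]$Wd, set = function(n, i, d) {
      n$dec[[1]]$Wd[i] <- n$dec[[1]]$Wd[i] + d; n }),
    list(g = gr$head$W, set = function(n, i, d) {
      n$head$W[i] <- n$head$W[i] + d; n }))
  for (cs in cases) {
    i <- which.max(abs(cs$g))
    num <- (loss_at(cs$set(net, i, eps)) -
              loss_at(cs$set(net, i, -eps))) / (2 * eps)
    expect_equal(cs$g[i], num, tolerance = 1e-4)
  }
})

test_that("training is inert at zero learning rate and seed-reproducible", {
  p <- phantom_params(image_size = 64L, lesion_fraction = 0.5, seed = 3)
  samples <- generate_phantom_set(10L, p)
  net <- build_segmenter(seed = 3)
  frozen <- train_segmenter(net, samples,
                            train_config(epochs = 2L, batch_size = 4L,
                                         learning_rate = 0, seed = 1))
  expect_equal(frozen$net$enc[[1]]$W, net$enc[[1]]$W)
  expect_equal(frozen$history$loss[1], frozen$history$loss[2],
               tolerance = 1e-12)
  cfg <- train_config(epochs = 2L, batch_size = 4L, learning_rate = 2e-3,
                      seed = 8)
  a <- train_segmenter(net, samples, cfg)
  b <- train_segmenter(net, samples, cfg)
  expect_identical(a$history, b$history)
  empty <- lapply(samples, function(s) { s$lesion_mask[] <- 0L; s })
  expect_error(train_segmenter(net, empty), "positive")
  expect_error(train_segmenter(net, samples[1:5]), "10")
})

test_that("the segmenter learns easy phantoms to high held-out Dice", {
  p <- phantom_params(image_size = 64L, lesion_fraction = 0.5,
                      noise_sigma = 0.03, seed = 42)
  samples <- generate_phantom_set(50L, p)
  hold <- generate_phantom_set(10L, phantom_params(image_size = 64L,
                                                   lesion_fraction = 0.5,
                                                   noise_sigma = 0.03,
                                                   seed = 777))
  net <- build_segmenter(seed = 1)
  fit <- train_segmenter(net, samples,
                         train_config(epochs = 12L, batch_size = 4L,
                                      learning_rate = 2e-3, seed = 1))
  m <- evaluate_segmenter(fit$net, hold)
  les <- m$per_image[m$per_image$has_lesion, ]
  expect_gte(mean(les$dice), 0.9)
})
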