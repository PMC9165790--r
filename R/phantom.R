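#' Parameters for the synthetic CT-like phantom generator
#'
#' Bundles the knobs of the phantom generator: one bright elliptical body
#' (emulating a lung/body cross-section) occupying roughly 70% of the frame,
#' plus 0 or more blob-like lesions whose boundaries are discs perturbed by
#' low-frequency radial harmonics, and additive Gaussian pixel noise.
#'
#' @param image_size side of the square image in pixels (>= 64).
#' @param n_lesions number of lesions drawn by [generate_phantom()]; in
#'   [generate_dataset()] this is the maximum per lesion-bearing image.
#' @param lesion_radius_range two pixels, min and max base lesion radius.
#' @param body_intensity,lesion_intensity,background_intensity gray levels
#'   in `[0, 1]`.
#' @param noise_sigma standard deviation of the additive Gaussian noise, in
#'   gray levels; must satisfy `0 <= noise_sigma < 0.5`.
#' @param lesion_fraction probability that a dataset image carries lesions;
#'   the default 0.2 mirrors a 1:4 tumor:normal image ratio.
#' @param seed integer seed; identical parameters and seed give bit-identical
#'   phantoms.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(image_size = 128L, n_lesions = 3L,
                           lesion_radius_range = c(6, 14),
                           body_intensity = 0.55, lesion_intensity = 0.85,
                           background_intensity = 0.05,
                           noise_sigma = 0.05, lesion_fraction = 0.2,
                           seed = 1L) {
  image_size <- as.integer(image_size)
  if (is.na(image_size) || image_size < 64L)
    stop("image_size must be >= 64")
  if (length(lesion_radius_range) != 2L ||
      any(lesion_radius_range <= 0) ||
      lesion_radius_range[1] > lesion_radius_range[2])
    stop("lesion_radius_range must be increasing positive pixels")
  ints <- c(body_intensity, lesion_intensity, background_intensity)
  if (any(ints < 0 | ints > 1)) stop("intensities must lie in [0, 1]")
  if (noise_sigma < 0 || noise_sigma >= 0.5)
    stop("noise_sigma must lie in [0, 0.5)")
  if (lesion_fraction < 0 || lesion_fraction > 1)
    stop("lesion_fraction must lie in [0, 1]")
  if (n_lesions < 0) stop("n_lesions must be >= 0")
  structure(list(image_size = image_size, n_lesions = as.integer(n_lesions),
                 lesion_radius_range = as.numeric(lesion_radius_range),
                 body_intensity = body_intensity,
                 lesion_intensity = lesion_intensity,
                 background_intensity = background_intensity,
                 noise_sigma = noise_sigma, lesion_fraction = lesion_fraction,
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# Inner 8-connected boundary: mask pixels with at least one 8-neighbour
# outside the mask (pixels beyond the frame count as outside).
mask_boundary8 <- function(mask) {
  m <- mask != 0
  h <- nrow(m); w <- ncol(m)
  padded <- matrix(FALSE, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- m
  inside <- matrix(TRUE, h, w)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    inside <- inside & padded[(2:(h + 1L)) + di, (2:(w + 1L)) + dj]
  }
  m & !inside
}

# Rasterize one blob: disc of base radius r0 at (cr, cc) whose boundary
# radius is modulated by low-frequency cosine harmonics.
rasterize_blob <- function(size, cr, cc, r0, amp, phase) {
  rmax <- r0 * (1 + sum(abs(amp))) + 1
  i0 <- max(1L, floor(cr - rmax)); i1 <- min(size, ceiling(cr + rmax))
  j0 <- max(1L, floor(cc - rmax)); j1 <- min(size, ceiling(cc + rmax))
  ii <- i0:i1; jj <- j0:j1
  dr <- outer(ii - cr, rep(1, length(jj)))
  dc <- outer(rep(1, length(ii)), jj - cc)
  theta <- atan2(dc, dr)
  rt <- r0 * (1 + Reduce(`+`, lapply(seq_along(amp), function(k) {
    amp[k] * cos((k + 1) * theta + phase[k])
  })))
  mask <- matrix(FALSE, size, size)
  mask[ii, jj] <- sqrt(dr^2 + dc^2) <= rt
  mask
}

#' Generate one seeded CT-like phantom with exact ground truth
#'
#' Draws background, a rotated body ellipse, `n_lesions` perturbed-disc
#' lesions inside the body, and additive Gaussian noise, clipped to
#' `[0, 1]`. Ground truth is the binary lesion mask and an edge map holding
#' the 8-connected inner boundary pixels of the lesions and of the body
#' ellipse.
#'
#' @param params a [phantom_params()] object.
#' @return an object of class `phantom_sample`: list with `image`,
#'   `lesion_mask`, `edge_map` (all `image_size` x `image_size`), `params`
#'   and `seed`.
#' @examples
#' p <- phantom_params(noise_sigma = 0, n_lesions = 1, seed = 7)
#' s <- generate_phantom(p)
#' sum(s$lesion_mask)
#' @export
generate_phantom <- function(params) {
  if (!inherits(params, "phantom_params")) params <- do.call(phantom_params, params)
  n <- params$image_size
  withr::with_seed(params$seed, {
    cx <- n / 2 + runif(1, -3, 3)
    cy <- n / 2 + runif(1, -3, 3)
    a <- 0.35 * n * runif(1, 0.92, 1.05)
    b <- 0.28 * n * runif(1, 0.92, 1.05)
    ang <- runif(1, 0, pi)
    ii <- matrix(seq_len(n), n, n)
    jj <- matrix(seq_len(n), n, n, byrow = TRUE)
    xr <- (ii - cx) * cos(ang) + (jj - cy) * sin(ang)
    yr <- -(ii - cx) * sin(ang) + (jj - cy) * cos(ang)
    ellipse_d <- (xr / a)^2 + (yr / b)^2
    body <- ellipse_d <= 1

    lesion_mask <- matrix(FALSE, n, n)
    if (params$n_lesions > 0L) {
      for (l in seq_len(params$n_lesions)) {
        t <- runif(1, 0, 2 * pi)
        rad <- sqrt(runif(1)) * 0.55
        cr <- cx + rad * a * cos(t) * cos(ang) - rad * b * sin(t) * sin(ang)
        cc <- cy + rad * a * cos(t) * sin(ang) + rad * b * sin(t) * cos(ang)
        r0 <- runif(1, params$lesion_radius_range[1],
                    params$lesion_radius_range[2])
        amp <- runif(3, 0, 0.06)
        phase <- runif(3, 0, 2 * pi)
        lesion_mask <- lesion_mask | rasterize_blob(n, cr, cc, r0, amp, phase)
      }
      lesion_mask <- lesion_mask & body   # lesions live inside the body
    }

    img <- matrix(params$background_intensity, n, n)
    img[body] <- params$body_intensity
    img[lesion_mask] <- params$lesion_intensity
    if (params$noise_sigma > 0)
      img <- img + matrix(rnorm(n * n, sd = params$noise_sigma), n, n)
    img <- pmin(pmax(img, 0), 1)

    edge_map <- mask_boundary8(lesion_mask) | mask_boundary8(body)
    structure(list(image = img, lesion_mask = lesion_mask * 1L,
                   edge_map = edge_map * 1L, params = params,
                   seed = params$seed),
              class = "phantom_sample")
  })
}

patch_center_window <- function(side) {
  lo <- side %/% 2L - 3L
  lo:(lo + 7L)
}

#' Generate a phantom image set and a labeled patch dataset
#'
#' Generates `n_images` phantoms with an exact lesion-bearing image count of
#' `round(lesion_fraction * n_images)` (assigned by a seeded shuffle), then
#' cuts fixed-size grayscale patches from each. A patch is labeled 1
#' ("edge-segmentation success" class) when the central 8x8 window of the
#' patch contains at least one ground-truth edge pixel, else 0. Half of the
#' sampled patches are centered on a random true edge pixel so both labels
#' occur; labels are always recomputed from ground truth.
#'
#' @param n_images number of phantoms (>= 10).
#' @param params a [phantom_params()] object; `seed` drives everything.
#' @param patch_size patch side in pixels, 28 or 50.
#' @param patches_per_image patches cut per image (default 4).
#' @return list with `patches` (class `patch_dataset`: `patches` list of
#'   matrices, `labels` 0/1, `source` data frame, `patch_size`), `samples`
#'   (list of `phantom_sample`) and `split` (per-image `"train"`/`"test"`,
#'   80/20 by image).
#' @export
generate_dataset <- function(n_images, params = phantom_params(),
                             patch_size = 28L, patches_per_image = 4L) {
  if (n_images < 10L) stop("n_images must be >= 10")
  if (!patch_size %in% c(28L, 50L)) stop("patch_size must be 28 or 50")
  n_lesion_imgs <- round(params$lesion_fraction * n_images)
  withr::with_seed(params$seed, {
    order_ids <- sample.int(n_images)
    lesion_ids <- order_ids[seq_len(n_lesion_imgs)]
    lesion_counts <- integer(n_images)
    if (n_lesion_imgs > 0L && params$n_lesions > 0L)
      lesion_counts[lesion_ids] <- sample.int(params$n_lesions,
                                              n_lesion_imgs, replace = TRUE)
    img_seeds <- (params$seed + 7919L * seq_len(n_images)) %% 2147483647L
    split <- rep("train", n_images)
    split[sample.int(n_images, max(1L, round(0.2 * n_images)))] <- "test"
  })

  samples <- vector("list", n_images)
  patches <- list(); labels <- integer(0); src <- list()
  win_off <- patch_center_window(patch_size)
  for (i in seq_len(n_images)) {
    p_i <- params
    p_i$n_lesions <- lesion_counts[i]
    p_i$seed <- as.integer(img_seeds[i])
    s <- generate_phantom(p_i)
    samples[[i]] <- s
    n <- params$image_size
    withr::with_seed(p_i$seed + 1L, {
      edge_px <- which(s$edge_map == 1L, arr.ind = TRUE)
      for (k in seq_len(patches_per_image)) {
        if (k <= patches_per_image / 2 && nrow(edge_px) > 0L) {
          ctr <- edge_px[sample.int(nrow(edge_px), 1L), ]
          r0 <- min(max(1L, ctr[1] - patch_size %/% 2L), n - patch_size + 1L)
          c0 <- min(max(1L, ctr[2] - patch_size %/% 2L), n - patch_size + 1L)
        } else {
          r0 <- sample.int(n - patch_size + 1L, 1L)
          c0 <- sample.int(n - patch_size + 1L, 1L)
        }
        rows <- r0:(r0 + patch_size - 1L)
        cols <- c0:(c0 + patch_size - 1L)
        lab <- as.integer(any(s$edge_map[r0 - 1L + win_off,
                                         c0 - 1L + win_off] == 1L))
        patches[[length(patches) + 1L]] <- s$image[rows, cols]
        labels <- c(labels, lab)
        src[[length(src) + 1L]] <- data.frame(image = i, row = r0, col = c0,
                                              seed = p_i$seed)
      }
    })
  }
  ds <- structure(list(patches = patches, labels = labels,
                       source = do.call(rbind, src),
                       patch_size = as.integer(patch_size)),
                  class = "patch_dataset")
  list(patches = ds, samples = samples, split = split)
}
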