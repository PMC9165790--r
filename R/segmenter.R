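# Encoder-decoder pixel-labeling network. The encoder alternates 3x3
# same-padded convolutions with 2x2 max pooling whose argmax indices are
# stored; the deepest stage drops its pooling and aggregates context with a
# stack of dilated convolutions instead; the decoder mirrors the encoder,
# unpooling with the stored indices and densifying each sparse map with a
# residual "dense decode" convolution; a dilated head emits two per-pixel
# class scores. Input values are centered (x - 0.5) on entry.

glorot_conv <- function(k, cin, cout) {
  lim <- sqrt(6 / (k * k * cin + k * k * cout))
  matrix(runif(k * k * cin * cout, -lim, lim), k * k * cin, cout)
}

# He (Kaiming) initialization, suited to rectifier activations.
he_conv <- function(k, cin, cout) {
  matrix(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
         k * k * cin, cout)
}

# Leaky rectifier (slope 0.1 on the negative side) keeps every unit of the
# narrow feature maps trainable.
lrelu <- function(x, alpha = 0.1) ifelse(x > 0, x, alpha * x)
dlrelu <- function(x, alpha = 0.1) ifelse(x > 0, 1, alpha)

# Min-max rescaling of an (up-sampled) filter bank to a stated range: the
# kernels keep their shape but their values are mapped linearly so the bank
# spans exactly [lo, hi].
rescale_filter_bank <- function(W, lo, hi) {
  rng <- range(W)
  if (diff(rng) == 0) return(W)
  lo + (W - rng[1]) / diff(rng) * (hi - lo)
}

#' Build the encoder-decoder segmentation network
#'
#' @param depth number of encoder stages (>= 2); stages `1..depth-1` are
#'   conv + indexed max pool, the deepest stage is a pooling-free dilated
#'   convolution stack (its dilation rates stack receptive field without
#'   adding weights).
#' @param channels feature counts per stage, length `depth`.
#' @param dilation_rates dilation factors of the deepest stage's stack.
#' @param kernel_size odd convolution kernel side (default 3).
#' @param packet packet scale of the residual dense decode (default 4).
#' @param boundary_weight loss weight for pixels within 2 px of a
#'   ground-truth edge (default 3).
#' @param lesion_weight loss weight for lesion pixels; the default `NA`
#'   lets [train_segmenter()] balance the classes by their pixel
#'   frequencies in the training set.
#' @param head_rate dilation rate of the scoring head (default 2).
#' @param seed seed for the He-normal weight initialization; the dilated
#'   bank is additionally min-max rescaled to a symmetric range.
#' @return object of class `ct_segmenter`.
#' @export
build_segmenter <- function(depth = 3L, channels = c(4L, 8L, 16L),
                            dilation_rates = c(1L, 2L, 4L),
                            kernel_size = 3L, packet = 4,
                            boundary_weight = 3, lesion_weight = NA_real_,
                            head_rate = 2L, seed = 1L) {
  if (depth < 2L) stop("depth must be >= 2")
  if (length(channels) != depth) stop("need one channel count per stage")
  if (any(dilation_rates < 1L)) stop("dilation rates must be >= 1")
  if (kernel_size %% 2L == 0L) stop("kernel size must be odd")
  k <- as.integer(kernel_size)
  withr::with_seed(seed, {
    enc <- vector("list", depth - 1L)
    cin <- 1L
    for (s in seq_len(depth - 1L)) {
      enc[[s]] <- list(W = he_conv(k, cin, channels[s]),
                       b = rep(0, channels[s]))
      cin <- channels[s]
    }
    dil <- vector("list", length(dilation_rates))
    for (t in seq_along(dilation_rates)) {
      cout <- channels[depth]
      W <- he_conv(k, cin, cout)
      lim <- max(abs(W))
      dil[[t]] <- list(W = rescale_filter_bank(W, -lim, lim),
                       b = rep(0, cout), rate = as.integer(dilation_rates[t]))
      cin <- cout
    }
    proj <- list(W = he_conv(1L, channels[depth], channels[depth - 1L]),
                 b = rep(0, channels[depth - 1L]))
    dec <- vector("list", depth - 1L)
    for (s in (depth - 1L):1L) {
      cs <- channels[s]
      dec[[s]] <- list(Wd = he_conv(k, cs, cs), bd = rep(0, cs))
      if (s > 1L) {
        dec[[s]]$Wr <- he_conv(k, cs, channels[s - 1L])
        dec[[s]]$br <- rep(0, channels[s - 1L])
      }
    }
    head <- list(W = he_conv(k, channels[1], 2L), b = rep(0, 2L),
                 rate = as.integer(head_rate))
  })
  structure(list(depth = as.integer(depth), channels = as.integer(channels),
                 dilation_rates = as.integer(dilation_rates), k = k,
                 packet = packet, boundary_weight = boundary_weight,
                 lesion_weight = lesion_weight,
                 enc = enc, dil = dil, proj = proj, dec = dec, head = head),
            class = "ct_segmenter")
}

# Gradient of max pooling wrt its pooled output: gather the sparse grads at
# the stored argmax positions back onto the pooled grid.
pool_gather <- function(g, idx_vec, out_dim) {
  C <- dim(g)[3]
  gp <- array(0, dim = c(out_dim, C))
  plane <- out_dim[1] * out_dim[2]
  for (c in seq_len(C)) {
    gs <- g[, , c]
    ids <- idx_vec[((c - 1L) * plane + 1L):(c * plane)]
    gp[, , c] <- matrix(gs[ids], out_dim[1], out_dim[2])
  }
  gp
}

segmenter_forward <- function(net, image) {
  k <- net$k; D <- net$depth
  pad <- (k - 1L) %/% 2L
  scale <- net$packet / (net$packet + 1)
  cache <- list(enc = vector("list", D - 1L),
                dil = vector("list", length(net$dil)),
                dec = vector("list", D - 1L))
  cur <- array(image - 0.5, dim = c(dim(image), 1L))
  for (s in seq_len(D - 1L)) {
    a <- cpp_conv_forward(cur, net$enc[[s]]$W, net$enc[[s]]$b, k, 1L, pad)
    z <- lrelu(a)
    p <- cpp_maxpool(z)
    cache$enc[[s]] <- list(x = cur, a = a, z = z, zdim = dim(z), p = p)
    cur <- p$pooled
  }
  for (t in seq_along(net$dil)) {
    l <- net$dil[[t]]
    a <- cpp_conv_forward(cur, l$W, l$b, k, l$rate, l$rate * pad)
    cache$dil[[t]] <- list(x = cur, a = a)
    cur <- lrelu(a)
  }
  pa <- cpp_conv_forward(cur, net$proj$W, net$proj$b, 1L, 1L, 0L)
  cache$proj <- list(x = cur, a = pa)
  cur <- lrelu(pa)
  for (s in (D - 1L):1L) {
    ec <- cache$enc[[s]]
    # index-driven unpooling plus pixel-by-pixel superposition of the
    # encoder map at the same resolution (multi-scale fusion)
    up <- cpp_unpool(cur, ec$p$indices, ec$zdim[1], ec$zdim[2]) + ec$z
    dl <- net$dec[[s]]
    cv <- cpp_conv_forward(up, dl$Wd, dl$bd, k, 1L, pad)
    dd <- cv * scale + up
    rd <- lrelu(dd)
    cache$dec[[s]] <- list(up = up, dd = dd, rd = rd)
    if (s > 1L) {
      ra <- cpp_conv_forward(rd, dl$Wr, dl$br, k, 1L, pad)
      cache$dec[[s]]$ra <- ra
      cur <- lrelu(ra)
    } else cur <- rd
  }
  scores <- cpp_conv_forward(cur, net$head$W, net$head$b, k, net$head$rate,
                             net$head$rate * pad)
  cache$head_x <- cur
  list(scores = scores, cache = cache)
}

# Pixelwise weighted cross-entropy plus a soft-Dice term on the lesion
# class; returns loss value, soft Dice, and the gradient wrt the scores.
segmenter_loss_grad <- function(scores, target, weight, dice_lambda = 1) {
  d <- dim(scores)
  flat <- matrix(scores, d[1] * d[2], 2L)
  mx <- pmax(flat[, 1], flat[, 2])
  e1 <- exp(flat[, 1] - mx); e2 <- exp(flat[, 2] - mx)
  z <- e1 + e2
  p2 <- e2 / z; p1 <- e1 / z
  y <- as.numeric(target != 0)
  w <- as.numeric(weight)
  wsum <- sum(w)
  ce <- -sum(w * log(pmax(ifelse(y == 1, p2, p1), 1e-12))) / wsum
  g2 <- w * (p2 - y) / wsum
  eps <- 1
  S <- sum(p2) + sum(y) + eps
  inter <- 2 * sum(p2 * y) + eps
  dice <- inter / S
  dLdp2 <- -dice_lambda * (2 * y * S - inter) / S^2
  g2 <- g2 + dLdp2 * p1 * p2
  gs <- array(0, dim = d)
  gs[, , 1] <- matrix(-g2, d[1], d[2])
  gs[, , 2] <- matrix(g2, d[1], d[2])
  list(loss = ce + dice_lambda * (1 - dice), dice = dice, grad = gs)
}

segmenter_backward <- function(net, cache, gscores) {
  k <- net$k; D <- net$depth
  pad <- (k - 1L) %/% 2L
  scale <- net$packet / (net$packet + 1)
  grads <- list(enc = vector("list", D - 1L),
                dil = vector("list", length(net$dil)),
                dec = vector("list", D - 1L))
  gh <- cpp_conv_backward(cache$head_x, net$head$W, gscores, k,
                          net$head$rate, net$head$rate * pad)
  grads$head <- list(W = gh$dW, b = gh$db)
  g <- gh$dx
  for (s in 1L:(D - 1L)) {
    dl <- net$dec[[s]]; dc <- cache$dec[[s]]
    if (s > 1L) {                 # g arrives after stage s's reduce conv
      g <- g * dlrelu(dc$ra)
      gr <- cpp_conv_backward(dc$rd, dl$Wr, g, k, 1L, pad)
      grads$dec[[s]]$Wr <- gr$dW; grads$dec[[s]]$br <- gr$db
      g <- gr$dx
    }
    g <- g * dlrelu(dc$dd)
    gd <- cpp_conv_backward(dc$up, dl$Wd, g * scale, k, 1L, pad)
    grads$dec[[s]]$Wd <- gd$dW; grads$dec[[s]]$bd <- gd$db
    g <- g + gd$dx                # residual path; g now at the fused map
    ec <- cache$enc[[s]]
    cache$enc[[s]]$gskip <- g     # superposition branch into the encoder
    g <- pool_gather(g, ec$p$indices, dim(ec$p$pooled)[1:2])
  }
  g <- g * dlrelu(cache$proj$a)
  gp <- cpp_conv_backward(cache$proj$x, net$proj$W, g, 1L, 1L, 0L)
  grads$proj <- list(W = gp$dW, b = gp$db)
  g <- gp$dx
  for (t in rev(seq_along(net$dil))) {
    l <- net$dil[[t]]
    g <- g * dlrelu(cache$dil[[t]]$a)
    gt <- cpp_conv_backward(cache$dil[[t]]$x, l$W, g, k, l$rate,
                            l$rate * pad)
    grads$dil[[t]] <- list(W = gt$dW, b = gt$db)
    g <- gt$dx
  }
  for (s in (D - 1L):1L) {
    ec <- cache$enc[[s]]
    g <- cpp_unpool(g, ec$p$indices, ec$zdim[1], ec$zdim[2]) + ec$gskip
    g <- g * dlrelu(ec$a)
    ge <- cpp_conv_backward(ec$x, net$enc[[s]]$W, g, k, 1L, pad)
    grads$enc[[s]] <- list(W = ge$dW, b = ge$db)
    g <- ge$dx
  }
  grads
}

# Chebyshev dilation of the edge map by `radius` pixels: pixels that close
# to a ground-truth edge receive the boundary loss weight.
near_edge_mask <- function(edge_map, radius = 2L) {
  m <- edge_map != 0
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (di in -radius:radius) {
    si <- max(1, 1 + di):min(h, h + di)
    ti <- max(1, 1 - di):min(h, h - di)
    for (dj in -radius:radius) {
      sj <- max(1, 1 + dj):min(w, w + dj)
      tj <- max(1, 1 - dj):min(w, w - dj)
      out[ti, tj] <- out[ti, tj] | m[si, sj]
    }
  }
  out
}

#' Train the segmentation network
#'
#' Minimizes a per-pixel loss: frequency-balanced two-class cross-entropy
#' (the lesion-class weight is set so lesion and background pixels carry
#' equal total mass over the training set, capped at 100; pixels within
#' 2 px of a ground-truth edge additionally carry `boundary_weight`) plus
#' `1 - softDice` on the lesion class. Parameters are updated with Adam
#' (`learning_rate` is the Adam step size) under global gradient-norm
#' clipping, which keeps training stable on the heavily imbalanced masks.
#' Deterministic given the config seed.
#'
#' @param net a `ct_segmenter` from [build_segmenter()]. When the net's
#'   `lesion_weight` is `NA` (the [build_segmenter()] default) the balanced
#'   weight is computed from the data; a finite value overrides it.
#' @param samples list of `phantom_sample` objects (>= 10) with masks.
#' @param cfg a [train_config()].
#' @param dice_lambda weight of the Dice term (default 1).
#' @param clip_norm global gradient-norm clip (default 5).
#' @return list with the trained `net` and `history` (data frame: `epoch`,
#'   `loss`, `dice`; `dice` is the mean soft Dice over lesion-bearing
#'   training images).
#' @export
train_segmenter <- function(net, samples,
                            cfg = train_config(epochs = 30L,
                                               batch_size = 4L,
                                               learning_rate = 2e-3),
                            dice_lambda = 1, clip_norm = 5) {
  stopifnot(inherits(net, "ct_segmenter"))
  if (length(samples) < 10L) stop("need at least 10 samples")
  n_pos <- sum(vapply(samples, function(s) sum(s$lesion_mask), numeric(1)))
  if (n_pos == 0) stop("no positive (lesion) pixels in any sample")
  lw <- net$lesion_weight
  if (is.na(lw)) {
    n_px <- sum(vapply(samples, function(s) length(s$lesion_mask),
                       numeric(1)))
    lw <- min(100, (n_px - n_pos) / n_pos)   # equal-mass class balance
  }
  weights <- lapply(samples, function(s) {
    w <- matrix(1, nrow(s$image), ncol(s$image))
    w[s$lesion_mask != 0] <- lw
    w + (net$boundary_weight - 1) * near_edge_mask(s$edge_map, 2L)
  })
  has_les <- vapply(samples, function(s) sum(s$lesion_mask) > 0, logical(1))
  n <- length(samples)
  adam_m <- NULL; adam_v <- NULL; step <- 0L
  beta1 <- 0.9; beta2 <- 0.999; aeps <- 1e-8
  hist <- vector("list", cfg$epochs)
  withr::with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      loss_sum <- 0; dice_sum <- 0
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        ids <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        acc <- NULL
        for (i in ids) {
          fw <- segmenter_forward(net, samples[[i]]$image)
          lg <- segmenter_loss_grad(fw$scores, samples[[i]]$lesion_mask,
                                    weights[[i]], dice_lambda)
          loss_sum <- loss_sum + lg$loss
          if (has_les[i]) dice_sum <- dice_sum + lg$dice
          g <- segmenter_backward(net, fw$cache, lg$grad)
          acc <- if (is.null(acc)) g else merge_grads(acc, g)
        }
        gvec <- unlist(acc, use.names = FALSE) / length(ids)
        gn <- sqrt(sum(gvec^2))
        if (gn > clip_norm) gvec <- gvec * (clip_norm / gn)
        if (is.null(adam_m)) { adam_m <- gvec * 0; adam_v <- gvec * 0 }
        step <- step + 1L
        adam_m <- beta1 * adam_m + (1 - beta1) * gvec
        adam_v <- beta2 * adam_v + (1 - beta2) * gvec^2
        mhat <- adam_m / (1 - beta1^step)
        vhat <- adam_v / (1 - beta2^step)
        upd <- utils::relist(mhat / (sqrt(vhat) + aeps), acc)
        net <- apply_update(net, upd, cfg$learning_rate)
      }
      hist[[ep]] <- data.frame(epoch = ep, loss = loss_sum / n,
                               dice = if (any(has_les))
                                 dice_sum / sum(has_les) else NA_real_)
    }
  })
  list(net = net, history = do.call(rbind, hist))
}

merge_grads <- function(a, b) {
  if (is.list(a)) return(Map(merge_grads, a, b))
  a + b
}

apply_update <- function(net, vel, lr) {
  for (s in seq_along(net$enc)) {
    net$enc[[s]]$W <- net$enc[[s]]$W - lr * vel$enc[[s]]$W
    net$enc[[s]]$b <- net$enc[[s]]$b - lr * vel$enc[[s]]$b
  }
  for (t in seq_along(net$dil)) {
    net$dil[[t]]$W <- net$dil[[t]]$W - lr * vel$dil[[t]]$W
    net$dil[[t]]$b <- net$dil[[t]]$b - lr * vel$dil[[t]]$b
  }
  net$proj$W <- net$proj$W - lr * vel$proj$W
  net$proj$b <- net$proj$b - lr * vel$proj$b
  for (s in seq_along(net$dec)) {
    net$dec[[s]]$Wd <- net$dec[[s]]$Wd - lr * vel$dec[[s]]$Wd
    net$dec[[s]]$bd <- net$dec[[s]]$bd - lr * vel$dec[[s]]$bd
    if (!is.null(net$dec[[s]]$Wr)) {
      net$dec[[s]]$Wr <- net$dec[[s]]$Wr - lr * vel$dec[[s]]$Wr
      net$dec[[s]]$br <- net$dec[[s]]$br - lr * vel$dec[[s]]$br
    }
  }
  net$head$W <- net$head$W - lr * vel$head$W
  net$head$b <- net$head$b - lr * vel$head$b
  net
}

#' Segment one image
#'
#' Runs the network forward, classifies each pixel independently by softmax
#' argmax, and returns the binary lesion mask together with the per-pixel
#' probabilities. The output mask has the input's spatial size.
#'
#' @param net a trained `ct_segmenter`.
#' @param image numeric matrix in `[0, 1]`.
#' @return list with `mask` (0/1 matrix), `labels` (1 = background,
#'   2 = lesion) and `probs` (`H x W x 2`).
#' @export
segment_image <- function(net, image) {
  stopifnot(inherits(net, "ct_segmenter"), is.matrix(image))
  fw <- segmenter_forward(net, image)
  cls <- pixel_classify(fw$scores)
  list(mask = (cls$labels == 2L) * 1L, labels = cls$labels,
       probs = cls$probs)
}
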