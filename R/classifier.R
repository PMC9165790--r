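#' Output side of a valid convolution
#'
#' Stride-1, no-padding convolution arithmetic: an `n`-pixel side convolved
#' with a `k`-pixel kernel yields `n - k + 1` (e.g. 28 - 5 + 1 = 24).
#'
#' @param n input side in pixels.
#' @param k kernel side in pixels, `1 <= k <= n`.
#' @return integer output side.
#' @export
conv_output_side <- function(n, k) {
  if (k < 1) stop("kernel side must be >= 1")
  if (n < k) stop("input side smaller than kernel")
  as.integer(n - k + 1)
}

#' Output side of non-overlapping 2x2 down-sampling
#'
#' Halving pool without repeated down-sampling; an odd trailing row/column
#' is dropped (`floor(n / 2)`).
#'
#' @param n input side in pixels (> 0).
#' @param scale pooling scale (fixed at 2).
#' @return integer output side.
#' @export
pool_output_side <- function(n, scale = 2L) {
  if (n <= 0) stop("input side must be positive")
  if (scale != 2L) stop("only scale 2 is supported")
  as.integer(n %/% 2L)
}

#' Fixed architecture of the patch classifier
#'
#' The two-class patch network: input, C1 (six 5x5 kernels), S1 (2x2 max
#' pool), C2 (sixteen 5x5 kernels), S2 (2x2 max pool), fully connected F1,
#' and a two-way softmax output. For a 28-pixel input the side chain is
#' 28 -> 24 -> 12 -> 8 -> 4, flattening to 16 * 4 * 4 = 256 features.
#'
#' @param input_side patch side in pixels, 28 or 50.
#' @param c1_kernels,c2_kernels kernel counts (defaults 6 and 16).
#' @param kernel_side kernel side (default 5).
#' @return list of class `network_spec` with the per-layer sides and the
#'   flattened feature length; errors if any stage degenerates.
#' @export
network_spec <- function(input_side = 28L, c1_kernels = 6L,
                         c2_kernels = 16L, kernel_side = 5L) {
  if (!input_side %in% c(28L, 50L))
    warning("canonical patch sides are 28 and 50")
  c1 <- conv_output_side(input_side, kernel_side)
  s1 <- pool_output_side(c1)
  c2 <- conv_output_side(s1, kernel_side)
  s2 <- pool_output_side(c2)
  if (s2 < 1L) stop("architecture collapses for this input side")
  structure(list(input_side = as.integer(input_side),
                 kernel_side = as.integer(kernel_side),
                 c1_kernels = as.integer(c1_kernels),
                 c2_kernels = as.integer(c2_kernels),
                 c1_side = c1, s1_side = s1, c2_side = c2, s2_side = s2,
                 flat_len = as.integer(s2 * s2 * c2_kernels),
                 n_classes = 2L),
            class = "network_spec")
}

glorot_mat <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Build the two-class patch classifier
#'
#' Instantiates the [network_spec()] architecture with seeded
#' Glorot-uniform weights. Convolutions are valid (no padding), pooling is
#' 2x2 max with stride 2, activations are ReLU, and the two-way output is a
#' softmax.
#'
#' @param spec a `network_spec`, or an input side (28 or 50).
#' @param seed integer seed for the weight initialization.
#' @return object of class `patch_classifier` holding the spec and the
#'   weight arrays (`W1`, `b1`, `W2`, `b2`, `Wf`, `bf`), introspectable by
#'   shape.
#' @export
build_classifier <- function(spec = network_spec(28L), seed = 1L) {
  if (is.numeric(spec)) spec <- network_spec(as.integer(spec))
  stopifnot(inherits(spec, "network_spec"))
  k <- spec$kernel_side
  withr::with_seed(seed, {
    net <- list(spec = spec,
                W1 = glorot_mat(k * k, spec$c1_kernels),
                b1 = rep(0, spec$c1_kernels),
                W2 = glorot_mat(k * k * spec$c1_kernels, spec$c2_kernels),
                b2 = rep(0, spec$c2_kernels),
                Wf = glorot_mat(spec$flat_len, spec$n_classes),
                bf = rep(0, spec$n_classes))
  })
  structure(net, class = "patch_classifier")
}

classifier_forward <- function(net, patch) {
  k <- net$spec$kernel_side
  x <- array(patch, dim = c(dim(patch), 1L))
  a1 <- cpp_conv_forward(x, net$W1, net$b1, k, 1L, 0L)
  z1 <- relu(a1)
  p1 <- cpp_maxpool(z1)
  a2 <- cpp_conv_forward(p1$pooled, net$W2, net$b2, k, 1L, 0L)
  z2 <- relu(a2)
  p2 <- cpp_maxpool(z2)
  flat <- as.numeric(p2$pooled)
  logits <- as.numeric(crossprod(net$Wf, flat)) + net$bf
  e <- exp(logits - max(logits))
  list(x = x, a1 = a1, z1 = z1, p1 = p1, a2 = a2, z2 = z2, p2 = p2,
       flat = flat, probs = e / sum(e))
}

classifier_backward <- function(net, fwd, label) {
  k <- net$spec$kernel_side
  target <- c(0, 0); target[label + 1L] <- 1
  dlog <- fwd$probs - target
  dWf <- fwd$flat %o% dlog
  dbf <- dlog
  dflat <- as.numeric(net$Wf %*% dlog)
  dp2 <- array(dflat, dim = dim(fwd$p2$pooled))
  dz2 <- cpp_unpool(dp2, fwd$p2$indices, nrow(fwd$z2), ncol(fwd$z2))
  da2 <- dz2 * (fwd$a2 > 0)
  g2 <- cpp_conv_backward(fwd$p1$pooled, net$W2, da2, k, 1L, 0L)
  dp1 <- g2$dx
  dz1 <- cpp_unpool(dp1, fwd$p1$indices, nrow(fwd$z1), ncol(fwd$z1))
  da1 <- dz1 * (fwd$a1 > 0)
  g1 <- cpp_conv_backward(fwd$x, net$W1, da1, k, 1L, 0L)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db, Wf = dWf, bf = dbf)
}

#' Training configuration for the networks
#'
#' @param epochs number of passes over the training set (>= 1).
#' @param batch_size samples per gradient step (>= 1).
#' @param learning_rate SGD step size.
#' @param momentum SGD momentum coefficient (default 0.9).
#' @param seed integer seed; identical configs give identical histories.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 15L, batch_size = 16L,
                         learning_rate = 0.05, momentum = 0.9, seed = 1L) {
  if (epochs < 1L) stop("epochs must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train the patch classifier
#'
#' Plain supervised training with momentum SGD on the two-class
#' cross-entropy. Logs per-epoch mean loss, recognition rate (training
#' accuracy) and error rate (`1 -` recognition rate). Deterministic given
#' the config seed.
#'
#' @param net a `patch_classifier`.
#' @param dataset a `patch_dataset` from [generate_dataset()]; must contain
#'   both classes.
#' @param cfg a [train_config()].
#' @return list with the trained `net` and `history` (data frame with
#'   columns `epoch`, `loss`, `recognition_rate`, `error_rate`).
#' @export
train_classifier <- function(net, dataset, cfg = train_config()) {
  stopifnot(inherits(net, "patch_classifier"),
            inherits(dataset, "patch_dataset"))
  labs <- dataset$labels
  if (length(unique(labs)) < 2L)
    stop("dataset must contain both classes")
  n <- length(labs)
  vel <- lapply(net[c("W1", "b1", "W2", "b2", "Wf", "bf")], function(w) w * 0)
  hist <- vector("list", cfg$epochs)
  withr::with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      loss_sum <- 0; correct <- 0
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        ids <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        acc <- NULL
        for (i in ids) {
          fwd <- classifier_forward(net, dataset$patches[[i]])
          p_true <- fwd$probs[labs[i] + 1L]
          loss_sum <- loss_sum - log(max(p_true, 1e-12))
          correct <- correct + (which.max(fwd$probs) - 1L == labs[i])
          g <- classifier_backward(net, fwd, labs[i])
          acc <- if (is.null(acc)) g else Map(`+`, acc, g)
        }
        for (nm in names(acc)) {
          vel[[nm]] <- cfg$momentum * vel[[nm]] + acc[[nm]] / length(ids)
          net[[nm]] <- net[[nm]] - cfg$learning_rate * vel[[nm]]
        }
      }
      hist[[ep]] <- data.frame(epoch = ep, loss = loss_sum / n,
                               recognition_rate = correct / n,
                               error_rate = 1 - correct / n)
    }
  })
  list(net = net, history = do.call(rbind, hist))
}

#' Classify one patch
#'
#' @param net a `patch_classifier`.
#' @param patch square matrix whose side matches the network's input side.
#' @return named numeric vector of two class probabilities (`no_edge`,
#'   `edge`) summing to 1.
#' @export
predict_patch <- function(net, patch) {
  stopifnot(inherits(net, "patch_classifier"))
  if (!is.matrix(patch) || !all(dim(patch) == net$spec$input_side))
    stop("patch must be ", net$spec$input_side, "x", net$spec$input_side)
  p <- classifier_forward(net, patch)$probs
  names(p) <- c("no_edge", "edge")
  p
}
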