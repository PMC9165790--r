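#' Repeated-instruction doubling count
#'
#' Each repeated pass doubles the execution amount of the previous one:
#' `u_n = u_{n-1} * 2` for `n >= 2`, i.e. `u_n = u_1 * 2^(n-1)`. For
#' `n < 2` the base amount is returned unchanged.
#'
#' @param u1 base execution amount (>= 1).
#' @param n pass index.
#' @return the execution amount `u_n`.
#' @export
doubling_count <- function(u1, n = 2L) {
  if (u1 < 1) stop("base amount must be >= 1")
  if (n < 2L) return(u1)
  u1 * 2^(n - 1)
}

#' Misclassification (error) rate
#'
#' @param t_q number of erroneous identifications, `0 <= t_q <= t_p`.
#' @param t_p total identifications (> 0).
#' @return `t_q / t_p`.
#' @export
error_rate <- function(t_q, t_p) {
  if (t_p <= 0) stop("total identifications must be positive")
  if (t_q < 0 || t_q > t_p) stop("need 0 <= t_q <= t_p")
  t_q / t_p
}

#' Recall over relevant (lesion/edge) pixels
#'
#' @param tp true positives retrieved.
#' @param fn relevant items missed.
#' @return `tp / (tp + fn)`; if there are no relevant items the value is
#'   undefined and `NA` is returned.
#' @export
recall_rate <- function(tp, fn) {
  if (tp < 0 || fn < 0) stop("counts must be nonnegative")
  if (tp + fn == 0) return(NA_real_)
  tp / (tp + fn)
}

#' Segmentation accuracy in percent
#'
#' `100 * J_i / J`, with `J_i` the number of pixels whose predicted label
#' agrees with the reference and `J` the total pixel count.
#'
#' @param j_i agreeing pixel count, `0 <= j_i <= j`.
#' @param j total pixel count (> 0).
#' @return accuracy in percent.
#' @export
segmentation_accuracy <- function(j_i, j) {
  if (j <= 0) stop("total pixel count must be positive")
  if (j_i < 0 || j_i > j) stop("need 0 <= j_i <= j")
  100 * j_i / j
}

#' Pixelwise agreement of two masks
#'
#' Convenience wrapper around [segmentation_accuracy()] for mask pairs.
#'
#' @param predicted,reference binary matrices of identical shape.
#' @return list with `accuracy_percent`, `accuracy_fraction`, `dice`,
#'   `recall` (lesion-pixel recall, `NA` when the reference has no lesion
#'   pixels) and the counts `j_i`, `j`.
#' @export
mask_metrics <- function(predicted, reference) {
  if (!all(dim(predicted) == dim(reference))) stop("mask shapes differ")
  p <- predicted != 0; r <- reference != 0
  j_i <- sum(p == r); j <- length(r)
  tp <- sum(p & r); fn <- sum(!p & r)
  list(accuracy_percent = segmentation_accuracy(j_i, j),
       accuracy_fraction = j_i / j,
       dice = dice_similarity(p, r),
       recall = recall_rate(tp, fn),
       j_i = j_i, j = j)
}

#' Distribution of predicted edge points around the true edge
#'
#' For each predicted edge point, computes the distance to the nearest
#' ground-truth edge pixel and summarizes how tightly the prediction hugs
#' the true boundary.
#'
#' @param predicted an `edge_points` object (noise points are ignored) or a
#'   two-column `row`/`col` matrix.
#' @param truth binary ground-truth edge map (nonempty).
#' @return list with `table` (data frame `row`, `col`, `dist` in Euclidean
#'   pixels), `mean_dist`, `median_dist` and `frac_within_1px` (Chebyshev
#'   distance <= 1, i.e. within the 8-neighborhood).
#' @export
edge_distribution_report <- function(predicted, truth) {
  tcoord <- which(truth != 0, arr.ind = TRUE)
  if (nrow(tcoord) == 0L) stop("truth edge map is empty")
  if (inherits(predicted, "edge_points")) {
    keep <- !predicted$is_noise
    pts <- cbind(predicted$row[keep], predicted$col[keep])
  } else pts <- as.matrix(predicted)[, 1:2, drop = FALSE]
  if (nrow(pts) == 0L)
    return(list(table = data.frame(row = integer(0), col = integer(0),
                                   dist = numeric(0)),
                mean_dist = NA_real_, median_dist = NA_real_,
                frac_within_1px = NA_real_, n_points = 0L))
  d_eu <- numeric(nrow(pts)); d_ch <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    dr <- tcoord[, 1] - pts[i, 1]; dc <- tcoord[, 2] - pts[i, 2]
    d_eu[i] <- sqrt(min(dr^2 + dc^2))
    d_ch[i] <- min(pmax(abs(dr), abs(dc)))
  }
  list(table = data.frame(row = pts[, 1], col = pts[, 2], dist = d_eu),
       mean_dist = mean(d_eu), median_dist = median(d_eu),
       frac_within_1px = mean(d_ch <= 1), n_points = nrow(pts))
}

#' Scaled-down segmentation benchmark over a dataset-size grid
#'
#' For each training-set size and seed, generates phantoms, trains the
#' default segmenter, and evaluates held-out accuracy, recall and Dice —
#' a desk-scale analogue of an accuracy-versus-dataset-size table.
#'
#' @param sizes training-set sizes (images).
#' @param seeds integer seeds (default `1:3`); every row of the report is
#'   reproducible from its seed.
#' @param image_size phantom side (default 64 to keep runtimes small).
#' @param epochs training epochs per run.
#' @param holdout_frac held-out fraction of each generated set.
#' @param params base [phantom_params()] (its `seed` is overridden).
#' @param cfg base [train_config()] (its `seed` is overridden).
#' @param csv_path,json_path optional output paths; written when non-NULL.
#' @return data frame with one row per size x seed: `size`, `seed`,
#'   `accuracy_percent`, `recall`, `dice`, `final_loss`.
#' @export
benchmark_suite <- function(sizes = c(20L, 60L), seeds = 1:3,
                            image_size = 64L, epochs = 8L,
                            holdout_frac = 0.25,
                            params = phantom_params(image_size = image_size),
                            cfg = train_config(epochs = epochs,
                                               batch_size = 4L,
                                               learning_rate = 2e-3),
                            csv_path = NULL, json_path = NULL) {
  rows <- list()
  for (size in sizes) {
    n_hold <- max(2L, round(holdout_frac * size))
    for (sd in seeds) {
      p <- params; p$seed <- as.integer(sd)
      all_s <- generate_phantom_set(size + n_hold, p)
      train <- all_s[seq_len(size)]
      hold <- all_s[size + seq_len(n_hold)]
      cfg_i <- cfg; cfg_i$seed <- as.integer(sd)
      net <- build_segmenter(seed = sd)
      fit <- train_segmenter(net, train, cfg_i)
      m <- evaluate_segmenter(fit$net, hold)
      rows[[length(rows) + 1L]] <-
        data.frame(size = size, seed = sd,
                   accuracy_percent = m$accuracy_percent,
                   recall = m$recall, dice = m$dice,
                   final_loss = fit$history$loss[nrow(fit$history)])
    }
  }
  report <- do.call(rbind, rows)
  if (!is.null(csv_path)) write.csv(report, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(report, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  report
}

#' Generate a plain list of phantoms with exact lesion-image counts
#'
#' Like [generate_dataset()] but returns only the `phantom_sample` list
#' (no patches); the lesion-bearing image count is exactly
#' `round(lesion_fraction * n_images)`.
#'
#' @inheritParams generate_dataset
#' @return list of `phantom_sample` objects.
#' @export
generate_phantom_set <- function(n_images, params = phantom_params()) {
  n_lesion_imgs <- round(params$lesion_fraction * n_images)
  withr::with_seed(params$seed, {
    lesion_ids <- sample.int(n_images)[seq_len(n_lesion_imgs)]
    lesion_counts <- integer(n_images)
    if (n_lesion_imgs > 0L && params$n_lesions > 0L)
      lesion_counts[lesion_ids] <- sample.int(params$n_lesions,
                                              n_lesion_imgs, replace = TRUE)
    img_seeds <- (params$seed + 7919L * seq_len(n_images)) %% 2147483647L
  })
  lapply(seq_len(n_images), function(i) {
    p_i <- params
    p_i$n_lesions <- lesion_counts[i]
    p_i$seed <- as.integer(img_seeds[i])
    generate_phantom(p_i)
  })
}

#' Evaluate a trained segmenter on held-out phantoms
#'
#' @param net a trained `ct_segmenter`.
#' @param samples list of `phantom_sample` objects.
#' @return list with mean `accuracy_percent`, `accuracy_fraction`, `dice`
#'   over all samples, `recall` (mean over lesion-bearing samples, `NA` if
#'   none), and the per-sample data frame `per_image`.
#' @export
evaluate_segmenter <- function(net, samples) {
  per <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    pred <- segment_image(net, s$image)$mask
    m <- mask_metrics(pred, s$lesion_mask)
    data.frame(image = i, accuracy_percent = m$accuracy_percent,
               accuracy_fraction = m$accuracy_fraction, dice = m$dice,
               recall = m$recall, has_lesion = sum(s$lesion_mask) > 0)
  })
  per <- do.call(rbind, per)
  rec <- per$recall[per$has_lesion]
  list(accuracy_percent = mean(per$accuracy_percent),
       accuracy_fraction = mean(per$accuracy_fraction),
       dice = mean(per$dice),
       recall = if (length(rec)) mean(rec) else NA_real_,
       per_image = per)
}
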