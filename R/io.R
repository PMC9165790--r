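#' Read a grayscale image
#'
#' Reads PNG or TIFF (8- or 16-bit); multi-channel images are averaged to
#' one gray channel.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return numeric matrix with values in `[0, 1]`.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3]),
                                               drop = FALSE], c(1, 2), mean)
  img
}

#' Write a grayscale image
#'
#' TIFF output is written at 16 bits per sample, PNG at the library's
#' 8-bit depth.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param path output path (`.png`, `.tif`, `.tiff`).
#' @export
write_gray_image <- function(image, path) {
  image <- pmin(pmax(image, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(image, path),
         tif = ,
         tiff = tiff::writeTIFF(image, path, bits.per.sample = 16L),
         stop("unsupported image format: .", ext))
  invisible(path)
}

#' Write a binary mask as 8-bit PNG (0/255)
#'
#' @param mask binary matrix.
#' @param path output `.png` path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask != 0) * 1, path)
  invisible(path)
}

#' Write an edge/mask overlay PNG
#'
#' Renders the grayscale image as RGB and paints the given points red.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param points an `edge_points` object, a binary mask, or a `row`/`col`
#'   matrix.
#' @param path output `.png` path.
#' @export
write_overlay_png <- function(image, points, path) {
  rgb <- array(rep(pmin(pmax(image, 0), 1), 3), dim = c(dim(image), 3L))
  if (inherits(points, "edge_points")) {
    keep <- !points$is_noise
    coords <- cbind(points$row[keep], points$col[keep])
  } else if (is.matrix(points) && all(dim(points) == dim(image))) {
    coords <- which(points != 0, arr.ind = TRUE)
  } else coords <- as.matrix(points)[, 1:2, drop = FALSE]
  if (nrow(coords)) {
    rgb[cbind(coords, 1L)] <- 1
    rgb[cbind(coords, 2L)] <- 0
    rgb[cbind(coords, 3L)] <- 0
  }
  png::writePNG(rgb, path)
  invisible(path)
}

#' Write an edge-point table as CSV
#'
#' Columns: `row`, `col`, `cluster`, `score` (plus `gradient`, `is_noise`).
#'
#' @param points an `edge_points` object.
#' @param path output `.csv` path.
#' @export
write_edge_csv <- function(points, path) {
  df <- as.data.frame(points)
  cols <- intersect(c("row", "col", "cluster", "score", "gradient",
                      "response", "is_noise"), names(df))
  write.csv(df[, cols], path, row.names = FALSE)
  invisible(path)
}
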