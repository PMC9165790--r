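# Checkpoints: a flat little-endian binary of doubles plus a JSON manifest
# describing the object skeleton, tensor shapes and offsets. Networks round
# trip exactly (doubles are stored at full precision).

encode_node <- function(x, registry) {
  if (is.numeric(x)) {
    i <- length(registry$tensors) + 1L
    registry$tensors[[i]] <- as.numeric(x)
    list(node = list(tensor = i,
                     dim = if (is.null(dim(x))) length(x) else dim(x),
                     integer = is.integer(x)),
         registry = registry)
  } else if (is.list(x)) {
    kids <- vector("list", length(x))
    for (j in seq_along(x)) {
      enc <- encode_node(x[[j]], registry)
      kids[[j]] <- enc$node
      registry <- enc$registry
    }
    list(node = list(list = kids, names = names(x),
                     class = class(x)[class(x) != "list"]),
         registry = registry)
  } else {
    list(node = list(value = x), registry = registry)
  }
}

decode_node <- function(node, tensors) {
  if (!is.null(node$tensor)) {
    v <- tensors[[node$tensor]]
    if (isTRUE(node$integer)) v <- as.integer(round(v))
    d <- unlist(node$dim)
    if (length(d) > 1L) dim(v) <- d
    v
  } else if (!is.null(node$list)) {
    out <- lapply(node$list, decode_node, tensors = tensors)
    if (!is.null(node$names)) names(out) <- unlist(node$names)
    cls <- unlist(node$class)
    if (length(cls)) class(out) <- cls
    out
  } else {
    unlist(node$value)
  }
}

#' Save a network checkpoint
#'
#' Writes `<prefix>.json` (shape manifest: object skeleton, tensor
#' dimensions and offsets into the flat file) and `<prefix>.bin` (all
#' tensor values as little-endian doubles, concatenated).
#'
#' @param net a `patch_classifier` or `ct_segmenter` (any list of numeric
#'   arrays works).
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
save_checkpoint <- function(net, prefix) {
  enc <- encode_node(net, list(tensors = list()))
  lens <- vapply(enc$registry$tensors, length, numeric(1))
  manifest <- list(format = "ctedge-checkpoint-1",
                   class = class(net),
                   n_tensors = length(lens),
                   lengths = lens,
                   offsets = c(0, cumsum(lens))[seq_along(lens)],
                   structure = enc$node)
  jsonlite::write_json(manifest, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  for (t in enc$registry$tensors)
    writeBin(t, con, size = 8L, endian = "little")
  invisible(prefix)
}

#' Load a network checkpoint written by [save_checkpoint()]
#'
#' @param prefix the path prefix used when saving.
#' @return the reconstructed object, bit-identical numerics included.
#' @export
load_checkpoint <- function(prefix) {
  manifest <- jsonlite::read_json(paste0(prefix, ".json"))
  if (!identical(manifest$format, "ctedge-checkpoint-1"))
    stop("not a ctedge checkpoint")
  lens <- unlist(manifest$lengths)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  tensors <- lapply(lens, function(l)
    readBin(con, "double", n = l, size = 8L, endian = "little"))
  decode_node(manifest$structure, tensors)
}
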