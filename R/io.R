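#' Read a single-channel micrograph from TIFF
#'
#' 8/16-bit integer TIFFs are converted to float without rescaling; float
#' TIFFs are read as stored. Multi-page TIFFs return a list of matrices.
#'
#' @param path TIFF file path.
#' @return numeric matrix, or list of matrices for a multi-page file.
#' @export
read_micrograph <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path, call. = FALSE)
  img <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  to_mat <- function(m) {
    fmt <- attr(m, "sample.format")
    bits <- attr(m, "bits.per.sample")
    if (length(dim(m)) == 3) {
      if (dim(m)[3] > 1) stop("multi-channel TIFF: expected one channel",
                              call. = FALSE)
      m <- m[, , 1]
    }
    if (length(dim(m)) != 2) stop("not a 2D image", call. = FALSE)
    m <- unclass(m)
    attributes(m) <- list(dim = dim(m))
    storage.mode(m) <- "double"
    # integer TIFFs are normalized to [0, 1] by the reader; undo that so
    # 8/16-bit counts come through unrescaled. 32-bit samples are floats
    # (the reader does not expose the sample format; 32-bit integer TIFFs
    # do not occur in this context) and are kept as stored.
    is_float <- (!is.null(fmt) && identical(fmt, "float")) ||
      (!is.null(bits) && bits >= 32L)
    if (!is_float) {
      if (is.null(bits)) bits <- 16L
      m <- m * (2^bits - 1)
    }
    m
  }
  imgs <- lapply(img, to_mat)
  if (length(imgs) == 1) imgs[[1]] else imgs
}

#' Write a float map as a normalized 32-bit TIFF
#'
#' TIFF float storage here is confined to \[0, 1\]; the map is rescaled to
#' that range and the original `min`/`max` are returned (and recorded in
#' pipeline manifests) so values can be recovered.
#'
#' @param map numeric matrix.
#' @param path output path.
#' @return invisibly, list with `min` and `max` of the original map.
#' @export
write_map_tiff <- function(map, path) {
  lo <- min(map)
  hi <- max(map)
  scaled <- if (hi > lo) (map - lo) / (hi - lo) else map * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  invisible(list(min = lo, max = hi))
}

#' Export phantom, fragment or trace coordinates as CSV
#'
#' Thin wrappers around the `tidy()` methods writing the standard long
#' format (`*_id`, `point_index`, `row`, `col`; 1-based pixel coordinates).
#'
#' @param x a `phantom_scene`, `fragment_set` or `fiber_traces`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_coords_csv <- function(x, path) {
  write.csv(tidy(x), path, row.names = FALSE)
  invisible(path)
}
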