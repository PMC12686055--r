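#' Read a multichannel z-stack from TIFF files
#'
#' Reads one multi-page TIFF per channel into a named list of 3D arrays with
#' axis order (z, row, col). Values are kept at their source integer scale;
#' use [normalize_brightness()] to move to the normalized \[0, 1\] brightness
#' scale that the thresholding functions expect.
#'
#' @param paths Named character vector of TIFF paths, one per channel.
#'   Unnamed inputs get channel names `ch1`, `ch2`, ...
#' @param calibration A [calibration()].
#' @param bit_depth Integer bit depth of the source data (8 or 16). If `NULL`
#'   it is taken from the file's bits-per-sample tag when present, otherwise
#'   inferred from the data range (<= 255 is treated as 8-bit).
#' @return An object of class `image_stack`: list with `channels` (named list
#'   of (z, row, col) arrays), `calibration`, `bit_depth`.
#' @export
read_stack <- function(paths, calibration, bit_depth = NULL) {
  stopifnot(is.character(paths), length(paths) >= 1L, is_calibration(calibration))
  nms <- names(paths)
  if (is.null(nms) || any(nms == "")) nms <- paste0("ch", seq_along(paths))
  channels <- list()
  depth_seen <- integer(0)
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
    pages <- tiff::readTIFF(p, all = TRUE, as.is = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    bps <- attr(pages[[1L]], "bits.per.sample")
    if (!is.null(bps)) depth_seen <- c(depth_seen, as.integer(bps))
    dims <- vapply(pages, function(m) dim(m)[1:2], integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      stop(sprintf("inconsistent slice shapes in %s", p), call. = FALSE)
    }
    arr <- array(0, dim = c(length(pages), dims[1, 1], dims[2, 1]))
    for (z in seq_along(pages)) {
      m <- pages[[z]]
      if (length(dim(m)) == 3L) m <- m[, , 1L]  # single sample per pixel expected
      arr[z, , ] <- m
    }
    channels[[nms[i]]] <- arr
  }
  shp <- vapply(channels, function(a) dim(a), integer(3))
  if (any(shp != shp[, 1])) stop("channels differ in shape", call. = FALSE)
  if (is.null(bit_depth)) {
    bit_depth <- if (length(depth_seen)) max(depth_seen)
                 else if (max(unlist(lapply(channels, max))) <= 255) 8L else 16L
  }
  structure(
    list(channels = channels, calibration = calibration,
         bit_depth = as.integer(bit_depth)),
    class = "image_stack"
  )
}

#' Write an image or mask to disk
#'
#' Writes normalized-brightness images as TIFF at a stated bit depth, and
#' boolean masks as black-and-white PNG (white = included).
#'
#' @param path Output path; `.png` writes PNG, anything else TIFF.
#' @param image Numeric matrix in \[0, 1\], or a logical matrix (mask).
#' @param bit_depth TIFF bit depth, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(path, image, bit_depth = 16L) {
  if (is.logical(image)) {
    storage <- matrix(as.numeric(image), nrow(image), ncol(image))
  } else {
    stop_if_not_image(image)
    if (min(image) < 0 || max(image) > 1) {
      stop("numeric images must be normalized to [0, 1] before writing", call. = FALSE)
    }
    storage <- image
  }
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(storage, path)
  } else {
    if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16", call. = FALSE)
    tiff::writeTIFF(storage, path, bits.per.sample = as.integer(bit_depth))
  }
  invisible(path)
}

#' Read a black-and-white PNG mask or skeleton image
#'
#' White pixels (value >= 0.5 after PNG decoding) mark the pixels to be
#' included; everything else is background.
#'
#' @param path PNG path.
#' @return Logical matrix, `TRUE` = included.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  px >= 0.5
}

#' Maximum-intensity projection of a z-stack channel
#'
#' Collapses a (z, row, col) channel to a 2D image in which each output pixel
#' is the maximum over all optical sections at that position — the standard
#' "Z project, Max Intensity" step applied per channel before cluster and
#' colocalization analysis.
#'
#' @param stack An `image_stack` from [read_stack()], or a bare
#'   (z, row, col) array.
#' @param channel Channel name (ignored for bare arrays).
#' @return Numeric matrix (row, col) at the stack's original intensity scale.
#' @export
max_intensity_projection <- function(stack, channel = NULL) {
  if (inherits(stack, "image_stack")) {
    if (is.null(channel)) channel <- names(stack$channels)[1L]
    if (!channel %in% names(stack$channels)) {
      stop(sprintf("unknown channel '%s'", channel), call. = FALSE)
    }
    arr <- stack$channels[[channel]]
  } else {
    arr <- stack
  }
  stopifnot(length(dim(arr)) == 3L, dim(arr)[1L] >= 1L)
  apply(arr, c(2L, 3L), max)
}

#' Normalize integer brightness to \[0, 1\]
#'
#' Divides by the full scale of the declared bit depth (`2^bit_depth - 1`),
#' never by the image's own maximum: the fixed brightness thresholds used in
#' cluster analysis (e.g. 0.4) are only meaningful on an image-independent
#' scale.
#'
#' @param image Numeric matrix or array of non-negative integer intensities.
#' @param bit_depth 8 or 16; alternatively supply `max_value` directly.
#' @param max_value Full-scale value; overrides `bit_depth`.
#' @return Same shape as `image`, values in \[0, 1\].
#' @export
normalize_brightness <- function(image, bit_depth = 16L, max_value = NULL) {
  if (is.null(max_value)) {
    if (!bit_depth %in% c(8L, 16L)) {
      stop("bit_depth must be 8 or 16 (or give max_value)", call. = FALSE)
    }
    max_value <- 2^bit_depth - 1
  }
  if (any(image < 0) || any(image > max_value)) {
    stop("image values exceed the declared bit depth", call. = FALSE)
  }
  image / max_value
}
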