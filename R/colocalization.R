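#' Pearson-correlation colocalization over an ROI
#'
#' Computes the Pearson correlation coefficient between the paired pixel
#' intensities of two channels (typically maximum-intensity projections),
#' restricted to an ROI mask. PCC ranges from 1 (complete colocalization)
#' through 0 (no relation) to -1 (mutual exclusion). A channel that is
#' constant within the ROI has no defined correlation and raises an error
#' rather than returning 0.
#'
#' @param chanA,chanB Numeric matrices (same shape) or vectors of paired
#'   intensities.
#' @param roi Logical mask of pixels to include; `NULL` uses every pixel.
#' @return Object of class `coloc_result`: `pcc`, `n_pixels`.
#' @examples
#' p <- make_coloc_pair(1000, rho = 0.8, seed = 7)
#' pcc(p$chanA, p$chanB)
#' @export
pcc <- function(chanA, chanB, roi = NULL) {
  if (!identical(dim(chanA), dim(chanB)) || length(chanA) != length(chanB)) {
    stop("channels must have the same shape", call. = FALSE)
  }
  if (!is.null(roi)) {
    stopifnot(is.logical(roi))
    if (!identical(dim(roi), dim(chanA))) {
      stop("ROI must match the channel shape", call. = FALSE)
    }
    a <- chanA[roi]; b <- chanB[roi]
  } else {
    a <- as.numeric(chanA); b <- as.numeric(chanB)
  }
  n <- length(a)
  if (n < 3L) stop("need at least 3 ROI pixels", call. = FALSE)
  if (sd(a) == 0 || sd(b) == 0) {
    stop("correlation undefined: a channel is constant within the ROI",
         call. = FALSE)
  }
  structure(list(pcc = cor(a, b), n_pixels = n), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> PCC = %.4f over %d pixels\n", x$pcc, x$n_pixels))
  invisible(x)
}

#' Membrane versus diffuse intensity ratio
#'
#' From a single focal plane through the middle of a dendrite, averages the
#' intensity along two 1-px lines drawn on the dendrite edges (plasma
#' membrane) and one line along the dendrite middle (diffuse protein), and
#' returns membrane mean / centre mean. Lines are sampled at the nearest
#' pixel; coordinates are rounded, no sub-pixel interpolation.
#'
#' @param plane Numeric matrix (single focal plane).
#' @param membrane_lines List of two (row, col) coordinate matrices.
#' @param center_line One (row, col) coordinate matrix.
#' @return Object of class `line_profile`: `membrane_means` (length 2),
#'   `center_mean`, `ratio`.
#' @export
membrane_diffuse_ratio <- function(plane, membrane_lines, center_line) {
  stop_if_not_image(plane, "plane")
  stopifnot(is.list(membrane_lines), length(membrane_lines) == 2L)
  mm <- vapply(membrane_lines, function(l) line_mean(plane, l), numeric(1))
  cm <- line_mean(plane, center_line)
  if (cm == 0) stop("centre-line mean is zero", call. = FALSE)
  structure(
    list(membrane_means = mm, center_mean = cm, ratio = mean(mm) / cm),
    class = "line_profile"
  )
}

line_mean <- function(plane, coords) {
  stopifnot(is.matrix(coords), ncol(coords) == 2L, nrow(coords) >= 1L)
  r <- round(coords[, 1L]); cl <- round(coords[, 2L])
  if (any(r < 1L | r > nrow(plane) | cl < 1L | cl > ncol(plane))) {
    stop("line coordinates fall outside the image", call. = FALSE)
  }
  mean(plane[rc_to_idx(as.integer(r), as.integer(cl), nrow(plane))])
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> membrane %.4f / centre %.4f = ratio %.4f\n",
              mean(x$membrane_means), x$center_mean, x$ratio))
  invisible(x)
}

#' Expressing / non-expressing intensity ratio
#'
#' Ratio of mean intensity in an ROI over cells expressing a construct to
#' the mean intensity in an ROI over untransfected cells in the same image
#' (e.g. phalloidin staining in transfected vs neighbouring cells). A ratio
#' of 1 means the construct did not change the measured signal.
#'
#' @param image Numeric matrix.
#' @param roi_expressing,roi_nonexpressing Logical masks, non-empty,
#'   same shape as `image`.
#' @return Single numeric ratio (expressing / non-expressing).
#' @export
expression_ratio <- function(image, roi_expressing, roi_nonexpressing) {
  stop_if_not_image(image)
  stopifnot(is.logical(roi_expressing), is.logical(roi_nonexpressing),
            identical(dim(roi_expressing), dim(image)),
            identical(dim(roi_nonexpressing), dim(image)))
  if (!any(roi_expressing) || !any(roi_nonexpressing)) {
    stop("both ROIs must be non-empty", call. = FALSE)
  }
  denom <- mean(image[roi_nonexpressing])
  if (denom == 0) stop("non-expressing ROI mean is zero", call. = FALSE)
  mean(image[roi_expressing]) / denom
}
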