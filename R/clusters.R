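#' Cluster-analysis parameters
#'
#' Bundles the adjustable parameters of the brightness-cluster pipeline.
#' Defaults follow the values used throughout this workflow: a global
#' minimum-brightness threshold of 0.4 on the normalized scale, an adaptive
#' moving rectangular window with half-width and half-height 10 px, a
#' Gaussian smoothing "brush" of size 51 px with sigma 0.8 px, and
#' 8-connectivity for region labeling. The adaptive offset is
#' study-specific (selected by the analyst per experimental setup); 0.1 is
#' a neutral default.
#'
#' @param mode `"global"` or `"adaptive"`.
#' @param global_threshold Minimum normalized brightness for global mode,
#'   in \[0, 1\].
#' @param window_half Half-width/height of the adaptive window, px (>= 1).
#' @param offset Adaptive thresholding offset above the window mean,
#'   normalized brightness units.
#' @param gauss_size Side of the square Gaussian kernel, px (odd).
#' @param gauss_sigma Gaussian sigma, px (> 0).
#' @param connectivity 4 or 8 (pixel neighbourhood for labeling).
#' @param require_raw_bright If `TRUE`, a labeled region is kept only when at
#'   least one of its *unsmoothed* pixels also satisfies the brightness
#'   criterion; by default regions are defined on the smoothed image alone.
#' @return Object of class `cluster_params`.
#' @export
cluster_params <- function(mode = c("adaptive", "global"),
                           global_threshold = 0.4,
                           window_half = 10L,
                           offset = 0.1,
                           gauss_size = 51L,
                           gauss_sigma = 0.8,
                           connectivity = 8L,
                           require_raw_bright = FALSE) {
  mode <- match.arg(mode)
  stopifnot(global_threshold >= 0, global_threshold <= 1,
            window_half >= 1, gauss_sigma > 0,
            connectivity %in% c(4L, 8L))
  if (gauss_size %% 2L == 0L) stop("`gauss_size` must be odd", call. = FALSE)
  structure(
    list(mode = mode, global_threshold = global_threshold,
         window_half = as.integer(window_half), offset = offset,
         gauss_size = as.integer(gauss_size), gauss_sigma = gauss_sigma,
         connectivity = as.integer(connectivity),
         require_raw_bright = isTRUE(require_raw_bright)),
    class = "cluster_params"
  )
}

#' Gaussian smoothing with an explicit square kernel
#'
#' Convolves the image with a normalized 2D Gaussian kernel of side
#' `gauss_size` and standard deviation `gauss_sigma`, evaluated on the integer
#' pixel grid and renormalized to sum 1 after truncation. Borders are handled
#' by edge replication, so a constant image is returned unchanged.
#'
#' @param image Numeric matrix, normalized brightness.
#' @param gauss_size Kernel side in px; must be odd.
#' @param gauss_sigma Sigma in px.
#' @return Smoothed matrix, same shape.
#' @export
gaussian_smooth <- function(image, gauss_size = 51L, gauss_sigma = 0.8) {
  stop_if_not_image(image)
  if (gauss_size %% 2L == 0L) stop("`gauss_size` must be odd", call. = FALSE)
  stopifnot(gauss_sigma > 0)
  k <- gaussian_kernel(gauss_size, gauss_sigma)
  # replicate-pad by the kernel half-width so the convolution sees edge
  # values, then crop; also lets the kernel exceed the image size
  h <- (gauss_size - 1L) / 2L
  ri <- c(rep(1L, h), seq_len(nrow(image)), rep(nrow(image), h))
  ci <- c(rep(1L, h), seq_len(ncol(image)), rep(ncol(image), h))
  pad <- image[ri, ci]
  out <- EBImage::filter2(pad, k, boundary = "circular")
  matrix(as.numeric(out), nrow(pad), ncol(pad))[h + seq_len(nrow(image)),
                                                h + seq_len(ncol(image))]
}

gaussian_kernel <- function(size, sigma) {
  h <- (size - 1L) / 2
  g <- exp(-(seq(-h, h)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Global brightness threshold mask
#'
#' Marks every pixel whose normalized brightness is at least the threshold —
#' the same minimum brightness requirement applied to all parts of the image.
#' The comparison is inclusive (`>=`), so the threshold is a minimum.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param global_threshold Minimum brightness, default 0.4.
#' @return Logical matrix.
#' @export
global_threshold_mask <- function(image, global_threshold = 0.4) {
  stop_if_not_image(image)
  image >= global_threshold
}

#' Adaptive (moving-window) threshold mask
#'
#' Marks a pixel as bright when its value is at least the mean of the
#' surrounding rectangular window plus an offset:
#' `value >= mean(window) + offset`. The window is the
#' `(2 * window_half + 1)^2` square centred on the pixel, clipped at image
#' borders (the mean is taken over the available pixels; the centre pixel is
#' included). Because the criterion is relative to the local mean, the mask
#' is invariant under adding a constant to the whole image — the property
#' that makes it robust to uneven illumination where a global threshold is
#' not.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param window_half Window half-width/height, px (>= 1). Default 10.
#' @param offset Offset above the window mean. Default 0.1.
#' @return Logical matrix.
#' @export
adaptive_threshold_mask <- function(image, window_half = 10L, offset = 0.1) {
  stop_if_not_image(image)
  stopifnot(window_half >= 1)
  image >= window_mean(image, as.integer(window_half)) + offset
}

# Clipped moving-window mean via a summed-area table.
window_mean <- function(image, h) {
  nr <- nrow(image); nc <- ncol(image)
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- t(apply(apply(image, 2L, cumsum), 1L, cumsum))
  r1 <- pmax(seq_len(nr) - h, 1L); r2 <- pmin(seq_len(nr) + h, nr)
  c1 <- pmax(seq_len(nc) - h, 1L); c2 <- pmin(seq_len(nc) + h, nc)
  sums <- S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  counts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sums / counts
}

#' Label brightness clusters inside an observation path
#'
#' Takes a bright-pixel mask, restricts it to the ROI, labels connected
#' components, and reports per-cluster and total areas in pixels and square
#' micrometres, plus total cluster area per micrometre of dendrite.
#'
#' @param mask Logical matrix of bright pixels.
#' @param roi An [grow_skeleton()] `observation_path` (or a plain logical
#'   matrix, in which case `length_um` must be given).
#' @param connectivity 4 or 8.
#' @param length_um Dendrite length in um; taken from `roi` when it is an
#'   observation path.
#' @param calibration A [calibration()]; taken from the ROI's skeleton when
#'   omitted.
#' @return Object of class `cluster_result`: `labels` (integer matrix, 0 =
#'   background), `areas_px`, `areas_um2`, `n_clusters`, `total_area_um2`,
#'   `area_per_length` (um^2 per um), `length_um`.
#' @export
label_clusters <- function(mask, roi, connectivity = 8L,
                           length_um = NULL, calibration = NULL) {
  stopifnot(is.logical(mask), connectivity %in% c(4L, 8L))
  if (inherits(roi, "observation_path")) {
    roi_mask <- roi$mask
    if (is.null(length_um)) length_um <- roi$length_um
    if (is.null(calibration)) calibration <- roi$skeleton$calibration
  } else {
    stopifnot(is.logical(roi))
    roi_mask <- roi
  }
  if (!identical(dim(mask), dim(roi_mask))) {
    stop("mask and ROI must have the same shape", call. = FALSE)
  }
  if (is.null(calibration)) stop("`calibration` is required", call. = FALSE)
  if (is.null(length_um) || length_um <= 0) {
    stop("dendrite length must be positive", call. = FALSE)
  }
  labels <- label_components(mask & roi_mask, connectivity)
  areas_px <- if (max(labels) > 0L) tabulate(labels[labels > 0L]) else integer(0)
  px_area_um2 <- calibration$pixel_size_um^2
  areas_um2 <- areas_px * px_area_um2
  total <- sum(areas_um2)
  structure(
    list(labels = labels,
         areas_px = areas_px,
         areas_um2 = areas_um2,
         n_clusters = length(areas_px),
         total_area_um2 = total,
         area_per_length = total / length_um,
         length_um = length_um),
    class = "cluster_result"
  )
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d clusters, total %.4f um^2, %.4f um^2/um over %.2f um\n",
              x$n_clusters, x$total_area_um2, x$area_per_length, x$length_um))
  invisible(x)
}

# Connected-component labeling with configurable 4/8 connectivity.
# Components are numbered in raster (column-major) order of first occurrence.
label_components <- function(m, connectivity = 8L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  idx <- which(m)
  n <- length(idx)
  if (n == 0L) return(out)
  pos <- integer(length(m))
  pos[idx] <- seq_len(n)
  rc <- idx_to_rc(idx, nr)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  edges <- vector("list", length(offs))
  for (i in seq_along(offs)) {
    o <- offs[[i]]
    r2 <- rc[, 1L] + o[1L]; c2 <- rc[, 2L] + o[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- rc_to_idx(r2[ok], c2[ok], nr)
    hit <- pos[nb] > 0L
    edges[[i]] <- cbind(seq_len(n)[ok][hit], pos[nb][hit])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(el) && nrow(el) > 0L) g <- igraph::add_edges(g, t(el))
  memb <- igraph::components(g)$membership
  # renumber by first pixel occurrence so labels are deterministic
  relab <- integer(max(memb))
  nxt <- 0L
  lab <- integer(n)
  for (i in seq_len(n)) {
    mi <- memb[i]
    if (relab[mi] == 0L) { nxt <- nxt + 1L; relab[mi] <- nxt }
    lab[i] <- relab[mi]
  }
  out[idx] <- lab
  out
}

#' Run the brightness-cluster pipeline on a projection
#'
#' Full pipeline: Gaussian smoothing of the normalized maximum-intensity
#' projection, then either the global minimum-brightness threshold or the
#' adaptive moving-window criterion applied to the smoothed image, then
#' connected-component labeling restricted to the observation path. The
#' smoothed image defines the cluster regions (the smoothing agglomerates
#' separate but closely positioned bright pixels); set
#' `require_raw_bright = TRUE` in the parameters to additionally demand one
#' raw bright pixel per region.
#'
#' @param projection Numeric matrix in \[0, 1\] (normalized MIP).
#' @param roi An `observation_path`.
#' @param params A [cluster_params()].
#' @return A `cluster_result`; the smoothed image and bright-pixel mask are
#'   attached as attributes `smoothed` and `mask`.
#' @export
run_cluster_pipeline <- function(projection, roi, params = cluster_params()) {
  stop_if_not_image(projection, "projection")
  stopifnot(inherits(params, "cluster_params"))
  sm <- gaussian_smooth(projection, params$gauss_size, params$gauss_sigma)
  mask <- switch(params$mode,
    global = global_threshold_mask(sm, params$global_threshold),
    adaptive = adaptive_threshold_mask(sm, params$window_half, params$offset)
  )
  res <- label_clusters(mask, roi, params$connectivity)
  if (params$require_raw_bright && res$n_clusters > 0L) {
    raw_ok <- switch(params$mode,
      global = global_threshold_mask(projection, params$global_threshold),
      adaptive = adaptive_threshold_mask(projection, params$window_half, params$offset)
    )
    keep <- vapply(seq_len(res$n_clusters),
                   function(k) any(raw_ok[res$labels == k]), logical(1))
    drop <- which(!keep)
    if (length(drop)) {
      lab <- res$labels
      lab[lab %in% drop] <- 0L
      res <- label_clusters(lab > 0L, roi, params$connectivity)
    }
  }
  attr(res, "smoothed") <- sm
  attr(res, "mask") <- mask
  res
}

#' Per-cluster summary table
#'
#' @param result A `cluster_result`.
#' @return A tibble with `cluster_id`, `area_px`, `area_um2`, `centroid_row`,
#'   `centroid_col`.
#' @export
cluster_table <- function(result) {
  stopifnot(inherits(result, "cluster_result"))
  if (result$n_clusters == 0L) {
    return(tibble::tibble(cluster_id = integer(0), area_px = integer(0),
                          area_um2 = numeric(0), centroid_row = numeric(0),
                          centroid_col = numeric(0)))
  }
  idx <- which(result$labels > 0L)
  lab <- result$labels[idx]
  rc <- idx_to_rc(idx, nrow(result$labels))
  tibble::tibble(
    cluster_id = seq_len(result$n_clusters),
    area_px = result$areas_px,
    area_um2 = result$areas_um2,
    centroid_row = as.numeric(tapply(rc[, 1L], lab, mean)),
    centroid_col = as.numeric(tapply(rc[, 2L], lab, mean))
  )
}

#' Normalize a cluster-area time series to its pre-treatment baseline
#'
#' For live-imaging time series, each frame's total cluster area is divided
#' by the mean of the `n_baseline` frames immediately preceding the treatment
#' frame, so the treatment effect is expressed relative to a within-neuron
#' baseline of 1.
#'
#' @param total_areas Numeric vector of per-frame total cluster areas (um^2).
#' @param treatment_frame Index of the first post-treatment frame; defaults
#'   to `n_baseline + 1` (series starts with the baseline frames).
#' @param n_baseline Number of baseline frames, default 4.
#' @return Numeric vector of relative values, same length.
#' @export
normalize_timeseries <- function(total_areas, treatment_frame = n_baseline + 1L,
                                 n_baseline = 4L) {
  stopifnot(is.numeric(total_areas), n_baseline >= 1L)
  if (treatment_frame <= n_baseline || treatment_frame > length(total_areas) + 1L) {
    stop(sprintf("need %d baseline frames before the treatment frame", n_baseline),
         call. = FALSE)
  }
  base <- mean(total_areas[(treatment_frame - n_baseline):(treatment_frame - 1L)])
  if (base == 0) stop("baseline mean is zero", call. = FALSE)
  total_areas / base
}
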