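#' Skeleton curve
#'
#' A hand-drawn 1-pixel-wide dendrite trace on a black background. The curve
#' is stored as a logical matrix; [skeleton_length()] measures its physical
#' length and [grow_skeleton()] widens it into an "observation path" ROI.
#'
#' @param pixels Logical matrix, `TRUE` on the curve; or an integer matrix of
#'   (row, col) coordinates together with `shape`.
#' @param calibration A [calibration()].
#' @param shape Image shape `c(rows, cols)` when `pixels` is a coordinate
#'   matrix.
#' @return Object of class `skeleton_curve` with fields `pixels` (logical
#'   matrix) and `calibration`.
#' @export
skeleton_curve <- function(pixels, calibration, shape = NULL) {
  stopifnot(is_calibration(calibration))
  if (!is.logical(pixels)) {
    stopifnot(is.matrix(pixels), ncol(pixels) == 2L, !is.null(shape))
    m <- matrix(FALSE, shape[1L], shape[2L])
    m[rc_to_idx(pixels[, 1L], pixels[, 2L], shape[1L])] <- TRUE
    pixels <- m
  }
  if (!any(pixels)) stop("skeleton is empty", call. = FALSE)
  structure(list(pixels = pixels, calibration = calibration),
            class = "skeleton_curve")
}

#' Grow a skeleton curve into an observation-path ROI mask
#'
#' Widens a 1-px skeleton curve to both sides by Euclidean disk dilation:
#' the mask contains every pixel whose distance to the nearest skeleton pixel
#' is at most `radius_px`. Growing a straight curve by the default 95 px
#' yields the 191-pixel-wide observation path used for cluster analysis
#' (95 px to each side at 5/95 um/px is 5 um). The mask is clipped at image
#' borders; partial paths are allowed.
#'
#' @param skeleton A [skeleton_curve()].
#' @param radius_px Grow radius in pixels (>= 0). Default 95.
#' @return Object of class `observation_path`: `mask` (logical),
#'   `grow_radius_px`, `skeleton`, `length_um` (from [skeleton_length()]).
#' @examples
#' cal <- calibration(5 / 95)
#' sk <- matrix(FALSE, 21, 21); sk[11, ] <- TRUE
#' path <- grow_skeleton(skeleton_curve(sk, cal), radius_px = 5)
#' sum(path$mask[, 11])  # 11 = 2 * 5 + 1
#' @export
grow_skeleton <- function(skeleton, radius_px = 95L) {
  stopifnot(inherits(skeleton, "skeleton_curve"))
  if (!is.numeric(radius_px) || length(radius_px) != 1L || radius_px < 0) {
    stop("`radius_px` must be a single non-negative number", call. = FALSE)
  }
  sk <- skeleton$pixels
  mask <- if (radius_px == 0) {
    sk
  } else {
    # distance of every pixel to the nearest skeleton pixel
    d <- EBImage::distmap(matrix(as.numeric(!sk), nrow(sk), ncol(sk)))
    matrix(as.numeric(d) <= radius_px, nrow(sk), ncol(sk))
  }
  structure(
    list(mask = mask,
         grow_radius_px = radius_px,
         skeleton = skeleton,
         length_um = skeleton_length(skeleton)),
    class = "observation_path"
  )
}

#' @export
print.observation_path <- function(x, ...) {
  cat(sprintf("<observation_path> grow radius %g px, mask area %d px, dendrite length %.3f um\n",
              x$grow_radius_px, sum(x$mask), x$length_um))
  invisible(x)
}

#' Physical length of a skeleton curve
#'
#' Traces the curve through its 8-connected pixel graph and sums step
#' lengths: 1 px for orthogonal steps, sqrt(2) px for diagonal steps,
#' converted to micrometres by the pixel size. Branched skeletons sum all
#' branches. The tracing is implemented as the minimum spanning tree of the
#' pixel adjacency graph, which walks every pixel once without double-counting
#' the diagonal shortcut edges that 8-adjacency adds at corners; each loop
#' is counted once (its closing step is not traversed twice).
#'
#' @param skeleton A [skeleton_curve()].
#' @return Length in micrometres (0 for a single pixel).
#' @export
skeleton_length <- function(skeleton) {
  stopifnot(inherits(skeleton, "skeleton_curve"))
  skeleton_length_px(skeleton$pixels) * skeleton$calibration$pixel_size_um
}

# Branch length in pixel units from the MST of the 8-adjacency graph.
skeleton_length_px <- function(sk) {
  idx <- which(sk)
  n <- length(idx)
  if (n == 0L) stop("skeleton is empty", call. = FALSE)
  if (n == 1L) return(0)
  nr <- nrow(sk)
  pos <- integer(length(sk))
  pos[idx] <- seq_len(n)
  rc <- idx_to_rc(idx, nr)
  edges <- NULL
  w <- NULL
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (o in offs) {
    r2 <- rc[, 1L] + o[1L]; c2 <- rc[, 2L] + o[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(sk)
    nb <- rc_to_idx(r2[ok], c2[ok], nr)
    hit <- pos[nb] > 0L
    from <- seq_len(n)[ok][hit]
    to <- pos[nb][hit]
    edges <- rbind(edges, cbind(from, to))
    w <- c(w, rep(sqrt(sum(o^2)), sum(hit)))
  }
  if (is.null(edges) || nrow(edges) == 0L) return(0)  # isolated pixels only
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::E(g)$weight <- w
  mst <- igraph::mst(g)
  sum(igraph::E(mst)$weight)
}
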