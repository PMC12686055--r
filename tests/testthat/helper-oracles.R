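# Independent brute-force oracles used across the suite. These deliberately
# use naive loops so they share no code path with the implementation.

# Clipped moving-window mean by direct per-pixel looping.
bf_window_mean <- function(img, h) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rr <- max(1, i - h):min(nr, i + h)
    cc <- max(1, j - h):min(nc, j + h)
    out[i, j] <- mean(img[rr, cc])
  }
  out
}

# Recursive-free flood fill labeling with an explicit stack.
bf_flood_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- if (connectivity == 8) {
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (mask[i, j] && lab[i, j] == 0L) {
      nxt <- nxt + 1L
      stack <- list(c(i, j))
      lab[i, j] <- nxt
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        for (k in seq_len(nrow(offs))) {
          r <- p[1] + offs[k, 1]; cl <- p[2] + offs[k, 2]
          if (r >= 1 && r <= nr && cl >= 1 && cl <= nc &&
              mask[r, cl] && lab[r, cl] == 0L) {
            lab[r, cl] <- nxt
            stack[[length(stack) + 1L]] <- c(r, cl)
          }
        }
      }
    }
  }
  lab
}

# Distance of every pixel to the nearest TRUE pixel, by direct minimization.
bf_distance_to <- function(pts_mask) {
  pts <- which(pts_mask, arr.ind = TRUE)
  nr <- nrow(pts_mask); nc <- ncol(pts_mask)
  out <- matrix(Inf, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    out[i, j] <- sqrt(min((pts[, 1] - i)^2 + (pts[, 2] - j)^2))
  }
  out
}

# Exact Mann-Whitney p by enumerating every split of the pooled sample into
# the two groups (independent of the package's combn-over-ranks route: works
# on the raw values and counts pairwise wins directly).
bf_mann_whitney <- function(a, b, alternative = "two.sided") {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(x, y) {
    u <- 0
    for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
  }
  u_obs <- u_of(a, b)
  splits <- utils::combn(length(pooled), n1)
  us <- apply(splits, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  switch(alternative,
         less = p_le, greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

# Straight horizontal skeleton in an image of the given shape.
horizontal_skeleton <- function(nr, nc, row = nr %/% 2L,
                                cal = calibration(5 / 95)) {
  m <- matrix(FALSE, nr, nc)
  m[row, ] <- TRUE
  skeleton_curve(m, cal)
}

full_frame_roi <- function(nr, nc, cal = calibration(5 / 95)) {
  grow_skeleton(horizontal_skeleton(nr, nc, cal = cal), radius_px = nr + nc)
}
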