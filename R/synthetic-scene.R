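#' Synthetic-scene parameters
#'
#' Parameters for the seeded puncta-image generator. Puncta are isotropic
#' Gaussian spots truncated at 3 sigma; the "true" area of a punctum is the
#' set of pixels above its half-maximum, and `punctum_radius_px` is the
#' half-maximum radius (so sigma = radius / sqrt(2 ln 2)). Backgrounds can be
#' flat, a linear left-to-right gradient (the case that defeats a global
#' threshold while the adaptive criterion still works), or smooth
#' low-frequency variation. Noise is additive Gaussian, clipped to \[0, 1\].
#'
#' @param image_shape `c(rows, cols)` in px.
#' @param n_puncta Number of puncta (>= 0).
#' @param punctum_radius_px Half-maximum radius, px.
#' @param punctum_peak Peak brightness added above background, in \[0, 1\].
#' @param background `"flat"`, `"linear-gradient"` or `"low-frequency"`.
#' @param background_level Flat background brightness.
#' @param gradient_range Brightness range `c(lo, hi)` spanned left to right
#'   by the gradient background (also the amplitude range of the
#'   low-frequency background).
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param calibration A [calibration()].
#' @return Object of class `scene_params`.
#' @export
scene_params <- function(image_shape = c(256L, 256L),
                         n_puncta = 12L,
                         punctum_radius_px = 4,
                         punctum_peak = 0.8,
                         background = c("flat", "linear-gradient", "low-frequency"),
                         background_level = 0.1,
                         gradient_range = c(0, 0.5),
                         noise_sd = 0,
                         calibration = NULL) {
  if (is.null(calibration)) calibration <- cluster_calibration()
  background <- match.arg(background)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 8L),
            n_puncta >= 0L, punctum_radius_px > 0,
            punctum_peak >= 0, punctum_peak <= 1,
            noise_sd >= 0, is_calibration(calibration))
  structure(
    list(image_shape = as.integer(image_shape), n_puncta = as.integer(n_puncta),
         punctum_radius_px = punctum_radius_px, punctum_peak = punctum_peak,
         background = background, background_level = background_level,
         gradient_range = gradient_range, noise_sd = noise_sd,
         calibration = calibration),
    class = "scene_params"
  )
}

background_image <- function(params) {
  nr <- params$image_shape[1L]; nc <- params$image_shape[2L]
  switch(params$background,
    "flat" = matrix(params$background_level, nr, nc),
    "linear-gradient" = {
      lo <- params$gradient_range[1L]; hi <- params$gradient_range[2L]
      matrix(rep(seq(lo, hi, length.out = nc), each = nr), nr, nc)
    },
    "low-frequency" = {
      lo <- params$gradient_range[1L]; hi <- params$gradient_range[2L]
      r <- matrix(seq_len(nr), nr, nc)
      cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
      f <- (sin(2 * pi * r / nr) + cos(2 * pi * cc / nc) + 2) / 4  # in [0,1]
      lo + (hi - lo) * f
    }
  )
}

#' Generate a seeded puncta image with known ground truth
#'
#' Places `n_puncta` Gaussian spots with pairwise-disjoint supports (at least
#' 2 px between the 3-sigma truncation disks) on the requested background,
#' adds clipped Gaussian noise, and returns the image together with a
#' `scene_truth` listing the planted centers and true (above-half-maximum)
#' areas. Regeneration with the same seed is bit-identical; the generator
#' uses one explicit RNG seed per call and leaves the session RNG untouched.
#'
#' @param params A [scene_params()].
#' @param seed Integer seed.
#' @return List with `image` (matrix in \[0, 1\]) and `truth` (class
#'   `scene_truth`: `puncta_centers` (n x 2 matrix of row, col),
#'   `puncta_area_px`, `rho`, `enrichment`, `spine_classes`, `seed`).
#' @export
make_puncta_image <- function(params = scene_params(), seed = 1L) {
  stopifnot(inherits(params, "scene_params"))
  seed <- check_seed(seed)
  nr <- params$image_shape[1L]; nc <- params$image_shape[2L]
  sigma <- params$punctum_radius_px / sqrt(2 * log(2))
  support <- ceiling(3 * sigma)
  img <- background_image(params)
  centers <- matrix(numeric(0), 0L, 2L)
  if (params$n_puncta > 0L) {
    margin <- support + 1L
    if (2L * margin >= min(nr, nc)) {
      stop("puncta do not fit inside the image", call. = FALSE)
    }
    min_dist <- 2 * support + 2  # disjoint supports, >= 2 px apart
    centers <- withr::with_seed(seed, place_centers(
      params$n_puncta, nr, nc, margin, min_dist,
      max_attempts = 2000L * params$n_puncta
    ))
    for (i in seq_len(nrow(centers))) {
      img <- add_gaussian_spot(img, centers[i, 1L], centers[i, 2L],
                               sigma, support, params$punctum_peak)
    }
  }
  if (params$noise_sd > 0) {
    img <- img + withr::with_seed(seed + 1L,
      matrix(rnorm(nr * nc, sd = params$noise_sd), nr, nc))
  }
  img <- clamp01(img)
  # true area: pixels above half maximum, i.e. within the half-maximum radius
  area_px <- if (nrow(centers)) {
    rep(disk_pixel_count(sigma * sqrt(2 * log(2))), nrow(centers))
  } else numeric(0)
  truth <- scene_truth(puncta_centers = centers, puncta_area_px = area_px,
                       seed = seed)
  list(image = img, truth = truth)
}

scene_truth <- function(puncta_centers = matrix(numeric(0), 0L, 2L),
                        puncta_area_px = numeric(0), rho = NA_real_,
                        enrichment = NA_real_, spine_classes = character(0),
                        seed = NA_integer_, ...) {
  structure(
    list(puncta_centers = puncta_centers, puncta_area_px = puncta_area_px,
         rho = rho, enrichment = enrichment, spine_classes = spine_classes,
         seed = seed, ...),
    class = "scene_truth"
  )
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d puncta, rho=%s, enrichment=%s, %d protrusions, seed %s\n",
              nrow(x$puncta_centers), format(x$rho), format(x$enrichment),
              length(x$spine_classes), format(x$seed)))
  invisible(x)
}

# Rejection-sample centers with a minimum pairwise distance; errors out when
# the request is too dense to satisfy within the attempt budget.
place_centers <- function(n, nr, nc, margin, min_dist, max_attempts) {
  centers <- matrix(0, n, 2L)
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf(
        "could not place %d disjoint puncta after %d attempts; scene too dense",
        n, max_attempts), call. = FALSE)
    }
    r <- round(runif(1L, margin + 1L, nr - margin))
    cl <- round(runif(1L, margin + 1L, nc - margin))
    if (placed > 0L) {
      d2 <- (centers[seq_len(placed), 1L] - r)^2 + (centers[seq_len(placed), 2L] - cl)^2
      if (min(d2) < min_dist^2) next
    }
    placed <- placed + 1L
    centers[placed, ] <- c(r, cl)
  }
  colnames(centers) <- c("row", "col")
  centers
}

add_gaussian_spot <- function(img, r0, c0, sigma, support, peak) {
  nr <- nrow(img); nc <- ncol(img)
  rr <- max(1L, r0 - support):min(nr, r0 + support)
  cc <- max(1L, c0 - support):min(nc, c0 + support)
  d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
  spot <- peak * exp(-d2 / (2 * sigma^2))
  spot[d2 > (3 * sigma)^2] <- 0  # truncate at 3 sigma
  img[rr, cc] <- img[rr, cc] + spot
  img
}

# Number of integer pixels with distance <= radius from a pixel center.
disk_pixel_count <- function(radius) {
  h <- ceiling(radius)
  off <- seq(-h, h)
  sum(outer(off^2, off^2, `+`) <= radius^2)
}

#' Generate a channel pair with a planted Pearson correlation
#'
#' Draws a reference channel and builds the second as
#' `rho * S + sqrt(1 - rho^2) * N`, where `S` is the first channel's
#' standardized signal and `N` independent standardized noise, so the
#' expected Pearson correlation between the channels equals `rho` and the
#' limits `rho = 1` / `rho = -1` give exact linear (anti-)colocalization.
#'
#' @param n_pixels Number of paired pixels (>= 3).
#' @param rho Target correlation in \[-1, 1\].
#' @param seed Integer seed.
#' @return List with numeric vectors `chanA` and `chanB` of length `n_pixels`
#'   and a `scene_truth` carrying `rho`.
#' @export
make_coloc_pair <- function(n_pixels, rho, seed = 1L) {
  stopifnot(n_pixels >= 3L, rho >= -1, rho <= 1)
  seed <- check_seed(seed)
  withr::with_seed(seed, {
    a <- rnorm(n_pixels)
    n <- rnorm(n_pixels)
  })
  s <- as.numeric(scale(a))
  n <- as.numeric(scale(n))
  b <- rho * s + sqrt(1 - rho^2) * n
  list(chanA = a, chanB = b,
       truth = scene_truth(rho = rho, seed = seed))
}

#' Generate a membrane-enriched dendrite cross-section scene
#'
#' Builds a horizontal dendrite band of the requested width on a dark
#' background, with a diffuse interior intensity and two 1-px membrane lines
#' along the band edges whose (pre-noise) mean intensity is
#' `enrichment` times the centre-line mean. The returned truth carries the
#' enrichment factor and the pixel coordinates of the two membrane lines and
#' the centre line, ready for [membrane_diffuse_ratio()].
#'
#' @param enrichment Membrane / centre intensity factor (> 0).
#' @param width_px Dendrite width including the membrane lines (>= 5).
#' @param noise_sd Additive Gaussian noise sd (clipped to \[0, 1\]).
#' @param length_px Dendrite length in px.
#' @param diffuse_level Interior brightness; membrane brightness is
#'   `enrichment * diffuse_level` and must stay within \[0, 1\].
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return List with `plane` (matrix), `truth` (`scene_truth` with
#'   `enrichment` and line coordinate fields `membrane_lines`, `center_line`).
#' @export
make_membrane_scene <- function(enrichment, width_px = 15L, noise_sd = 0,
                                length_px = 100L, diffuse_level = 0.3,
                                seed = 1L) {
  stopifnot(enrichment > 0, width_px >= 5L, noise_sd >= 0)
  if (enrichment * diffuse_level > 1) {
    stop("enrichment * diffuse_level exceeds the brightness scale", call. = FALSE)
  }
  seed <- check_seed(seed)
  nr <- as.integer(width_px + 10L)  # 5-px dark margin on each side
  nc <- as.integer(length_px)
  top <- 6L
  bottom <- top + as.integer(width_px) - 1L
  plane <- matrix(0, nr, nc)
  plane[top:bottom, ] <- diffuse_level
  plane[top, ] <- enrichment * diffuse_level
  plane[bottom, ] <- enrichment * diffuse_level
  if (noise_sd > 0) {
    plane <- clamp01(plane + withr::with_seed(seed,
      matrix(rnorm(nr * nc, sd = noise_sd), nr, nc)))
  }
  center <- as.integer(round((top + bottom) / 2))
  lines <- list(
    membrane1 = cbind(row = rep(top, nc), col = seq_len(nc)),
    membrane2 = cbind(row = rep(bottom, nc), col = seq_len(nc))
  )
  center_line <- cbind(row = rep(center, nc), col = seq_len(nc))
  truth <- scene_truth(enrichment = enrichment, seed = seed,
                       membrane_lines = lines, center_line = center_line)
  list(plane = plane, truth = truth)
}

#' Generate a protrusion measurement table with known classes
#'
#' Samples geometric descriptors strictly inside each spine class's parameter
#' region (with at least a 5% margin from every decision boundary of the
#' supplied rules), so the rule-based classifier must recover every label.
#' Optionally adds items that violate the retention filters (over-long,
#' under-volume, over-wide) labeled `"reject"`.
#'
#' @param n_per_class Protrusions per class (thin, stubby, mushroom).
#' @param rules A [spine_rules()].
#' @param seed Integer seed.
#' @param n_reject Number of retention-violating items to add.
#' @return A tibble with columns `id`, `length_um`, `max_width_um`,
#'   `volume_um3`, `head_diameter_um`, `neck_diameter_um`, `class`.
#' @export
make_protrusion_table <- function(n_per_class, rules = spine_rules(),
                                  seed = 1L, n_reject = 0L) {
  stopifnot(n_per_class >= 1L, inherits(rules, "spine_rules"))
  seed <- check_seed(seed)
  withr::with_seed(seed, {
    len <- function(n) runif(n, rules$min_length_um * 2, rules$max_length_um * 0.5)
    small_head <- function(n) runif(n, 0.10, rules$mushroom_min_head_um * 0.95)
    thin <- tibble::tibble(
      length_um = len(n_per_class),
      max_width_um = runif(n_per_class, 0.10, 0.30),
      volume_um3 = runif(n_per_class, rules$min_volume_um3 * 1.05,
                         rules$stubby_min_volume_um3 * 0.95),
      head_diameter_um = small_head(n_per_class),
      class = "thin"
    )
    thin$neck_diameter_um <- thin$head_diameter_um / runif(n_per_class, 0.95, 1.04)
    stubby <- tibble::tibble(
      length_um = runif(n_per_class, rules$min_length_um * 2, 1.0),
      max_width_um = runif(n_per_class, 0.4, 1.0),
      volume_um3 = runif(n_per_class, rules$stubby_min_volume_um3 * 1.05, 0.3),
      head_diameter_um = small_head(n_per_class),
      class = "stubby"
    )
    stubby$neck_diameter_um <- stubby$head_diameter_um / runif(n_per_class, 0.95, 1.04)
    mushroom <- tibble::tibble(
      length_um = len(n_per_class),
      max_width_um = runif(n_per_class, 0.4, 1.0),
      volume_um3 = runif(n_per_class, rules$min_volume_um3 * 1.05,
                         rules$stubby_min_volume_um3 * 0.95),
      head_diameter_um = runif(n_per_class, rules$mushroom_min_head_um * 1.05, 0.8),
      class = "mushroom"
    )
    mushroom$neck_diameter_um <- mushroom$head_diameter_um /
      runif(n_per_class, rules$mushroom_min_head_neck_ratio * 1.05, 2.0)
    out <- rbind(thin, stubby, mushroom)
    if (n_reject > 0L) {
      kind <- rep_len(c("too_long", "too_small", "too_wide"), n_reject)
      rej <- tibble::tibble(
        length_um = ifelse(kind == "too_long", rules$max_length_um + 1,
                           runif(n_reject, 0.5, 2)),
        max_width_um = ifelse(kind == "too_wide", rules$max_width_um * 1.2,
                              runif(n_reject, 0.2, 0.5)),
        volume_um3 = ifelse(kind == "too_small", rules$min_volume_um3 * 0.5,
                            runif(n_reject, rules$min_volume_um3 * 1.1, 0.1)),
        head_diameter_um = runif(n_reject, 0.1, 0.3),
        class = "reject"
      )
      rej$neck_diameter_um <- rej$head_diameter_um
      out <- rbind(out, rej)
    }
  })
  out$id <- seq_len(nrow(out))
  out[, c("id", "length_um", "max_width_um", "volume_um3",
          "head_diameter_um", "neck_diameter_um", "class")]
}

#' Draw a synthetic dendrite with protrusions of known class
#'
#' Renders a horizontal dendrite shaft with upward protrusions drawn as
#' geometric templates — narrow pegs (thin), short wide rectangles (stubby),
#' and ball-on-stick shapes (mushroom) — whose dimensions land strictly
#' inside the corresponding class region of the default rules at the chosen
#' calibration. Used to exercise [measure_protrusions()] end to end.
#'
#' @param classes Character vector of `"thin"`, `"stubby"`, `"mushroom"`
#'   giving the protrusions left to right.
#' @param seed Integer seed (jitters template dimensions by a few percent).
#' @param pixel_size_um Pixel size; default 0.02 um/px renders a 0.35-um head
#'   as ~18 px, comfortably above rasterization noise.
#' @param section_um Section thickness used for the 2D volume convention
#'   (volume = area x thickness).
#' @return List with `mask` (logical image), `shaft` (logical shaft mask),
#'   `calibration`, `section_um`, and `truth` (`scene_truth` with
#'   `spine_classes`).
#' @export
make_spine_image <- function(classes, seed = 1L, pixel_size_um = 0.02,
                             section_um = 0.2) {
  stopifnot(length(classes) >= 1L,
            all(classes %in% c("thin", "stubby", "mushroom")))
  seed <- check_seed(seed)
  n <- length(classes)
  slot_w <- 60L
  nr <- 110L
  nc <- n * slot_w + 40L
  mask <- matrix(FALSE, nr, nc)
  shaft_top <- 86L
  shaft <- matrix(FALSE, nr, nc)
  shaft[shaft_top:nr, ] <- TRUE
  mask[shaft_top:nr, ] <- TRUE
  jit <- withr::with_seed(seed, matrix(runif(3L * n, 0.95, 1.05), n, 3L))
  for (i in seq_len(n)) {
    cx <- 20L + (i - 1L) * slot_w + slot_w %/% 2L
    cls <- classes[i]
    if (cls == "thin") {
      w <- max(4L, round(6 * jit[i, 1L]))          # ~0.12 um wide
      len <- round(60 * jit[i, 2L])                # ~1.2 um long
      mask[(shaft_top - len):(shaft_top - 1L),
           (cx - w %/% 2L):(cx - w %/% 2L + w - 1L)] <- TRUE
    } else if (cls == "stubby") {
      w <- round(26 * jit[i, 1L])                  # ~0.52 um wide
      len <- round(25 * jit[i, 2L])                # ~0.5 um long
      mask[(shaft_top - len):(shaft_top - 1L),
           (cx - w %/% 2L):(cx - w %/% 2L + w - 1L)] <- TRUE
    } else {
      stick_w <- max(6L, round(8 * jit[i, 1L]))    # ~0.16 um neck
      stick_len <- round(20 * jit[i, 2L])
      head_r <- round(12 * jit[i, 3L])             # head ~0.48 um across
      mask[(shaft_top - stick_len):(shaft_top - 1L),
           (cx - stick_w %/% 2L):(cx - stick_w %/% 2L + stick_w - 1L)] <- TRUE
      hc <- shaft_top - stick_len - head_r
      rr <- (hc - head_r):(hc + head_r)
      cc <- (cx - head_r):(cx + head_r)
      d2 <- outer((rr - hc)^2, (cc - cx)^2, `+`)
      mask[rr, cc] <- mask[rr, cc] | (d2 <= head_r^2)
    }
  }
  truth <- scene_truth(spine_classes = classes, seed = seed)
  list(mask = mask, shaft = shaft,
       calibration = calibration(pixel_size_um, z_step_um = section_um),
       section_um = section_um, truth = truth)
}
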