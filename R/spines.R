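#' Dendritic-spine retention and classification rules
#'
#' Thresholds of the rule set used to retain dendrite protrusions as spines
#' and classify them as thin, stubby or mushroom. Retention: volume at least
#' 0.020 um^3, base-to-tip length between 0.1 and 5 um, maximal width at
#' most 3 um (all boundaries inclusive). Classification, evaluated in order:
#' mushroom when the head diameter is at least 0.35 um and the head-to-neck
#' ratio at least 1.1; otherwise stubby when the volume is at least
#' 0.040 um^3; otherwise thin.
#'
#' The physical (um^3) volume thresholds are the authoritative contract;
#' equivalent voxel counts depend on the voxel size and can be derived with
#' [voxel_volume_um3()].
#'
#' @param min_volume_um3,min_length_um,max_length_um,max_width_um Retention
#'   thresholds.
#' @param mushroom_min_head_um,mushroom_min_head_neck_ratio,stubby_min_volume_um3
#'   Classification thresholds.
#' @return Object of class `spine_rules`.
#' @export
spine_rules <- function(min_volume_um3 = 0.020,
                        min_length_um = 0.1,
                        max_length_um = 5,
                        max_width_um = 3,
                        mushroom_min_head_um = 0.35,
                        mushroom_min_head_neck_ratio = 1.1,
                        stubby_min_volume_um3 = 0.040) {
  stopifnot(min_length_um < max_length_um,
            min_volume_um3 > 0, max_width_um > 0,
            mushroom_min_head_um > 0, mushroom_min_head_neck_ratio > 0,
            stubby_min_volume_um3 > 0)
  structure(
    list(min_volume_um3 = min_volume_um3, min_length_um = min_length_um,
         max_length_um = max_length_um, max_width_um = max_width_um,
         mushroom_min_head_um = mushroom_min_head_um,
         mushroom_min_head_neck_ratio = mushroom_min_head_neck_ratio,
         stubby_min_volume_um3 = stubby_min_volume_um3),
    class = "spine_rules"
  )
}

#' Retain protrusions that qualify as spines
#'
#' Applies the retention filters: a protrusion is kept iff its volume is at
#' least `min_volume_um3`, its length lies in
#' \[`min_length_um`, `max_length_um`\] and its maximal width is at most
#' `max_width_um`. All comparisons are inclusive.
#'
#' @param measures Data frame with columns `length_um`, `max_width_um`,
#'   `volume_um3` (and typically `head_diameter_um`, `neck_diameter_um`).
#' @param rules A [spine_rules()].
#' @return The retained rows of `measures`.
#' @export
filter_protrusions <- function(measures, rules = spine_rules()) {
  stopifnot(is.data.frame(measures), inherits(rules, "spine_rules"))
  keep <- retention_flags(measures, rules)
  keep[is.na(keep)] <- FALSE   # unmeasured (e.g. border-flagged) protrusions
  measures[keep, , drop = FALSE]
}

#' @rdname filter_protrusions
#' @return For `retention_flags`, a logical vector (TRUE = retained).
#' @export
retention_flags <- function(measures, rules = spine_rules()) {
  measures$volume_um3 >= rules$min_volume_um3 &
    measures$length_um >= rules$min_length_um &
    measures$length_um <= rules$max_length_um &
    measures$max_width_um <= rules$max_width_um
}

#' Classify a retained protrusion as thin, stubby or mushroom
#'
#' Rules evaluated in order: mushroom iff head diameter >= 0.35 um and
#' head-to-neck ratio >= 1.1; else stubby iff volume >= 0.040 um^3; else
#' thin. A zero neck with a nonzero head leaves the ratio undefined and is
#' an error.
#'
#' @param measure One-row data frame or list with `head_diameter_um`,
#'   `neck_diameter_um`, `volume_um3`.
#' @param rules A [spine_rules()].
#' @return `"mushroom"`, `"stubby"` or `"thin"`.
#' @export
classify_spine <- function(measure, rules = spine_rules()) {
  head <- measure$head_diameter_um
  neck <- measure$neck_diameter_um
  vol <- measure$volume_um3
  stopifnot(length(head) == 1L, length(neck) == 1L, length(vol) == 1L)
  if (neck == 0 && head > 0) {
    stop("head/neck ratio undefined: neck diameter is zero", call. = FALSE)
  }
  ratio <- if (head == 0 && neck == 0) 0 else head / neck
  if (head >= rules$mushroom_min_head_um &&
      ratio >= rules$mushroom_min_head_neck_ratio) {
    "mushroom"
  } else if (vol >= rules$stubby_min_volume_um3) {
    "stubby"
  } else {
    "thin"
  }
}

#' @rdname classify_spine
#' @param measures Data frame of retained protrusions.
#' @return For `classify_spines`, a character vector of classes.
#' @export
classify_spines <- function(measures, rules = spine_rules()) {
  vapply(seq_len(nrow(measures)),
         function(i) classify_spine(measures[i, ], rules),
         character(1))
}

#' Spine census and per-length densities
#'
#' Builds the spine census: counts and densities (spines per um of dendrite)
#' in total and per morphological class.
#'
#' @param classes Character vector of classes of the retained spines
#'   (from [classify_spines()]).
#' @param dendrite_length_um Dendrite length in um (> 0).
#' @return Object of class `spine_census`: `counts`, `densities` (named
#'   vectors over thin/stubby/mushroom plus `total`), `dendrite_length_um`.
#' @examples
#' spine_density(rep(c("thin", "stubby", "mushroom"), c(3, 2, 1)), 10)
#' @export
spine_density <- function(classes, dendrite_length_um) {
  if (!is.numeric(dendrite_length_um) || dendrite_length_um <= 0) {
    stop("`dendrite_length_um` must be positive", call. = FALSE)
  }
  lv <- c("thin", "stubby", "mushroom")
  stopifnot(all(classes %in% lv))
  counts <- table(factor(classes, levels = lv))
  counts <- c(as.vector(counts), total = length(classes))
  names(counts) <- c(lv, "total")
  structure(
    list(counts = counts,
         densities = counts / dendrite_length_um,
         dendrite_length_um = dendrite_length_um),
    class = "spine_census"
  )
}

#' @export
print.spine_census <- function(x, ...) {
  cat(sprintf("<spine_census> %d spines on %.2f um (%.3f /um): %d thin, %d stubby, %d mushroom\n",
              x$counts[["total"]], x$dendrite_length_um,
              x$densities[["total"]], x$counts[["thin"]],
              x$counts[["stubby"]], x$counts[["mushroom"]]))
  invisible(x)
}

#' Measure protrusion geometry on a segmented dendrite image
#'
#' Desk-scale 2D morphometry of protrusions off a dendrite shaft. The shaft
#' mask is subtracted from the segmentation; each remaining connected
#' component is one protrusion. Pixels are binned by their Euclidean
#' distance to the shaft; each bin is one chord perpendicular to the
#' protrusion axis, and:
#' length = maximal shaft distance, widths = chord extents, head diameter =
#' maximal chord in the distal half, neck diameter = minimal chord between
#' base and head, volume = pixel count x pixel area x section thickness.
#' Protrusions touching the image border are flagged and excluded.
#'
#' @param mask Logical segmentation (shaft + protrusions), e.g. from
#'   [make_spine_image()].
#' @param shaft Logical shaft mask.
#' @param calibration A [calibration()].
#' @param section_um Section thickness for the 2D volume convention.
#' @return A tibble with `id`, `length_um`, `max_width_um`, `volume_um3`,
#'   `head_diameter_um`, `neck_diameter_um`, `n_px`, `border` (logical;
#'   border-touching protrusions are returned flagged, not measured).
#' @export
measure_protrusions <- function(mask, shaft, calibration, section_um = 0.2) {
  stopifnot(is.logical(mask), is.logical(shaft),
            identical(dim(mask), dim(shaft)), is_calibration(calibration))
  px <- calibration$pixel_size_um
  prot <- mask & !shaft
  labels <- label_components(prot, 8L)
  n <- max(labels)
  dist_to_shaft <- EBImage::distmap(matrix(as.numeric(!shaft), nrow(shaft), ncol(shaft)))
  out <- vector("list", n)
  nr <- nrow(mask); nc <- ncol(mask)
  for (k in seq_len(n)) {
    idx <- which(labels == k)
    rc <- idx_to_rc(idx, nr)
    border <- any(rc[, 1L] %in% c(1L, nr)) || any(rc[, 2L] %in% c(1L, nc))
    if (border) {
      out[[k]] <- tibble::tibble(id = k, length_um = NA_real_,
                                 max_width_um = NA_real_, volume_um3 = NA_real_,
                                 head_diameter_um = NA_real_,
                                 neck_diameter_um = NA_real_,
                                 n_px = length(idx), border = TRUE)
      next
    }
    d <- dist_to_shaft[idx]
    bin <- pmax(1L, ceiling(d))
    chords <- tabulate(bin) * px          # chord extent per 1-px distance bin
    chords[chords == 0] <- NA             # bins a slanted axis can skip
    nb <- length(chords)
    len_um <- max(bin) * px
    distal <- chords[seq_len(nb) > nb / 2]
    head_bin <- which(chords == max(distal, na.rm = TRUE) &
                        seq_len(nb) > nb / 2)[1L]
    head_um <- chords[head_bin]
    neck_um <- min(chords[seq_len(head_bin)], na.rm = TRUE)
    out[[k]] <- tibble::tibble(
      id = k, length_um = len_um, max_width_um = max(chords),
      volume_um3 = length(idx) * px^2 * section_um,
      head_diameter_um = head_um, neck_diameter_um = neck_um,
      n_px = length(idx), border = FALSE
    )
  }
  if (n == 0L) {
    return(tibble::tibble(id = integer(0), length_um = numeric(0),
                          max_width_um = numeric(0), volume_um3 = numeric(0),
                          head_diameter_um = numeric(0),
                          neck_diameter_um = numeric(0), n_px = integer(0),
                          border = logical(0)))
  }
  do.call(rbind, out)
}
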