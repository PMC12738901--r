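#' Classify detections as mother or daughter cells by diameter
#'
#' Pre-division (mother) cells are roughly 20 um in diameter and post-division
#' (daughter) cells roughly 15 um; detections strictly larger than the
#' threshold are classified as mothers, all others as daughters.
#'
#' @param diameter_um Numeric vector of equivalent diameters in micrometres.
#' @param threshold_um Classification threshold (default 18 um).
#' @return Character vector of `"mother"` / `"daughter"`.
#' @export
classify_size <- function(diameter_um, threshold_um = 18) {
  check_positive_scalar(threshold_um, "threshold_um")
  ifelse(diameter_um > threshold_um, "mother", "daughter")
}

#' Equivalent circular diameter from a mask area
#'
#' Cell size `S` is the pixel count of an instance mask; the equivalent
#' diameter solves `S = pi * R^2` with `D = 2 R`, i.e.
#' `D = 2 * sqrt(area / pi)`.
#'
#' @param area_um2 Area in square micrometres.
#' @return Diameter in micrometres.
#' @export
diameter_from_area <- function(area_um2) 2 * sqrt(area_um2 / pi)

#' Tabulate per-frame instance detections from label masks
#'
#' One row per instance per frame with the pixel area, physical area
#' (`area_px * pixel_size^2` using the mask's own calibration), equivalent
#' diameter, centroid, and mother/daughter size class.
#'
#' @param masks A [label_mask_stack()].
#' @param frame_interval Minutes between frames; defaults to the stack's own.
#' @param origin_time Minutes of frame 0; defaults to the stack's own.
#' @param threshold_um Mother/daughter split diameter (default 18 um).
#' @return A tibble of class `detection_table` with columns `frame` (0-based),
#'   `time_min`, `label`, `area_px`, `area_um2`, `diameter_um`,
#'   `centroid_row`, `centroid_col`, `size_class`. The number of frames and
#'   calibration are attached as attributes.
#' @export
masks_to_detections <- function(masks, frame_interval = NULL,
                                origin_time = NULL, threshold_um = 18) {
  stopifnot(inherits(masks, "label_mask_stack"))
  frame_interval <- frame_interval %||% masks$frame_interval
  origin_time <- origin_time %||% masks$origin_time %||% 0
  if (is.null(frame_interval) || is.na(frame_interval)) {
    abort("`frame_interval` is required (stack carries none).")
  }
  d <- dim(masks$masks)
  ps <- masks$pixel_size
  per_frame <- vector("list", d[1])
  for (f in seq_len(d[1])) {
    m <- masks$masks[f, , ]
    idx <- which(m > 0)
    if (length(idx) == 0L) next
    lab <- m[idx]
    rows <- (idx - 1L) %% d[2] + 1L
    cols <- (idx - 1L) %/% d[2] + 1L
    agg <- rowsum(cbind(n = 1, r = rows, c = cols), group = lab)
    labels <- as.integer(rownames(agg))
    per_frame[[f]] <- tibble(
      frame = f - 1L,
      label = labels,
      area_px = as.numeric(agg[, "n"]),
      centroid_row = agg[, "r"] / agg[, "n"],
      centroid_col = agg[, "c"] / agg[, "n"]
    )
  }
  out <- bind_rows(per_frame)
  if (nrow(out) == 0L) {
    out <- tibble(frame = integer(), label = integer(), area_px = numeric(),
                  centroid_row = numeric(), centroid_col = numeric())
  }
  out <- out |>
    mutate(
      time_min = origin_time + .data$frame * frame_interval,
      area_um2 = .data$area_px * ps^2,
      diameter_um = diameter_from_area(.data$area_um2),
      size_class = classify_size(.data$diameter_um, threshold_um)
    ) |>
    dplyr::select("frame", "time_min", "label", "area_px", "area_um2",
                  "diameter_um", "centroid_row", "centroid_col", "size_class")
  structure(out, class = c("detection_table", class(out)),
            n_frames = d[1], pixel_size = ps,
            frame_interval = frame_interval, origin_time = origin_time)
}

#' Count cells in the field of view
#'
#' The total-cell denominator used by [rounding_curve()] and
#' [viability_fraction()]. It is taken from the first frame of a nuclei
#' label-mask stack (external segmentation) or passed through from a known
#' ground-truth count, and is kept fixed for the whole video.
#'
#' @param x A [label_mask_stack()] (count = distinct positive labels in frame
#'   0) or a single non-negative number (ground truth).
#' @return An object of class `nuclei_count` with fields `count` and `source`.
#' @export
count_nuclei <- function(x) {
  if (inherits(x, "label_mask_stack")) {
    labs <- unique(as.vector(x$masks[1, , ]))
    n <- sum(labs > 0)
    src <- "external-mask"
  } else if (is.numeric(x) && length(x) == 1L && !is.na(x) &&
             x >= 0 && x == round(x)) {
    n <- as.integer(x)
    src <- "ground-truth"
  } else {
    abort("Provide a label mask stack or a single non-negative integer count.")
  }
  structure(list(count = as.integer(n), source = src), class = "nuclei_count")
}

#' @export
print.nuclei_count <- function(x, ...) {
  cat(sprintf("<nuclei_count> %d cells (%s)\n", x$count, x$source))
  invisible(x)
}

# Perimeter from EBImage's boundary-pixel count underestimates the true
# contour length; the factor below rescales 4*pi*A/P^2 so that rasterised
# discs of 6-25 px radius - including discs flattened on one side by a
# watershed split of a touching pair - stay at or above the 0.8 circularity
# default while 3:1 ellipses fall to ~0.67.
PERIMETER_CORRECTION <- 1.08

#' Classical round-cell detector
#'
#' A threshold-based detector for bright-halo rounded cells, used to close
#' the analysis loop on synthetic or other high-contrast data in place of an
#' external learned detector. Rounded mitotic cells in defocused brightfield
#' show a bright ring with a darker interior; the detector smooths the frame,
#' thresholds it adaptively against the local mean at the scale of the
#' largest expected cell (so slow illumination gradients do not matter),
#' fills ring interiors, splits touching cells by a watershed on the distance
#' transform, and keeps components whose circularity `4*pi*A/P^2` and
#' equivalent diameter fall within bounds.
#'
#' @param frame Numeric matrix in `[0, 1]` (a preprocessed or rendered frame).
#' @param pixel_size Micrometres per pixel.
#' @param diameter_range Kept equivalent-diameter range in um (default
#'   `c(10, 25)`).
#' @param circularity_min Minimum circularity (default 0.8).
#' @param offset Adaptive-threshold offset above the local mean, in intensity
#'   units of the `[0, 1]` frame (default 0.1); structures with less local
#'   contrast than this, such as flat adherent cells, are ignored.
#' @return An integer instance-label matrix (0 = background).
#' @export
detect_round_cells_classical <- function(frame, pixel_size,
                                         diameter_range = c(10, 25),
                                         circularity_min = 0.8,
                                         offset = 0.1) {
  check_positive_scalar(pixel_size, "pixel_size")
  if (length(diameter_range) != 2L || diff(diameter_range) <= 0) {
    abort("`diameter_range` must be an increasing (min, max) pair in um.")
  }
  if (min(frame) < 0 || max(frame) > 1) abort("`frame` must lie in [0, 1].")
  empty <- matrix(0L, nrow(frame), ncol(frame))
  if (diff(range(frame)) == 0) return(empty)

  sm <- smooth_gaussian(frame, 1)
  # local contrast against the mean over a window of the largest expected
  # cell: both the bright halo and the darker interior of a rounded cell
  # exceed it, while flat adherent cells and slow illumination trends do not
  w <- 2L * ceiling(diameter_range[2] / pixel_size / 2) + 1L
  w <- min(w, dim(sm) - 1L + (dim(sm) %% 2L))  # kernel must fit the frame
  box <- matrix(1 / (w * w), w, w)
  local_mean <- as.matrix(EBImage::filter2(sm, box, boundary = "replicate"))
  bin <- abs(sm - local_mean) > offset
  if (!any(bin)) return(empty)
  filled <- EBImage::fillHull(EBImage::Image(bin * 1))
  filled <- EBImage::opening(filled, EBImage::makeBrush(3, shape = "disc"))
  if (sum(filled > 0) == 0) return(empty)
  lab <- EBImage::watershed(EBImage::distmap(filled))
  lab <- as.matrix(EBImage::imageData(lab))
  if (max(lab) == 0) return(empty)

  fs <- EBImage::computeFeatures.shape(lab)
  area <- fs[, "s.area"]
  perim <- pmax(fs[, "s.perimeter"], 1) * PERIMETER_CORRECTION
  circ <- pmin(4 * pi * area / perim^2, 1)
  diam <- diameter_from_area(area * pixel_size^2)
  keep <- which(circ >= circularity_min &
                  diam >= diameter_range[1] & diam <= diameter_range[2])
  if (length(keep) == 0L) return(empty)
  relabel <- integer(max(lab) + 1L)
  relabel[keep + 1L] <- seq_along(keep)
  matrix(relabel[lab + 1L], nrow(lab), ncol(lab))
}

#' Run the classical detector over a whole video
#'
#' @param video A [video_stack()] or `preprocessed_video`; frames must lie in
#'   `[0, 1]` (raw stacks are min-max normalised per frame first).
#' @inheritParams detect_round_cells_classical
#' @return A [label_mask_stack()] on the video's grid.
#' @export
detect_round_cells_video <- function(video, diameter_range = c(10, 25),
                                     circularity_min = 0.8, offset = 0.1) {
  frames <- video$frames
  d <- dim(frames)
  if (min(frames) < 0 || max(frames) > 1) {
    frames <- normalize_minmax(frames, scope = "frame")
  }
  out <- array(0L, dim = d)
  for (i in seq_len(d[1])) {
    out[i, , ] <- detect_round_cells_classical(
      frames[i, , ], pixel_size = video$pixel_size,
      diameter_range = diameter_range, circularity_min = circularity_min,
      offset = offset)
  }
  label_mask_stack(out, pixel_size = video$pixel_size,
                   frame_interval = video$frame_interval,
                   origin_time = video$origin_time %||% 0)
}
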