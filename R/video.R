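#' Construct a calibrated time-lapse video stack
#'
#' A `video_stack` bundles a single field of view (FOV) with its spatial and
#' temporal calibration. Frames are stored as a 3-D array indexed
#' `(time, row, column)`; frame indices reported in tables are 0-based so that
#' `time_min = origin_time + frame * frame_interval`.
#'
#' @param frames Numeric 3-D array `(time, row, column)` of non-negative
#'   intensities. A matrix is accepted and treated as a single frame.
#' @param pixel_size Isotropic pixel size in micrometres. A length-2 vector is
#'   accepted only when both entries are equal; anisotropic pixels are
#'   rejected.
#' @param frame_interval Minutes between consecutive frames.
#' @param origin_time Minutes of frame 0 relative to synchronisation release.
#' @param identifier Free-text FOV/condition label.
#'
#' @return An object of class `video_stack`.
#' @export
video_stack <- function(frames, pixel_size, frame_interval, origin_time = 0,
                        identifier = "fov") {
  if (is.matrix(frames)) {
    frames <- array(frames, dim = c(1L, dim(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    abort("`frames` must be a (time, row, column) array or a single matrix.")
  }
  if (anyNA(frames) || any(frames < 0)) {
    abort("`frames` must be non-negative and free of missing values.")
  }
  pixel_size <- check_isotropic_pixel_size(pixel_size)
  check_positive_scalar(frame_interval, "frame_interval")
  if (!is.numeric(origin_time) || length(origin_time) != 1L) {
    abort("`origin_time` must be a single number (minutes).")
  }
  structure(
    list(frames = frames, pixel_size = pixel_size,
         frame_interval = frame_interval, origin_time = origin_time,
         identifier = as.character(identifier)),
    class = "video_stack"
  )
}

check_isotropic_pixel_size <- function(pixel_size) {
  if (length(pixel_size) == 2L) {
    if (!isTRUE(all.equal(pixel_size[1], pixel_size[2]))) {
      abort("Anisotropic pixels are not supported: supply a single pixel size.")
    }
    pixel_size <- pixel_size[1]
  }
  check_positive_scalar(pixel_size, "pixel_size")
  pixel_size
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<video_stack '%s'> %d frames of %d x %d px | %.3g um/px | %.3g min/frame | t0 = %g min\n",
    x$identifier, d[1], d[2], d[3], x$pixel_size, x$frame_interval,
    x$origin_time))
  invisible(x)
}

#' @export
dim.video_stack <- function(x) dim(x$frames)

#' Frame times of a video or mask stack
#'
#' @param x A `video_stack`, `preprocessed_video` or `label_mask_stack`.
#' @return Numeric vector of frame times in minutes (frame 0 first).
#' @export
frame_times <- function(x) {
  n <- dim(x$frames %||% x$masks)[1]
  (x$origin_time %||% 0) + (seq_len(n) - 1L) * x$frame_interval
}

#' Construct an instance label mask stack
#'
#' Per-frame instance segmentation masks aligned to a video. The background is
#' label 0 and instance labels are positive integers unique within a frame;
#' labels are not tracked across frames. The mask grid may be calibrated
#' differently from the video when detection ran on a resampled grid, so all
#' physical quantities derived from masks use the mask's own `pixel_size`.
#'
#' @param masks Integer 3-D array `(time, row, column)` of instance labels.
#' @param pixel_size Micrometres per mask pixel.
#' @param frame_interval Minutes between frames (used when deriving times).
#' @param origin_time Minutes of frame 0.
#'
#' @return An object of class `label_mask_stack`.
#' @export
label_mask_stack <- function(masks, pixel_size, frame_interval = NA_real_,
                             origin_time = 0) {
  if (is.matrix(masks)) masks <- array(masks, dim = c(1L, dim(masks)))
  if (!is.array(masks) || length(dim(masks)) != 3L) {
    abort("`masks` must be a (time, row, column) array or a single matrix.")
  }
  if (anyNA(masks) || any(masks != round(masks))) {
    abort("Mask labels must be integer-valued.")
  }
  if (any(masks < 0)) abort("Mask labels must be non-negative.")
  pixel_size <- check_isotropic_pixel_size(pixel_size)
  structure(
    list(masks = masks, pixel_size = pixel_size,
         frame_interval = frame_interval, origin_time = origin_time),
    class = "label_mask_stack"
  )
}

#' @export
print.label_mask_stack <- function(x, ...) {
  d <- dim(x$masks)
  cat(sprintf("<label_mask_stack> %d frames of %d x %d px | %.3g um/px\n",
              d[1], d[2], d[3], x$pixel_size))
  invisible(x)
}

#' Read a multi-page TIFF time-lapse video
#'
#' Intensities are preserved bit-exactly for integer TIFFs (the raw sample
#' values are returned, not rescaled to `[0, 1]`). Calibration is never
#' guessed from metadata: `pixel_size` and `frame_interval` are required.
#'
#' @param path Path to a multi-page TIFF, one page per frame.
#' @inheritParams video_stack
#' @return A [video_stack()].
#' @export
read_video <- function(path, pixel_size, frame_interval, origin_time = 0,
                       identifier = NULL) {
  pages <- read_tiff_pages(path)
  video_stack(pages_to_array(pages), pixel_size = pixel_size,
              frame_interval = frame_interval, origin_time = origin_time,
              identifier = identifier %||% basename(path))
}

# Supported sample formats: 8/16-bit unsigned integer (returned bit-exact as
# raw sample values) and 32-bit float (returned as stored).
read_tiff_pages <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) {
                      abort(sprintf("Not a readable TIFF (%s): %s",
                                    conditionMessage(e), path))
                    })
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 1L) abort(sprintf("TIFF has no pages: %s", path))
  bits <- attr(pages[[1L]], "bits.per.sample") %||% 16L
  if (bits < 32L) {
    # integer samples: re-read unnormalised for a bit-exact round trip
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  # multi-channel pages are collapsed to their first channel
  lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1L] else p)
}

pages_to_array <- function(pages) {
  d <- dim(pages[[1L]])
  same <- vapply(pages, function(p) identical(dim(p), d), logical(1))
  if (!all(same)) abort("All TIFF pages must share the same height/width.")
  out <- array(0, dim = c(length(pages), d))
  for (i in seq_along(pages)) out[i, , ] <- pages[[i]]
  out
}

#' Write a video stack to a multi-page TIFF
#'
#' Integer-valued stacks with intensities below 2^16 are written as 16-bit
#' pages (lossless round trip via [read_video()]); stacks with values in
#' `[0, 1]` are written as 32-bit float pages.
#'
#' @param video A [video_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_video <- function(video, path) {
  stopifnot(inherits(video, "video_stack"))
  write_frames_tiff(video$frames, path)
}

write_frames_tiff <- function(frames, path) {
  n <- dim(frames)[1]
  pages <- lapply(seq_len(n), function(i) frames[i, , ])
  if (all(frames == round(frames)) && max(frames) <= 65535) {
    pages <- lapply(pages, function(p) p / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else if (min(frames) >= 0 && max(frames) <= 1) {
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  } else {
    abort("Frames must be integers in [0, 65535] or floats in [0, 1].")
  }
  invisible(path)
}

#' Read instance label masks from a multi-page TIFF
#'
#' @param path Path to an integer-valued multi-page TIFF.
#' @inheritParams label_mask_stack
#' @return A [label_mask_stack()].
#' @export
read_label_masks <- function(path, pixel_size, frame_interval = NA_real_,
                             origin_time = 0) {
  pages <- read_tiff_pages(path)
  arr <- pages_to_array(pages)
  if (any(arr != round(arr))) {
    abort(sprintf("Label masks must be integer-valued: %s", path))
  }
  label_mask_stack(arr, pixel_size = pixel_size,
                   frame_interval = frame_interval, origin_time = origin_time)
}

#' Write instance label masks to a multi-page TIFF
#'
#' @param masks A [label_mask_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_label_masks <- function(masks, path) {
  stopifnot(inherits(masks, "label_mask_stack"))
  if (max(masks$masks) > 65535) abort("Labels above 65535 are not supported.")
  write_frames_tiff(masks$masks, path)
}

#' Write an analysis table to CSV
#'
#' CSV with a header row and stable column order; re-reading with
#' [read_table_csv()] recovers the values.
#'
#' @param rows A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  readr::write_csv(as_tibble(rows), path)
  invisible(path)
}

#' Read an analysis table written by [write_table()]
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a YAML analysis configuration
#'
#' Configuration files carry the calibration (`pixel_size`, `frame_interval`)
#' and condition metadata that TIFF files do not; absent calibration is an
#' error rather than a silent default.
#'
#' @param path YAML (or JSON) file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
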