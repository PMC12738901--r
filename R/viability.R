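#' Segment viability-dye positive nuclei
#'
#' Segments bright nuclei in a fluorescence viability channel (e.g. a
#' membrane-impermeant nucleic-acid dye marking dead cells): the frame is
#' min-max normalised, thresholded with Otsu's method, touching nuclei are
#' split by a watershed on the distance transform, and components smaller
#' than `min_area_px` are discarded as noise. Because thresholding happens on
#' the normalised frame, the segmentation is invariant to positive affine
#' rescaling of the intensities.
#'
#' Dye-positive nuclei are sparse; if the thresholded foreground covers more
#' than `max_foreground` of the frame the channel is considered signal-free
#' (e.g. a blank or constant frame whose threshold lands inside the noise)
#' and an empty mask is returned with a warning.
#'
#' @param frame Single-channel numeric matrix.
#' @param min_area_px Minimum component area in pixels (default 10).
#' @param max_foreground Maximum plausible foreground fraction (default 0.25).
#' @return An integer instance-label matrix (0 = background).
#' @export
segment_positive_nuclei <- function(frame, min_area_px = 10,
                                    max_foreground = 0.25) {
  if (!is.matrix(frame)) abort("`frame` must be a single-channel matrix.")
  empty <- matrix(0L, nrow(frame), ncol(frame))
  if (diff(range(frame)) == 0) {
    warn("Constant frame: no threshold separates signal from background.")
    return(empty)
  }
  f <- normalize_minmax(frame)
  thr <- EBImage::otsu(EBImage::Image(f))
  bin <- f > thr
  if (mean(bin) > max_foreground) {
    warn("Thresholded foreground exceeds the plausible nuclei cover; treating the channel as signal-free.")
    return(empty)
  }
  if (!any(bin)) return(empty)
  lab <- EBImage::watershed(EBImage::distmap(EBImage::Image(bin * 1)))
  lab <- as.matrix(EBImage::imageData(lab))
  if (max(lab) == 0) return(empty)
  area <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(area >= min_area_px)
  relabel <- integer(max(lab) + 1L)
  relabel[keep + 1L] <- seq_along(keep)
  matrix(relabel[lab + 1L], nrow(lab), ncol(lab))
}

#' Viability fraction from a positive-nuclei mask
#'
#' The fraction of dead/dying cells: dye-positive nuclei divided by the total
#' cell count of the field of view. The denominator is the fixed first-frame
#' count, consistent with the rounding-fraction convention.
#'
#' @param positive_mask Integer instance-label matrix from
#'   [segment_positive_nuclei()].
#' @param nuclei A [count_nuclei()] result or a single positive count.
#' @return An object of class `viability_result` with fields `n_positive`,
#'   `n_total` and `fraction`.
#' @export
viability_fraction <- function(positive_mask, nuclei) {
  if (is.numeric(nuclei) && length(nuclei) == 1L) nuclei <- count_nuclei(nuclei)
  if (nuclei$count <= 0) abort("Viability needs a positive total-cell count.")
  n_pos <- length(setdiff(unique(as.vector(positive_mask)), 0L))
  structure(
    list(n_positive = n_pos, n_total = nuclei$count,
         fraction = n_pos / nuclei$count),
    class = "viability_result"
  )
}

#' @export
print.viability_result <- function(x, ...) {
  cat(sprintf("<viability_result> %d / %d positive (%.1f%%)\n",
              x$n_positive, x$n_total, 100 * x$fraction))
  invisible(x)
}

#' @export
tidy.viability_result <- function(x, ...) {
  tibble(n_positive = x$n_positive, n_total = x$n_total, fraction = x$fraction)
}

#' Per-frame viability series over a fluorescence video
#'
#' @param video A [video_stack()] whose frames are the viability channel.
#' @param nuclei A [count_nuclei()] result or a single positive count.
#' @param min_area_px Passed to [segment_positive_nuclei()].
#' @return A tibble with `frame`, `time_min`, `n_positive` and `fraction`.
#' @export
viability_series <- function(video, nuclei, min_area_px = 10) {
  stopifnot(inherits(video, "video_stack"))
  if (is.numeric(nuclei)) nuclei <- count_nuclei(nuclei)
  d <- dim(video$frames)
  res <- purrr::map(seq_len(d[1]), function(i) {
    m <- segment_positive_nuclei(video$frames[i, , ], min_area_px)
    v <- viability_fraction(m, nuclei)
    tibble(frame = i - 1L, n_positive = v$n_positive, fraction = v$fraction)
  })
  bind_rows(res) |>
    mutate(time_min = video$origin_time +
             .data$frame * video$frame_interval, .after = "frame")
}
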