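#' Min-max normalisation to the unit interval
#'
#' Maps the minimum of the chosen scope to 0 and the maximum to 1. A constant
#' scope (zero range) maps to all zeros. With `scope = "frame"` each frame is
#' normalised independently, which makes all downstream analysis invariant to
#' per-frame positive affine rescaling of the raw intensities; with
#' `scope = "video"` one global min/max is used so temporal differences remain
#' comparable across frames.
#'
#' @param frames A matrix (single frame) or a `(time, row, column)` array.
#' @param scope `"frame"` (per-frame) or `"video"` (one global min/max).
#' @return An object of the same shape with values in `[0, 1]`.
#' @export
normalize_minmax <- function(frames, scope = c("frame", "video")) {
  scope <- match.arg(scope)
  if (length(frames) == 0L) abort("`frames` must be non-empty.")
  rescale <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) return(array(0, dim = dim(x) %||% length(x)))
    (x - r[1]) / (r[2] - r[1])
  }
  if (is.matrix(frames) || scope == "video" || length(dim(frames)) != 3L) {
    return(rescale(frames))
  }
  out <- frames
  for (i in seq_len(dim(frames)[1])) out[i, , ] <- rescale(frames[i, , ])
  out
}

# Gaussian low-pass with the kernel radius capped to the image size (EBImage
# requires the filter to fit inside the image); borders are replicated so the
# estimated illumination field does not wrap around. Very wide kernels
# (sigma > 32 px) are evaluated on a bilinearly decimated grid and
# interpolated back: at that scale the low-pass output is far smoother than
# the decimation step, so the approximation error is negligible relative to
# the field being estimated.
gaussian_lowpass <- function(frame, sigma) {
  d <- dim(frame)
  dec <- 1L
  if (sigma > 32) {
    dec <- 2L^ceiling(log2(sigma / 32))
    dec <- min(dec, max(1L, min(d) %/% 16L))
  }
  if (dec > 1L) {
    small <- as.matrix(EBImage::resize(frame, w = ceiling(d[1] / dec),
                                       h = ceiling(d[2] / dec)))
    low <- gaussian_lowpass(small, sigma / dec)
    return(as.matrix(EBImage::resize(low, w = d[1], h = d[2])))
  }
  radius <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  cap <- (min(d) %/% 2L) * 2L - 1L
  radius <- min(radius, cap)
  as.matrix(EBImage::gblur(frame, sigma = sigma, radius = radius,
                           boundary = "replicate"))
}

#' Bleach / illumination-field correction
#'
#' Estimates the slowly varying illumination field with a wide Gaussian
#' low-pass filter and subtracts it from the frame. The output may contain
#' negative values; the preprocessing chain renormalises afterwards.
#'
#' @param frame Numeric matrix.
#' @param sigma Gaussian standard deviation in pixels. Must be much larger
#'   than the structures of interest (a 20 um cell is ~36 px at 0.55 um/px);
#'   the chain default is `min(height, width) / 4`.
#' @return A matrix of illumination-corrected residuals.
#' @export
bleach_correct <- function(frame, sigma) {
  check_positive_scalar(sigma, "sigma")
  frame - gaussian_lowpass(frame, sigma)
}

#' Contrast-limited adaptive histogram equalisation (CLAHE)
#'
#' Local contrast enhancement on square tiles with a clipped histogram.
#' `clip` is the fraction of a tile's pixels any single histogram bin may
#' hold before the excess is redistributed (the convention used by
#' scikit-image); it is converted to the bin-count-scaled limit the
#' underlying implementation expects. Images whose sides are not multiples of
#' the tile size are edge-padded and cropped back.
#'
#' @param frame Numeric matrix with values in `[0, 1]`.
#' @param kernel Tile side in pixels (default 25, i.e. 25 x 25 tiles).
#' @param clip Clip limit as a fraction of tile pixels (default 0.01).
#' @param bins Histogram bins (default 256).
#' @return A matrix in `[0, 1]`.
#' @export
enhance_contrast_clahe <- function(frame, kernel = 25, clip = 0.01,
                                   bins = 256) {
  if (min(frame) < 0 || max(frame) > 1) {
    abort("CLAHE input must lie within [0, 1].")
  }
  if (diff(range(frame)) == 0) return(frame)
  d <- dim(frame)
  nx <- max(1L, as.integer(ceiling(d[1] / kernel)))
  ny <- max(1L, as.integer(ceiling(d[2] / kernel)))
  pad <- frame[c(seq_len(d[1]), rep(d[1], nx * kernel - d[1])),
               c(seq_len(d[2]), rep(d[2], ny * kernel - d[2])), drop = FALSE]
  out <- EBImage::clahe(pad, nx = nx, ny = ny, bins = bins,
                        limit = clip * bins)
  as.matrix(out)[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
}

#' Gaussian smoothing
#'
#' @param frame Numeric matrix.
#' @param sigma Standard deviation in pixels; 0 returns the frame unchanged.
#' @return A smoothed matrix.
#' @export
smooth_gaussian <- function(frame, sigma = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0) {
    abort("`sigma` must be a single non-negative number.")
  }
  if (sigma == 0) return(frame)
  gaussian_lowpass(frame, sigma)
}

#' Preprocess a video for activity analysis
#'
#' Applies, in order: per-frame min-max normalisation, per-frame illumination
#' (bleach) correction, whole-video min-max renormalisation, per-frame CLAHE,
#' and per-frame Gaussian smoothing. Negative values created by the bleach
#' correction are retained and rescaled by the whole-video renormalisation;
#' any residual values outside `[0, 1]` after smoothing (boundary effects)
#' are clipped. Each applied step and its parameters are recorded in the
#' `provenance` table.
#'
#' @param video A [video_stack()] with at least 2 frames.
#' @param sigma_bleach Bleach-correction Gaussian sigma in pixels
#'   (default `min(height, width) / 4`).
#' @param clahe_kernel,clahe_clip,clahe_bins CLAHE parameters
#'   (defaults 25 px, 0.01, 256).
#' @param sigma_smooth Final smoothing sigma in pixels (default 1).
#' @return An object of class `preprocessed_video` with fields `frames`
#'   (array in `[0, 1]`), `provenance` (tibble of steps), and the source
#'   calibration.
#' @export
preprocess_for_activity <- function(video,
                                    sigma_bleach = NULL,
                                    clahe_kernel = 25, clahe_clip = 0.01,
                                    clahe_bins = 256, sigma_smooth = 1) {
  stopifnot(inherits(video, "video_stack"))
  d <- dim(video$frames)
  if (d[1] < 2L) abort("Temporal analysis needs at least 2 frames.")
  sigma_bleach <- sigma_bleach %||% (min(d[2], d[3]) / 4)
  check_positive_scalar(sigma_bleach, "sigma_bleach")

  x <- normalize_minmax(video$frames, scope = "frame")
  for (i in seq_len(d[1])) x[i, , ] <- bleach_correct(x[i, , ], sigma_bleach)
  x <- normalize_minmax(x, scope = "video")
  for (i in seq_len(d[1])) {
    f <- enhance_contrast_clahe(x[i, , ], kernel = clahe_kernel,
                                clip = clahe_clip, bins = clahe_bins)
    x[i, , ] <- smooth_gaussian(f, sigma_smooth)
  }
  x[x < 0] <- 0
  x[x > 1] <- 1

  provenance <- tibble(
    step = c("normalize_minmax", "bleach_correct", "normalize_minmax",
             "enhance_contrast_clahe", "smooth_gaussian"),
    scope = c("frame", "frame", "video", "frame", "frame"),
    parameters = c("", sprintf("sigma=%g", sigma_bleach), "",
                   sprintf("kernel=%g,clip=%g,bins=%g", clahe_kernel,
                           clahe_clip, clahe_bins),
                   sprintf("sigma=%g", sigma_smooth))
  )
  structure(
    list(frames = x, provenance = provenance, pixel_size = video$pixel_size,
         frame_interval = video$frame_interval,
         origin_time = video$origin_time, identifier = video$identifier),
    class = "preprocessed_video"
  )
}

#' @export
print.preprocessed_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<preprocessed_video '%s'> %d frames of %d x %d px, values in [0, 1]\n",
              x$identifier, d[1], d[2], d[3]))
  cat("steps:", paste(x$provenance$step, collapse = " -> "), "\n")
  invisible(x)
}

#' Resample a video to a coarser pixel size
#'
#' Bilinear downsampling to (approximately) a target pixel size, as used to
#' bring videos onto the grid a detector was trained on. The output shape is
#' `round(physical_extent / target)` per axis and the realised pixel size is
#' recomputed from that shape, so it may differ from `target` by less than
#' one percent. Upsampling requests are rejected.
#'
#' @param video A [video_stack()].
#' @param target Target pixel size in micrometres (`>=` source pixel size).
#' @return A [video_stack()] on the coarser grid.
#' @export
resample_to_pixel_size <- function(video, target) {
  stopifnot(inherits(video, "video_stack"))
  check_positive_scalar(target, "target")
  if (target < video$pixel_size * (1 - 1e-9)) {
    abort("Upsampling is not supported: `target` must be >= the pixel size.")
  }
  if (abs(target - video$pixel_size) < 1e-9 * target) return(video)
  d <- dim(video$frames)
  extent <- d[2:3] * video$pixel_size
  shape <- pmax(1L, as.integer(round(extent / target)))
  realized <- extent / shape
  if (abs(realized[1] - realized[2]) > 0.01 * target) {
    abort("Resampling would introduce >1% pixel anisotropy.")
  }
  out <- array(0, dim = c(d[1], shape))
  for (i in seq_len(d[1])) {
    out[i, , ] <- as.matrix(EBImage::resize(video$frames[i, , ],
                                            w = shape[1], h = shape[2]))
  }
  video_stack(out, pixel_size = mean(realized),
              frame_interval = video$frame_interval,
              origin_time = video$origin_time, identifier = video$identifier)
}
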