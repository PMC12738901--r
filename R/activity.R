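#' Frame-to-frame cellular activity
#'
#' Activity between two preprocessed frames is the mean over all pixels of
#' the squared per-pixel intensity difference,
#' `activity = mean((a - b)^2)`. It is symmetric, non-negative, zero exactly
#' when the frames are identical, and comparable across image resolutions
#' because it is a per-pixel mean.
#'
#' @param a,b Numeric matrices of identical shape (preprocessed frames).
#' @return A non-negative scalar.
#' @export
frame_activity <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    abort("Frames must have identical dimensions.")
  }
  mean((a - b)^2)
}

#' Cellular activity trace of a video
#'
#' Computes [frame_activity()] for every consecutive frame pair. Entry `i`
#' (at the time of frame `i`, 0-based) compares frame `i` with frame `i - 1`;
#' frame 0 has no predecessor, its activity is defined as 0 and the cumulative
#' activity therefore starts at the first frame pair. The cumulative column is
#' the running sum of activity, which is non-decreasing.
#'
#' @param video A `preprocessed_video` (from [preprocess_for_activity()]) or
#'   any object with `frames`, `frame_interval` and `origin_time` fields.
#' @return A tibble of class `activity_trace` with columns `time_min`,
#'   `activity` and `cumulative` (one row per frame pair).
#' @export
activity_trace <- function(video) {
  frames <- video$frames
  d <- dim(frames)
  if (is.null(d) || length(d) != 3L || d[1] < 2L) {
    abort("Activity needs a video with at least 2 frames.")
  }
  act <- vapply(seq_len(d[1] - 1L),
                function(i) frame_activity(frames[i + 1L, , ], frames[i, , ]),
                numeric(1))
  out <- tibble(
    time_min = (video$origin_time %||% 0) +
      seq_len(d[1] - 1L) * video$frame_interval,
    activity = act,
    cumulative = cumsum(act)
  )
  structure(out, class = c("activity_trace", class(out)),
            identifier = video$identifier %||% "fov")
}

#' Cumulative activity at a report time
#'
#' Returns the cumulative activity at the last frame pair whose time does not
#' exceed `t_minutes`. The conventional report time is 420 min (7 h
#' post-exposure).
#'
#' @param trace An [activity_trace()] tibble.
#' @param t_minutes Report time in minutes (default 420).
#' @return A scalar cumulative activity.
#' @export
cumulative_activity_at <- function(trace, t_minutes = 420) {
  stopifnot(is.data.frame(trace), all(c("time_min", "cumulative") %in%
                                        names(trace)))
  if (t_minutes < trace$time_min[1]) {
    abort("`t_minutes` precedes the first frame pair of the trace.")
  }
  idx <- max(which(trace$time_min <= t_minutes))
  trace$cumulative[idx]
}

#' Normalise per-FOV summaries against each replica's control
#'
#' Within each replica, values are divided by the mean of the control
#' condition, so the control maps to mean 1 and exposed conditions become
#' fold-changes relative to their own replica. This makes replicas with
#' different raw intensity scales comparable.
#'
#' @param data A data frame of per-FOV summaries.
#' @param value Name of the value column (string).
#' @param condition Name of the condition-label column.
#' @param replica Name of the replica column.
#' @param control Label of the control condition (default `"control"`).
#' @return `data` with an added `<value>_norm` column.
#' @export
normalize_per_replica <- function(data, value = "cumulative_activity",
                                  condition = "condition",
                                  replica = "replica", control = "control") {
  stopifnot(is.data.frame(data),
            all(c(value, condition, replica) %in% names(data)))
  out <- data |>
    group_by(.data[[replica]]) |>
    mutate("{value}_norm" := {
      ctrl <- .data[[value]][.data[[condition]] == control]
      if (length(ctrl) == 0L) {
        abort(sprintf("Replica '%s' has no '%s' condition to normalise against.",
                      unique(.data[[replica]]), control))
      }
      .data[[value]] / mean(ctrl)
    }) |>
    ungroup()
  out
}

#' @export
autoplot.activity_trace <- function(object, cumulative = FALSE, ...) {
  y <- if (cumulative) "cumulative" else "activity"
  ggplot(object, aes(x = .data$time_min, y = .data[[y]])) +
    geom_line() +
    labs(x = "Time (min)",
         y = if (cumulative) "Cumulative activity" else "Activity",
         title = attr(object, "identifier"))
}
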