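#' Cell-rounding fraction across time, C(t)
#'
#' For every frame, the number of round-cell detections divided by the fixed
#' total-cell count of the field of view. The denominator is counted once (at
#' the first frame), so in pathological inputs the fraction may exceed 1;
#' this is allowed and flagged with a warning rather than rescaled.
#'
#' @param detections A [masks_to_detections()] table (or any tibble with a
#'   0-based `frame` column).
#' @param nuclei A [count_nuclei()] result (or a single positive count).
#' @param n_frames Total number of frames; defaults to the detection table's
#'   `n_frames` attribute.
#' @param frame_interval,origin_time Temporal calibration; default to the
#'   detection table's attributes.
#' @return A tibble of class `rounding_curve` with columns `time_min`,
#'   `n_round` and `fraction`, and the denominator in attribute `n_nuclei`.
#' @export
rounding_curve <- function(detections, nuclei, n_frames = NULL,
                           frame_interval = NULL, origin_time = NULL) {
  if (is.numeric(nuclei)) nuclei <- count_nuclei(nuclei)
  if (nuclei$count <= 0) abort("C(t) needs a positive total-cell count.")
  n_frames <- n_frames %||% attr(detections, "n_frames")
  frame_interval <- frame_interval %||% attr(detections, "frame_interval")
  origin_time <- origin_time %||% attr(detections, "origin_time") %||% 0
  if (is.null(n_frames) || is.null(frame_interval)) {
    abort("`n_frames` and `frame_interval` are required.")
  }
  counts <- integer(n_frames)
  if (nrow(detections) > 0) {
    tab <- table(factor(detections$frame, levels = 0:(n_frames - 1L)))
    counts <- as.integer(tab)
  }
  out <- tibble(
    time_min = origin_time + (seq_len(n_frames) - 1L) * frame_interval,
    n_round = counts,
    fraction = counts / nuclei$count
  )
  if (any(out$fraction > 1)) {
    warn("C(t) exceeds 1 for some frames: more detections than counted cells.")
  }
  structure(out, class = c("rounding_curve", class(out)),
            n_nuclei = nuclei$count)
}

#' Peak time of a rounding curve
#'
#' The earliest time at which C(t) attains its maximum. Phototoxic delays
#' manifest as rightward shifts of this peak, so ties resolve to the earliest
#' maximum (the conservative estimator). When the maximum fraction is below
#' `floor` the curve is considered peakless (as happens under widespread
#' cell-cycle arrest) and `NA` is returned with a warning.
#'
#' @param curve A [rounding_curve()].
#' @param floor Minimum fraction for a peak to count (default 0.01).
#' @return Peak time in minutes, or `NA_real_` when no peak is detected.
#' @export
peak_time <- function(curve, floor = 0.01) {
  stopifnot(is.data.frame(curve),
            all(c("time_min", "fraction") %in% names(curve)))
  m <- max(curve$fraction)
  if (m < floor) {
    warn(sprintf("No rounding peak: max fraction %.4g is below the %.4g floor.",
                 m, floor))
    return(NA_real_)
  }
  curve$time_min[which.max(curve$fraction)]
}

#' Mother and daughter population curves
#'
#' Per-frame counts of detections in each size class, plus the mean
#' equivalent diameter per frame. Daughter cells emerging after division make
#' the daughter count overtake the mother count; photodamage delays that
#' crossing.
#'
#' @param detections A [masks_to_detections()] table.
#' @return A tibble with columns `frame`, `time_min`, `n_mother`,
#'   `n_daughter` and `mean_diameter_um` (classes `population_curves`).
#' @export
population_curves <- function(detections) {
  if (nrow(detections) == 0L) {
    out <- tibble(frame = integer(), time_min = numeric(),
                  n_mother = integer(), n_daughter = integer(),
                  mean_diameter_um = numeric())
    return(structure(out, class = c("population_curves", class(out))))
  }
  out <- detections |>
    group_by(.data$frame, .data$time_min) |>
    summarise(
      n_mother = sum(.data$size_class == "mother"),
      n_daughter = sum(.data$size_class == "daughter"),
      mean_diameter_um = mean(.data$diameter_um),
      .groups = "drop"
    ) |>
    arrange(.data$frame)
  structure(out, class = c("population_curves", class(out)))
}

#' Classify tracked rounding events as divided or arrested
#'
#' A tracked cell enters mitotic rounding at `t_round_start`; if two daughter
#' cells become resolvable at `t_division` within the observation window the
#' event is a division with duration `t_division - t_round_start`, otherwise
#' the cell is considered cell-cycle arrested.
#'
#' @param t_round_start Minutes of first rounding frame (vector).
#' @param t_division Minutes of resolvable daughter emergence, `NA` if never
#'   observed.
#' @param t_end End of the observation window in minutes (scalar or vector).
#' @param event_id Optional identifiers.
#' @return A tibble of cell events with columns `event_id`, `t_round_start`,
#'   `t_division`, `outcome` and `division_duration`.
#' @export
classify_event <- function(t_round_start, t_division = NA_real_,
                           t_end = 480, event_id = NULL) {
  n <- length(t_round_start)
  t_division <- rep_len(t_division, n)
  t_end <- rep_len(t_end, n)
  bad <- !is.na(t_division) & t_division < t_round_start
  if (any(bad)) {
    abort("`t_division` precedes `t_round_start` for some events.")
  }
  divided <- !is.na(t_division) & t_division <= t_end
  tibble(
    event_id = event_id %||% seq_len(n),
    t_round_start = t_round_start,
    t_division = ifelse(divided, t_division, NA_real_),
    outcome = ifelse(divided, "divided", "arrested"),
    division_duration = ifelse(divided, t_division - t_round_start, NA_real_)
  )
}

#' Fraction of cells that divided by a given time
#'
#' The mother-to-daughter transition fraction: divided events with
#' `t_division <= by_time`, over all tracked events (divided or arrested).
#'
#' @param events A [classify_event()] tibble.
#' @param by_time Cut-off in minutes (default 50).
#' @return A fraction in `[0, 1]`.
#' @export
transition_fraction <- function(events, by_time = 50) {
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0L) abort("`events` is empty.")
  mean(events$outcome == "divided" & !is.na(events$t_division) &
         events$t_division <= by_time)
}

#' Read a tracked-event annotation table
#'
#' Columns: `event_id`, `t_round_start_min`, optional `t_division_min`
#' (empty = never divided) and `t_end_min`.
#'
#' @param path CSV file path.
#' @return A [classify_event()] tibble.
#' @export
read_events_csv <- function(path) {
  raw <- read_table_csv(path)
  need <- c("event_id", "t_round_start_min", "t_end_min")
  if (!all(need %in% names(raw))) {
    abort(sprintf("Events CSV must contain columns: %s.",
                  paste(need, collapse = ", ")))
  }
  t_div <- if ("t_division_min" %in% names(raw)) raw$t_division_min else NA_real_
  classify_event(raw$t_round_start_min, t_div, raw$t_end_min, raw$event_id)
}

#' @export
autoplot.rounding_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$time_min, y = .data$fraction)) +
    geom_line() +
    labs(x = "Time (min)", y = "Round-cell fraction C(t)")
}

#' @export
autoplot.population_curves <- function(object, ...) {
  long <- object |>
    pivot_longer(c("n_mother", "n_daughter"), names_to = "size_class",
                 values_to = "n", names_prefix = "n_")
  ggplot(long, aes(x = .data$time_min, y = .data$n,
                   colour = .data$size_class)) +
    geom_line() +
    labs(x = "Time (min)", y = "Detections", colour = "Size class")
}

#' @export
glance.rounding_curve <- function(x, ...) {
  pk <- suppressWarnings(peak_time(x))
  tibble(n_nuclei = attr(x, "n_nuclei"), peak_time_min = pk,
         peak_fraction = max(x$fraction), n_frames = nrow(x))
}
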