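#' Define a synthetic time-lapse scenario
#'
#' Describes a simulated field of view of synchronised adherent cells. The
#' defaults emulate the acquisition conditions the analysis targets: ~126
#' cells per FOV imaged every 4 min for 8 h at 0.55 um/px, mother cells of
#' ~20 um dividing into two ~15 um daughters after ~30 min of mitotic
#' rounding, with the population's round-cell fraction peaking near 50 min
#' after synchronisation release.
#'
#' `rounding_time_mean` parameterises the peak of the observable round-cell
#' fraction C(t). Because detections include both round mothers and the two
#' briefly-round daughters, the expected detection curve peaks later than the
#' onset law; the generator therefore places the onset distribution so that
#' the expected C(t) attains its maximum at the configured value (see
#' [onset_distribution()]). `extra_delay` shifts all onsets rightwards and
#' `arrest_prob` marks cells that round but never divide - the two knobs that
#' emulate photodamage.
#'
#' @param n_cells Cells in the field of view (default 126).
#' @param field Field size in pixels, `(rows, cols)` (default 512 x 512).
#' @param pixel_size Micrometres per pixel (default 0.55).
#' @param frame_interval Minutes between frames (default 4).
#' @param duration Length of the time lapse in minutes (default 480 = 8 h).
#' @param rounding_time_mean Peak time of the round-cell fraction in minutes
#'   (default 50).
#' @param rounding_time_sd Spread of rounding onsets in minutes (default 10).
#' @param rounding_time_dist `"normal"` (default) or `"gamma"` for skewed,
#'   high-dose-like onset laws (same location and sd; the peak calibration is
#'   approximate for the skewed law).
#' @param rounding_duration Minutes a mother stays round before dividing
#'   (default 30).
#' @param daughter_round_duration Minutes daughters remain round and
#'   detectable after division before re-spreading (default 16, within the
#'   15-30 min window over which the mother-to-daughter transition is
#'   typically resolvable).
#' @param arrest_prob Probability a cell rounds but never divides (default 0).
#' @param extra_delay Minutes added to every rounding onset, a photodamage
#'   surrogate (default 0).
#' @param mother_diameter,daughter_diameter Cell diameters in um
#'   (defaults 20 and 15; daughters must be smaller).
#' @param gradient_amplitude Relative amplitude of a static illumination
#'   gradient across the field (default 0.1).
#' @param drift_factor Multiplicative brightness drift from first to last
#'   frame (default 1, i.e. none).
#' @param noise_sd Gaussian sensor noise standard deviation in intensity
#'   units (default 0.01).
#' @param min_separation_um Minimum centre-to-centre cell distance in um.
#'   The default (`mother_diameter` plus one pixel) emulates a near-confluent
#'   culture where rounded cells may touch; raise it to
#'   `2 * daughter_diameter` or more for fields whose rounded cells are
#'   guaranteed not to overlap at any stage.
#' @param seed Integer seed; every random draw of the scenario flows from it.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_cells = 126, field = c(512, 512),
                               pixel_size = 0.55, frame_interval = 4,
                               duration = 480, rounding_time_mean = 50,
                               rounding_time_sd = 10,
                               rounding_time_dist = c("normal", "gamma"),
                               rounding_duration = 30,
                               daughter_round_duration = 16,
                               arrest_prob = 0, extra_delay = 0,
                               mother_diameter = 20, daughter_diameter = 15,
                               gradient_amplitude = 0.1, drift_factor = 1,
                               noise_sd = 0.01, min_separation_um = NULL,
                               seed = 1L) {
  rounding_time_dist <- match.arg(rounding_time_dist)
  stopifnot(n_cells >= 1, length(field) == 2L, all(field >= 32))
  check_positive_scalar(pixel_size, "pixel_size")
  check_positive_scalar(frame_interval, "frame_interval")
  check_positive_scalar(duration, "duration")
  if (arrest_prob < 0 || arrest_prob > 1) abort("`arrest_prob` must be in [0, 1].")
  if (daughter_diameter >= mother_diameter) {
    abort("`daughter_diameter` must be smaller than `mother_diameter`.")
  }
  if (daughter_diameter <= 0) abort("Diameters must be positive.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  min_separation_um <- min_separation_um %||% (mother_diameter + 2 * pixel_size)
  if (min_separation_um < mother_diameter) {
    abort("`min_separation_um` below `mother_diameter` would overlap mothers.")
  }
  structure(
    list(n_cells = as.integer(n_cells), field = as.integer(field),
         pixel_size = pixel_size, frame_interval = frame_interval,
         duration = duration, rounding_time_mean = rounding_time_mean,
         rounding_time_sd = rounding_time_sd,
         rounding_time_dist = rounding_time_dist,
         rounding_duration = rounding_duration,
         daughter_round_duration = daughter_round_duration,
         arrest_prob = arrest_prob, extra_delay = extra_delay,
         mother_diameter = mother_diameter,
         daughter_diameter = daughter_diameter,
         gradient_amplitude = gradient_amplitude,
         drift_factor = drift_factor, noise_sd = noise_sd,
         min_separation_um = min_separation_um,
         seed = as.integer(seed)),
    class = "synthetic_scenario"
  )
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat(sprintf(
    "<synthetic_scenario> %d cells, %d x %d px @ %.3g um, %g min x %g min, peak %g min (sd %g), arrest %.2g, delay %g, seed %d\n",
    x$n_cells, x$field[1], x$field[2], x$pixel_size, x$frame_interval,
    x$duration, x$rounding_time_mean, x$rounding_time_sd, x$arrest_prob,
    x$extra_delay, x$seed))
  invisible(x)
}

# Offset between the onset-law location and the peak of the expected
# detection fraction: mothers are round for `D` minutes and each division
# contributes two daughters for `dd` more, so with onset CDF F the expected
# per-cell detection count is
#   (1 - a) * (F(t) + F(t - D) - 2 F(t - D - dd)) + a * F(t).
# The argmax of that curve relative to the onset location is found on a grid.
peak_offset <- function(sd, duration, daughter_duration, arrest_prob) {
  u <- seq(-4 * sd, duration + daughter_duration + 4 * sd, by = 0.01)
  h <- (1 - arrest_prob) *
    (pnorm(u / sd) + pnorm((u - duration) / sd) -
       2 * pnorm((u - duration - daughter_duration) / sd)) +
    arrest_prob * pnorm(u / sd)
  u[which.max(h)]
}

#' Onset law of a synthetic scenario
#'
#' The distribution the generator draws mitotic-rounding onsets from. Its
#' location is the configured C(t) peak time minus the peak offset implied by
#' the rounding and daughter-round durations (plus `extra_delay`), truncated
#' at zero.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A list with `dist`, `location` (pre-truncation), `sd` and the
#'   truncation bound `lower`.
#' @export
onset_distribution <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  off <- peak_offset(scenario$rounding_time_sd, scenario$rounding_duration,
                     scenario$daughter_round_duration, scenario$arrest_prob)
  list(dist = scenario$rounding_time_dist,
       location = scenario$rounding_time_mean - off + scenario$extra_delay,
       sd = scenario$rounding_time_sd, lower = 0)
}

#' Expected round-cell fraction of a scenario
#'
#' The expectation of C(t) under the scenario's event law (normal onsets;
#' truncation at zero included). Useful as an analytic reference for the
#' empirical curves the quantification layer recovers.
#'
#' @param scenario A [synthetic_scenario()].
#' @param times Times in minutes.
#' @return Numeric vector of expected fractions.
#' @export
expected_rounding_fraction <- function(scenario, times) {
  od <- onset_distribution(scenario)
  p0 <- pnorm(0, od$location, od$sd)
  Ftr <- function(x) {
    pmax(0, (pnorm(x, od$location, od$sd) - p0) / (1 - p0))
  }
  D <- scenario$rounding_duration
  dd <- scenario$daughter_round_duration
  a <- scenario$arrest_prob
  (1 - a) * (Ftr(times) + Ftr(times - D) - 2 * Ftr(times - D - dd)) +
    a * Ftr(times)
}

sample_onsets <- function(scenario, n) {
  od <- onset_distribution(scenario)
  if (od$dist == "normal") {
    p0 <- pnorm(0, od$location, od$sd)
    if (p0 > 1 - 1e-9) {
      abort(paste0("The onset law truncates almost entirely below zero: ",
                   "`rounding_time_mean` is too early for the configured ",
                   "rounding/daughter durations."))
    }
    qnorm(p0 + runif(n) * (1 - p0), od$location, od$sd)
  } else {
    shape <- (od$location / od$sd)^2
    rate <- od$location / od$sd^2
    rgamma(n, shape = shape, rate = rate)
  }
}

#' Sample the per-cell event schedule of a scenario
#'
#' Draws, per cell, the mitotic-rounding onset time and whether the cell
#' arrests; non-arrested cells divide `rounding_duration` minutes after
#' rounding onset. Cells whose division would fall beyond the observation
#' window are arrested by the end-of-window rule. The schedule is fully
#' determined by the scenario's seed.
#'
#' @param scenario A [synthetic_scenario()].
#' @return A tibble of cell events (see [classify_event()]) with an extra
#'   `t_round_end` column: when a cell stops being round (division time, or
#'   the end of the video for arrested cells).
#' @export
sample_events <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  local_seed(scenario$seed, {
    n <- scenario$n_cells
    onset <- sample_onsets(scenario, n)
    arrested <- runif(n) < scenario$arrest_prob
    t_div <- ifelse(arrested, NA_real_, onset + scenario$rounding_duration)
    ev <- classify_event(onset, t_div, t_end = scenario$duration)
    ev$t_round_end <- ifelse(ev$outcome == "divided", ev$t_division,
                             scenario$duration)
    ev
  })
}

# Cell state at a given time: 0 adherent (pre-rounding), 1 round mother,
# 2 two round daughters, 3 re-spread post-division.
cell_state <- function(events, scenario, time_min) {
  out <- integer(nrow(events))
  round_m <- events$t_round_start <= time_min & time_min < events$t_round_end
  out[round_m] <- 1L
  div <- events$outcome == "divided" & !is.na(events$t_division)
  d_round <- div & events$t_division <= time_min &
    time_min < events$t_division + scenario$daughter_round_duration
  out[d_round] <- 2L
  spread <- div & time_min >= events$t_division + scenario$daughter_round_duration
  out[spread] <- 3L
  out
}

# Jittered-grid placement: guarantees a minimum centre separation (and an
# optional inset from the borders) or errors.
place_cells <- function(n, field, min_sep_px, margin_px = 0) {
  k <- ceiling(sqrt(n))
  inner <- field - 2 * margin_px
  sp <- inner / k
  if (min(sp) < min_sep_px) {
    abort(sprintf(
      "Cannot place %d cells of separation %.1f px in a %d x %d field.",
      n, min_sep_px, field[1], field[2]))
  }
  slots <- sample.int(k * k, n)
  gi <- (slots - 1L) %% k
  gj <- (slots - 1L) %/% k
  jit <- pmax((sp - min_sep_px) / 2, 0)
  cbind(row = margin_px + (gi + 0.5) * sp[1] + runif(n, -1, 1) * jit[1],
        col = margin_px + (gj + 0.5) * sp[2] + runif(n, -1, 1) * jit[2])
}

# Precomputed stamp geometry: linear indices (into a field-sized matrix) of a
# ring band and its interior around `centre`, clipped to the field.
ring_stamp <- function(centre, radius_px, field) {
  r <- ceiling(radius_px) + 2L
  rows <- max(1L, floor(centre[1] - r)):min(field[1], ceiling(centre[1] + r))
  cols <- max(1L, floor(centre[2] - r)):min(field[2], ceiling(centre[2] + r))
  dist <- sqrt(outer((rows - centre[1])^2, (cols - centre[2])^2, "+"))
  idx <- outer(rows, (cols - 1L) * field[1], "+")
  list(band = idx[dist >= radius_px - 1.5 & dist <= radius_px + 0.5],
       inner = idx[dist < radius_px - 1.5])
}

# Additive soft blob (adherent-cell texture).
blob_stamp <- function(centre, radius_px, amplitude, field) {
  r <- ceiling(2 * radius_px)
  rows <- max(1L, floor(centre[1] - r)):min(field[1], ceiling(centre[1] + r))
  cols <- max(1L, floor(centre[2] - r)):min(field[2], ceiling(centre[2] + r))
  dist2 <- outer((rows - centre[1])^2, (cols - centre[2])^2, "+")
  idx <- outer(rows, (cols - 1L) * field[1], "+")
  list(idx = as.vector(idx),
       add = amplitude * exp(-as.vector(dist2) / (2 * radius_px^2)))
}

#' Render a synthetic brightfield time lapse with ground truth
#'
#' Renders the scenario into a calibrated video: adherent cells appear as
#' faint low-contrast blobs, rounding cells as bright rings with a darker
#' interior (the defocused-brightfield halo look of mitotic cells), and
#' divided cells as two daughter rings displaced by one daughter radius. A
#' static illumination gradient, a linear temporal brightness drift and
#' Gaussian sensor noise are applied on top. Ground-truth masks label round
#' cells only (the detector's target class), with labels unique within each
#' frame, alongside the true cell count and event schedule.
#'
#' @param scenario A [synthetic_scenario()].
#' @param events Optional precomputed [sample_events()] schedule.
#' @return A list with `video` (a [video_stack()]), `truth` (list of `masks`
#'   as [label_mask_stack()], `nuclei` as [count_nuclei()], `events`, and the
#'   cell `positions`).
#' @export
render_video <- function(scenario, events = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  events <- events %||% sample_events(scenario)
  ps <- scenario$pixel_size
  field <- scenario$field
  r_m <- scenario$mother_diameter / 2 / ps
  r_d <- scenario$daughter_diameter / 2 / ps
  n_frames <- as.integer(scenario$duration / scenario$frame_interval) + 1L
  n <- scenario$n_cells

  local_seed(scenario$seed + 1L, {
    pos <- place_cells(n, field,
                       min_sep_px = scenario$min_separation_um / ps,
                       margin_px = r_m + 2)
    angle <- runif(n, 0, 2 * pi)
    # near a border, split daughters parallel to it so neither leaves the
    # field (corner cells prefer the nearer border)
    edge <- 2 * r_d + 3
    near_row <- pmin(pos[, 1], field[1] - pos[, 1]) < edge
    near_col <- pmin(pos[, 2], field[2] - pos[, 2]) < edge
    angle[near_row] <- pi / 2
    angle[near_col & !near_row] <- 0
    tex_r <- r_m * runif(n, 0.8, 1.3)
    tex_a <- runif(n, 0.04, 0.08)

    # static per-cell stamp caches
    mother_ring <- lapply(seq_len(n), function(i) ring_stamp(pos[i, ], r_m,
                                                             field))
    offs <- r_d * cbind(cos(angle), sin(angle))
    daughter_rings <- lapply(seq_len(n), function(i) {
      list(ring_stamp(pos[i, ] + offs[i, ], r_d, field),
           ring_stamp(pos[i, ] - offs[i, ], r_d, field))
    })
    adherent <- lapply(seq_len(n), function(i) blob_stamp(pos[i, ], tex_r[i],
                                                          tex_a[i], field))
    spread <- lapply(seq_len(n), function(i) {
      a <- blob_stamp(pos[i, ] + offs[i, ], tex_r[i] * 0.8, tex_a[i], field)
      b <- blob_stamp(pos[i, ] - offs[i, ], tex_r[i] * 0.8, tex_a[i], field)
      list(idx = c(a$idx, b$idx), add = c(a$add, b$add))
    })

    grad <- 1 + scenario$gradient_amplitude *
      (matrix(seq(-0.5, 0.5, length.out = field[2]), field[1], field[2],
              byrow = TRUE) +
         0.5 * matrix(seq(-0.5, 0.5, length.out = field[1]), field[1],
                      field[2]))
    frames <- array(0, dim = c(n_frames, field))
    masks <- array(0L, dim = c(n_frames, field))
    times <- (seq_len(n_frames) - 1L) * scenario$frame_interval
    npx <- prod(field)

    for (f in seq_len(n_frames)) {
      canvas <- matrix(0.45, field[1], field[2])
      mask <- matrix(0L, field[1], field[2])
      state <- cell_state(events, scenario, times[f])
      label <- 0L
      for (i in seq_len(n)) {
        if (state[i] == 0L) {
          st <- adherent[[i]]
          canvas[st$idx] <- canvas[st$idx] + st$add
        } else if (state[i] == 1L) {
          st <- mother_ring[[i]]
          label <- label + 1L
          canvas[st$band] <- 0.9
          canvas[st$inner] <- 0.25
          mask[st$band] <- label
          mask[st$inner] <- label
        } else if (state[i] == 2L) {
          for (st in daughter_rings[[i]]) {
            label <- label + 1L
            canvas[st$band] <- 0.9
            canvas[st$inner] <- 0.25
            mask[st$band] <- label
            mask[st$inner] <- label
          }
        } else {
          st <- spread[[i]]
          canvas[st$idx] <- canvas[st$idx] + st$add
        }
      }
      drift <- if (n_frames > 1L) {
        1 + (scenario$drift_factor - 1) * (f - 1) / (n_frames - 1)
      } else 1
      canvas <- canvas * (grad * drift)
      if (scenario$noise_sd > 0) {
        canvas <- canvas + rnorm(npx, 0, scenario$noise_sd)
      }
      canvas[canvas < 0] <- 0
      canvas[canvas > 1] <- 1
      frames[f, , ] <- canvas
      masks[f, , ] <- mask
    }

    list(
      video = video_stack(frames, pixel_size = ps,
                          frame_interval = scenario$frame_interval,
                          identifier = sprintf("synthetic-seed%d",
                                               scenario$seed)),
      truth = list(
        masks = label_mask_stack(masks, pixel_size = ps,
                                 frame_interval = scenario$frame_interval),
        nuclei = count_nuclei(scenario$n_cells),
        events = events,
        positions = pos
      )
    )
  })
}

#' Ground-truth detection table of an event schedule
#'
#' Builds the detection table the ideal detector would produce for a
#' scenario, directly from the event schedule and without rasterising frames:
#' one mother-sized row per cell while it is round, and two daughter-sized
#' rows while its daughters remain round. Useful for exercising the
#' quantification layer at scale.
#'
#' @param scenario A [synthetic_scenario()].
#' @param events Optional precomputed [sample_events()] schedule.
#' @return A `detection_table` tibble (see [masks_to_detections()]).
#' @export
ground_truth_detections <- function(scenario, events = NULL) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  events <- events %||% sample_events(scenario)
  n_frames <- as.integer(scenario$duration / scenario$frame_interval) + 1L
  times <- (seq_len(n_frames) - 1L) * scenario$frame_interval
  ps <- scenario$pixel_size
  rows <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    state <- cell_state(events, scenario, times[f])
    n_m <- sum(state == 1L)
    n_d <- 2L * sum(state == 2L)
    if (n_m + n_d == 0L) next
    diam <- c(rep(scenario$mother_diameter, n_m),
              rep(scenario$daughter_diameter, n_d))
    area_um2 <- pi * (diam / 2)^2
    rows[[f]] <- tibble(
      frame = f - 1L, time_min = times[f], label = seq_len(n_m + n_d),
      area_px = round(area_um2 / ps^2), area_um2 = area_um2,
      diameter_um = diam, centroid_row = NA_real_, centroid_col = NA_real_,
      size_class = classify_size(diam)
    )
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(frame = integer(), time_min = numeric(), label = integer(),
                  area_px = numeric(), area_um2 = numeric(),
                  diameter_um = numeric(), centroid_row = numeric(),
                  centroid_col = numeric(), size_class = character())
  }
  structure(out, class = c("detection_table", class(out)),
            n_frames = n_frames, pixel_size = ps,
            frame_interval = scenario$frame_interval, origin_time = 0)
}

#' Render a synthetic viability (dye) frame with known positives
#'
#' Dye-positive nuclei are rendered as bright soft-edged discs on a dim
#' background; negative cells are invisible in this channel, as with a
#' membrane-impermeant dye. Gaussian noise is added.
#'
#' @param n_total Total cells in the FOV.
#' @param positive_fraction Fraction of dye-positive cells.
#' @param field Frame size in pixels (default 512 x 512).
#' @param pixel_size Micrometres per pixel (default 0.55).
#' @param nucleus_diameter Nucleus diameter in um (default 10).
#' @param noise_sd Gaussian noise sd (default 0.01).
#' @param seed Integer seed.
#' @return A list with `frame` (matrix) and `truth` (list of `n_total`,
#'   `n_positive`, `positions`).
#' @export
render_viability_frame <- function(n_total, positive_fraction,
                                   field = c(512, 512), pixel_size = 0.55,
                                   nucleus_diameter = 10, noise_sd = 0.01,
                                   seed = 1L) {
  stopifnot(n_total >= 1, positive_fraction >= 0, positive_fraction <= 1)
  local_seed(seed, {
    n_pos <- round(positive_fraction * n_total)
    r_px <- nucleus_diameter / 2 / pixel_size
    pos <- place_cells(n_total, field, min_sep_px = 2 * r_px + 4,
                       margin_px = r_px + 2)
    which_pos <- sample.int(n_total, n_pos)
    canvas <- matrix(0.05, field[1], field[2])
    for (i in which_pos) {
      st <- ring_stamp(pos[i, ], r_px, field)
      canvas[st$band] <- 0.85
      canvas[st$inner] <- 0.85
    }
    if (noise_sd > 0) {
      canvas <- canvas + rnorm(prod(field), 0, noise_sd)
    }
    canvas[canvas < 0] <- 0
    canvas[canvas > 1] <- 1
    list(frame = canvas,
         truth = list(n_total = n_total, n_positive = n_pos,
                      positions = pos[which_pos, , drop = FALSE]))
  })
}
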