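#' Describe an illumination regime
#'
#' An illumination regime carries everything needed to convert an exposure
#' protocol into an areal light dose: the optical power measured at the
#' sample, the exposure duration (the full exposure time for widefield, the
#' per-pixel dwell time for point scanning), and the illuminated area (the
#' field of view for widefield, the single-pixel footprint for scanning).
#'
#' @param mode `"widefield"` or `"scanning"`.
#' @param power_w Power at the sample in watts.
#' @param duration_s Exposure time (widefield) or pixel dwell time (scanning)
#'   in seconds.
#' @param area_cm2 Illuminated area in cm^2 (FOV or single pixel).
#' @param n_repeats Number of identical exposure events (default 1).
#' @param max_power_w Maximum system output in watts, for percent-of-maximum
#'   reporting (optional).
#' @param label Free-text condition label.
#' @return An object of class `illumination_regime`.
#' @export
illumination_regime <- function(mode = c("widefield", "scanning"), power_w,
                                duration_s, area_cm2, n_repeats = 1,
                                max_power_w = NA_real_, label = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(power_w) || power_w < 0) abort("`power_w` must be >= 0.")
  if (!is.numeric(duration_s) || duration_s < 0) {
    abort("`duration_s` must be >= 0.")
  }
  check_positive_scalar(area_cm2, "area_cm2")
  if (!is.numeric(n_repeats) || n_repeats < 1 || n_repeats != round(n_repeats)) {
    abort("`n_repeats` must be a positive integer.")
  }
  structure(
    list(mode = mode, power_w = power_w, duration_s = duration_s,
         area_cm2 = area_cm2, n_repeats = as.integer(n_repeats),
         max_power_w = max_power_w,
         label = label %||% sprintf("%s %.3g W", mode, power_w)),
    class = "illumination_regime"
  )
}

#' @export
print.illumination_regime <- function(x, ...) {
  cat(sprintf("<illumination_regime '%s'> %s | %.4g W x %.4g s x %d over %.4g cm^2 -> %.4g J/cm^2\n",
              x$label, x$mode, x$power_w, x$duration_s, x$n_repeats,
              x$area_cm2, areal_dose(x)))
  invisible(x)
}

#' Areal light dose of an illumination regime
#'
#' Dose in J/cm^2 is `n_repeats * power * duration / area`. For point
#' scanning this is the per-pixel areal dose (power times dwell time over the
#' single-pixel footprint), which is the convention under which fast
#' high-power and slow low-power scans of equal energy are dose-equivalent.
#'
#' @param regime An [illumination_regime()].
#' @return Dose in J/cm^2 (exact; rounding is left to the reporting layer).
#' @export
areal_dose <- function(regime) {
  stopifnot(inherits(regime, "illumination_regime"))
  regime$n_repeats * regime$power_w * regime$duration_s / regime$area_cm2
}

#' Exposure duration needed for a target dose
#'
#' Inverse of [areal_dose()] for protocol design: the duration such that a
#' single exposure of `power_w` over `area_cm2` delivers `target_j_cm2`.
#'
#' @param target_j_cm2 Target dose in J/cm^2 (>= 0).
#' @param power_w Power at the sample in watts (> 0).
#' @param area_cm2 Illuminated area in cm^2.
#' @return Duration in seconds.
#' @export
duration_for_dose <- function(target_j_cm2, power_w, area_cm2) {
  if (!is.numeric(target_j_cm2) || target_j_cm2 < 0) {
    abort("`target_j_cm2` must be >= 0.")
  }
  check_positive_scalar(power_w, "power_w")
  check_positive_scalar(area_cm2, "area_cm2")
  target_j_cm2 * area_cm2 / power_w
}

#' Pixel footprint from its side length
#'
#' @param side_um Pixel side in micrometres.
#' @return A tibble with `side_um`, `area_um2` and `area_cm2`
#'   (`1 um^2 = 1e-8 cm^2`).
#' @export
pixel_area_from_dimension <- function(side_um) {
  if (any(side_um < 0)) abort("`side_um` must be >= 0.")
  if (any(side_um == 0)) warn("Zero pixel side: degenerate footprint.")
  tibble(side_um = side_um, area_um2 = side_um^2, area_cm2 = side_um^2 * 1e-8)
}

#' Power as a percentage of the system maximum
#'
#' @param power_w Measured power (watts, same units as `max_power_w`).
#' @param max_power_w System maximum output.
#' @return Percentage rounded to one decimal (reporting convention).
#' @export
percent_of_max <- function(power_w, max_power_w) {
  check_positive_scalar(max_power_w, "max_power_w")
  round(100 * power_w / max_power_w, 1)
}

#' Dose report table for a set of regimes
#'
#' @param regimes A list of [illumination_regime()] objects.
#' @return A tibble with one row per regime: label, mode, power, duration,
#'   area, repeats, dose in J/cm^2 and percent of maximum power (when known).
#' @export
dose_table <- function(regimes) {
  if (inherits(regimes, "illumination_regime")) regimes <- list(regimes)
  purrr::map(regimes, function(r) {
    tibble(
      label = r$label, mode = r$mode, power_w = r$power_w,
      duration_s = r$duration_s, area_cm2 = r$area_cm2,
      n_repeats = r$n_repeats, dose_j_cm2 = areal_dose(r),
      percent_of_max = if (is.finite(r$max_power_w)) {
        percent_of_max(r$power_w, r$max_power_w)
      } else NA_real_
    )
  }) |> bind_rows()
}
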