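#' Build a two-or-more-condition synthetic pipeline configuration
#'
#' Conditions are declared as label plus dose/wavelength metadata plus the
#' scenario parameters that emulate the exposure (typically `extra_delay`
#' and `arrest_prob`); every other scenario field comes from `defaults`.
#'
#' @param conditions A list of lists, each with at least `label`, and
#'   optionally `dose_j_cm2`, `wavelength_nm`, `n_fov`, and
#'   [synthetic_scenario()] overrides.
#' @param control Label of the control condition.
#' @param n_fov Fields of view per condition (default 10), overridable per
#'   condition.
#' @param seed Master seed; per-FOV seeds are derived from it.
#' @param report_time Cumulative-activity report time in minutes
#'   (default 420).
#' @param transition_by Transition-fraction cut-off in minutes (default 50).
#' @param defaults Named list of [synthetic_scenario()] defaults shared by
#'   all conditions.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(conditions, control = "control", n_fov = 10,
                            seed = 1L, report_time = 420, transition_by = 50,
                            defaults = list()) {
  labels <- vapply(conditions, function(cc) cc$label %||% NA_character_,
                   character(1))
  if (anyNA(labels) || anyDuplicated(labels)) {
    abort("Every condition needs a unique `label`.")
  }
  if (!control %in% labels) {
    abort(sprintf("Control condition '%s' is missing from the configuration.",
                  control))
  }
  structure(
    list(conditions = conditions, control = control, n_fov = n_fov,
         seed = as.integer(seed), report_time = report_time,
         transition_by = transition_by, defaults = defaults),
    class = "pipeline_config"
  )
}

run_stage <- function(stage, input, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed on %s: %s", stage, input,
                  conditionMessage(e)))
  })
}

#' Run the end-to-end synthetic analysis pipeline
#'
#' For every condition and field of view: generates a synthetic time lapse,
#' preprocesses it, computes the activity trace and its cumulative value at
#' the report time, turns the ground-truth (or classical-detector) masks into
#' detections, derives the rounding curve and its peak, and classifies
#' events. Conditions are then compared against the control: pooled rounding
#' onsets with the two-sample KS test, per-FOV peak times and
#' control-normalised cumulative activity with bootstrap confidence
#' intervals. All tables, plus a reproducibility manifest (config snapshot,
#' seeds, package version, per-stage wall-clock and output hashes), are
#' written under `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param detector `"ground-truth"` to consume the generator's masks,
#'   `"classical"` to run [detect_round_cells_video()] on the rendered
#'   frames.
#' @param p_adjust Multiple-testing correction applied across the
#'   condition-versus-control comparisons: `"none"` (default, raw p values
#'   as conventionally reported) or `"bonferroni"`.
#' @return Invisibly, a list with `fov_summary`, `comparisons`, `curves`,
#'   `traces` and `manifest`.
#' @export
run_pipeline <- function(config, out_dir,
                         detector = c("ground-truth", "classical"),
                         p_adjust = c("none", "bonferroni")) {
  stopifnot(inherits(config, "pipeline_config"))
  detector <- match.arg(detector)
  p_adjust <- match.arg(p_adjust)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- proc.time()["elapsed"]
  timings <- list()

  fov_rows <- list()
  curve_rows <- list()
  trace_rows <- list()
  pooled_onsets <- list()
  fov_seed <- 0L

  for (cond in config$conditions) {
    n_fov <- cond$n_fov %||% config$n_fov
    overrides <- cond[setdiff(names(cond),
                              c("label", "dose_j_cm2", "wavelength_nm",
                                "n_fov"))]
    onsets <- numeric(0)
    for (fov in seq_len(n_fov)) {
      fov_seed <- fov_seed + 1L
      t0 <- proc.time()["elapsed"]
      args <- utils::modifyList(config$defaults, overrides)
      args$seed <- config$seed * 1000L + fov_seed
      scenario <- run_stage("simulate", cond$label,
                            do.call(synthetic_scenario, args))
      sim <- run_stage("simulate", cond$label, render_video(scenario))
      stage_log("simulate", cond$label, sprintf("fov %d", fov))

      pre <- run_stage("preprocess", cond$label,
                       preprocess_for_activity(sim$video))
      trace <- run_stage("activity", cond$label, activity_trace(pre))
      cum_act <- cumulative_activity_at(trace,
                                        min(config$report_time,
                                            max(trace$time_min)))
      rm(pre)

      det <- run_stage("detect", cond$label, switch(
        detector,
        "ground-truth" = masks_to_detections(sim$truth$masks),
        "classical" = masks_to_detections(
          detect_round_cells_video(sim$video))
      ))
      curve <- run_stage("quantify", cond$label,
                         rounding_curve(det, sim$truth$nuclei))
      pk <- suppressWarnings(peak_time(curve))
      events <- sim$truth$events
      tf <- transition_fraction(events, config$transition_by)
      onsets <- c(onsets, events$t_round_start)

      fov_rows[[fov_seed]] <- tibble(
        condition = cond$label, fov = fov,
        dose_j_cm2 = cond$dose_j_cm2 %||% NA_real_,
        wavelength_nm = cond$wavelength_nm %||% NA_real_,
        seed = args$seed, n_cells = scenario$n_cells,
        peak_time_min = pk, peak_fraction = max(curve$fraction),
        cumulative_activity = cum_act, transition_fraction = tf,
        n_divided = sum(events$outcome == "divided"),
        n_arrested = sum(events$outcome == "arrested")
      )
      curve_rows[[fov_seed]] <- curve |>
        mutate(condition = cond$label, fov = fov, .before = 1)
      trace_rows[[fov_seed]] <- trace |>
        mutate(condition = cond$label, fov = fov, .before = 1)
      timings[[sprintf("%s_fov%d", cond$label, fov)]] <-
        round(proc.time()["elapsed"] - t0, 2)
      rm(sim)
    }
    pooled_onsets[[cond$label]] <- onsets
  }

  fov_summary <- bind_rows(fov_rows) |>
    mutate(replica = 1L) |>
    normalize_per_replica(value = "cumulative_activity",
                          control = config$control)

  comparisons <- purrr::map(
    setdiff(names(pooled_onsets), config$control),
    function(lab) {
      ks <- ks_two_sided(pooled_onsets[[config$control]],
                         pooled_onsets[[lab]])
      ctrl_pk <- fov_summary$peak_time_min[fov_summary$condition ==
                                             config$control]
      cond_pk <- fov_summary$peak_time_min[fov_summary$condition == lab]
      tidy(ks) |>
        mutate(condition = lab, control = config$control,
               peak_shift_min = mean(cond_pk, na.rm = TRUE) -
                 mean(ctrl_pk, na.rm = TRUE), .before = 1)
    }) |> bind_rows()
  if (p_adjust != "none" && nrow(comparisons) > 0) {
    comparisons$p_value <- stats::p.adjust(comparisons$p_value,
                                           method = p_adjust)
    comparisons$significance_stars <- significance_stars(comparisons$p_value)
  }

  curves <- bind_rows(curve_rows)
  traces <- bind_rows(trace_rows)

  write_table(fov_summary, file.path(out_dir, "fov_summary.csv"))
  write_table(comparisons, file.path(out_dir, "comparisons.csv"))
  write_table(curves, file.path(out_dir, "rounding_curves.csv"))
  write_table(traces, file.path(out_dir, "activity_traces.csv"))

  outputs <- file.path(out_dir, c("fov_summary.csv", "comparisons.csv",
                                  "rounding_curves.csv",
                                  "activity_traces.csv"))
  manifest <- list(
    package_version = as.character(packageVersion("phototox")),
    seed = config$seed,
    control = config$control,
    detector = detector,
    report_time = config$report_time,
    transition_by = config$transition_by,
    conditions = config$conditions,
    defaults = config$defaults,
    stage_seconds = timings,
    total_seconds = round(proc.time()["elapsed"] - t_start, 2),
    output_md5 = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  stage_log("pipeline", sprintf("done in %.1f s", manifest$total_seconds))

  invisible(list(fov_summary = fov_summary, comparisons = comparisons,
                 curves = curves, traces = traces, manifest = manifest))
}
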