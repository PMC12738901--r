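test_that("the rounding curve is detections over a fixed denominator", {
  det <- tibble::tibble(frame = c(rep(1L, 10), 2L))
  curve <- rounding_curve(det, 100, n_frames = 4, frame_interval = 4)
  expect_equal(curve$fraction, c(0, 0.10, 0.01, 0))
  expect_equal(curve$time_min, c(0, 4, 8, 12))
  expect_equal(attr(curve, "n_nuclei"), 100L)
  expect_error(rounding_curve(det, 0, n_frames = 4, frame_interval = 4),
               "positive")
  expect_warning(rounding_curve(tibble::tibble(frame = rep(0L, 5)), 2,
                                n_frames = 1, frame_interval = 4),
                 "exceeds 1")
})

test_that("peak time picks the earliest maximum and flags flat curves", {
  curve <- tibble::tibble(time_min = c(0, 4, 8), fraction = c(0.1, 0.5, 0.3))
  expect_equal(peak_time(curve), 4)
  tie <- tibble::tibble(time_min = c(4, 8), fraction = c(0.5, 0.5))
  expect_equal(peak_time(tie), 4)
  flat <- tibble::tibble(time_min = c(0, 4), fraction = c(0, 0.005))
  expect_warning(pk <- peak_time(flat), "No rounding peak")
  expect_true(is.na(pk))
})

test_that("population curves track the mother-to-daughter transition", {
  mothers_only <- suppressWarnings(masks_to_detections(
    label_mask_stack(array(0L, c(2, 8, 8)), 1), frame_interval = 4))
  expect_equal(nrow(population_curves(mothers_only)), 0L)

  # all detections 20 um -> no daughters anywhere
  det20 <- tibble::tibble(frame = 0:3, time_min = 0:3 * 4,
                          diameter_um = 20,
                          size_class = classify_size(rep(20, 4)))
  pc <- population_curves(det20)
  expect_true(all(pc$n_daughter == 0))

  # synchronous division at 60 min: daughter count crosses mothers there
  n <- 40
  ev <- classify_event(rep(30, n), rep(60, n), t_end = 480)
  ev$t_round_end <- ev$t_division
  sc <- synthetic_scenario(n_cells = n, field = c(448, 448), duration = 120,
                           seed = 5)
  det <- ground_truth_detections(sc, events = ev)
  pc2 <- population_curves(det)
  crossing <- pc2$time_min[which(pc2$n_daughter >= pc2$n_mother)[1]]
  expect_lte(abs(crossing - 60), sc$frame_interval)
})

test_that("events classify into divided and arrested by the window rule", {
  ev <- classify_event(t_round_start = 40, t_division = 70, t_end = 480)
  expect_equal(ev$outcome, "divided")
  expect_equal(ev$division_duration, 30)
  ev2 <- classify_event(t_round_start = 100, t_division = NA, t_end = 480)
  expect_equal(ev2$outcome, "arrested")
  expect_true(is.na(ev2$t_division))
  ev3 <- classify_event(t_round_start = 450, t_division = 490, t_end = 480)
  expect_equal(ev3$outcome, "arrested")  # divides after the window closes
  expect_error(classify_event(50, 40, 480), "precedes")
})

test_that("transition fractions count divisions completed by the cut-off", {
  ev <- classify_event(rep(10, 10), c(rep(45, 5), rep(200, 5)), t_end = 480)
  expect_equal(transition_fraction(ev, by_time = 50), 0.5)
  expect_equal(transition_fraction(ev, by_time = 5), 0)
  expect_error(transition_fraction(ev[0, ]), "empty")
})

test_that("event CSV round trip preserves outcomes", {
  ev <- classify_event(c(20, 30, 40), c(50, NA, 90), t_end = 480)
  path <- withr::local_tempfile(fileext = ".csv")
  write_table(tibble::tibble(event_id = ev$event_id,
                             t_round_start_min = ev$t_round_start,
                             t_division_min = ev$t_division,
                             t_end_min = 480), path)
  back <- read_events_csv(path)
  expect_equal(back$outcome, ev$outcome)
  expect_equal(back$division_duration, ev$division_duration)
})

test_that("rounding peaks recover the configured timing and its shifts", {
  peaks <- vapply(c(50, 70, 90), function(mode) {
    sc <- synthetic_scenario(n_cells = 200, field = c(800, 800),
                             rounding_time_mean = mode, seed = 21)
    curve <- suppressWarnings(
      rounding_curve(ground_truth_detections(sc), 200))
    peak_time(curve)
  }, numeric(1))
  expect_true(all(abs(peaks - c(50, 70, 90)) <= 4))
  expect_true(all(diff(peaks) > 0))
})

test_that("a 20-min photodamage delay shifts the peak in >= 95% of runs", {
  shifts <- vapply(1:20, function(s) {
    ctrl <- synthetic_scenario(n_cells = 200, field = c(800, 800),
                               rounding_time_mean = 50, seed = 100 + s)
    dmg <- synthetic_scenario(n_cells = 200, field = c(800, 800),
                              rounding_time_mean = 70, seed = 300 + s)
    p1 <- peak_time(suppressWarnings(
      rounding_curve(ground_truth_detections(ctrl), 200)))
    p2 <- peak_time(suppressWarnings(
      rounding_curve(ground_truth_detections(dmg), 200)))
    p2 - p1
  }, numeric(1))
  expect_gte(mean(shifts >= 16), 0.95)
})
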