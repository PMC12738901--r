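test_that("scenarios validate their parameters", {
  expect_error(synthetic_scenario(arrest_prob = 1.2), "arrest_prob")
  expect_error(synthetic_scenario(daughter_diameter = 25), "smaller")
  expect_error(synthetic_scenario(noise_sd = -1), "noise_sd")
  expect_error(synthetic_scenario(min_separation_um = 10), "overlap")
})

test_that("generation is fully deterministic under a fixed seed", {
  sc <- tiny_scenario(noise_sd = 0.01, seed = 77)
  ev1 <- sample_events(sc)
  ev2 <- sample_events(sc)
  expect_identical(ev1, ev2)
  sim1 <- render_video(sc)
  sim2 <- render_video(sc)
  expect_identical(sim1$video$frames, sim2$video$frames)
  expect_identical(sim1$truth$masks$masks, sim2$truth$masks$masks)
  # and the generator does not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(sample_events(sc)); after <- runif(1)
  expect_identical(before, after)
})

test_that("event schedules follow the configured law", {
  expect_true(all(sample_events(tiny_scenario(arrest_prob = 1))$outcome ==
                    "arrested"))
  sc0 <- synthetic_scenario(n_cells = 400, seed = 31)
  sc20 <- synthetic_scenario(n_cells = 400, extra_delay = 20, seed = 31)
  m0 <- mean(sample_events(sc0)$t_round_start)
  m20 <- mean(sample_events(sc20)$t_round_start)
  # oracle: truncated-normal means of the two onset laws
  tn_mean <- function(sc) {
    od <- onset_distribution(sc)
    a <- (0 - od$location) / od$sd
    od$location + od$sd * stats::dnorm(a) / (1 - pnorm(a))
  }
  expected_shift <- tn_mean(sc20) - tn_mean(sc0)
  expect_lt(abs((m20 - m0) - expected_shift),
            2 * sc0$rounding_time_sd / sqrt(400))
  expect_lt(abs(expected_shift - 20), 2)  # truncation at 0 biases by ~1 min
  # divided cells split exactly rounding_duration after onset
  ev <- sample_events(tiny_scenario(seed = 5))
  div <- ev[ev$outcome == "divided", ]
  expect_equal(div$division_duration, rep(30, nrow(div)))
})

test_that("ground truth is self-consistent: masks match the event schedule", {
  sc <- tiny_scenario(seed = 42)
  sim <- render_video(sc)
  expect_equal(sim$truth$nuclei$count, sc$n_cells)
  from_masks <- masks_to_detections(sim$truth$masks)
  from_schedule <- ground_truth_detections(sc, events = sim$truth$events)
  counts_m <- table(factor(from_masks$frame, levels = 0:20))
  counts_s <- table(factor(from_schedule$frame, levels = 0:20))
  expect_equal(as.integer(counts_m), as.integer(counts_s))
  # size classes agree frame by frame
  expect_equal(
    as.integer(table(from_masks$size_class)),
    as.integer(table(from_schedule$size_class))
  )
})

test_that("the expected rounding curve peaks at the configured time", {
  tt <- seq(0, 480, 0.5)
  for (mode in c(50, 70, 90)) {
    sc <- synthetic_scenario(rounding_time_mean = mode, seed = 1)
    ef <- expected_rounding_fraction(sc, tt)
    expect_lte(abs(tt[which.max(ef)] - mode), 1)
  }
  # arrest raises the late tail
  sc_a <- synthetic_scenario(arrest_prob = 0.5, seed = 1)
  expect_gt(expected_rounding_fraction(sc_a, 400), 0.4)
})

test_that("without noise, drift or events the video is static", {
  sc <- tiny_scenario(n_cells = 6, duration = 20, rounding_time_mean = 900,
                      noise_sd = 0, gradient_amplitude = 0.1)
  sim <- render_video(sc)
  tr <- activity_trace(sim$video)
  expect_true(all(tr$activity < 1e-12))
})

test_that("the empirical curve integrates to the expected round time per cell", {
  sc <- tiny_scenario(n_cells = 20, field = c(256, 256), duration = 160,
                      seed = 8)
  sim <- render_video(sc)
  det <- ground_truth_detections(sc, events = sim$truth$events)
  curve <- suppressWarnings(rounding_curve(det, sim$truth$nuclei))
  # oracle: total round-state frames per cell, straight from the schedule
  ev <- sim$truth$events
  times <- curve$time_min
  oracle <- sum(vapply(times, function(t) {
    sum(ev$t_round_start <= t & t < ev$t_round_end) +
      2 * sum(!is.na(ev$t_division) & ev$t_division <= t &
                t < ev$t_division + sc$daughter_round_duration)
  }, numeric(1))) / sc$n_cells
  expect_equal(sum(curve$fraction), oracle, tolerance = 1e-12)
})

test_that("placement refuses impossible densities", {
  expect_error(render_video(synthetic_scenario(n_cells = 200,
                                               field = c(128, 128))),
               "Cannot place")
})
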