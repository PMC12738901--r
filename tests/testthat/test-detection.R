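test_that("size classification uses a strict 18-um threshold", {
  expect_equal(classify_size(20), "mother")
  expect_equal(classify_size(15), "daughter")
  expect_equal(classify_size(18), "daughter")  # boundary is daughter
  expect_equal(classify_size(c(18.0001, 17.9999)), c("mother", "daughter"))
})

test_that("area-diameter conversion round-trips exactly", {
  set.seed(2)
  area <- runif(50, 0.5, 400)
  d <- diameter_from_area(area)
  expect_equal(pi * (d / 2)^2, area, tolerance = 1e-9)
})

test_that("masks become calibrated detection rows", {
  dim_px <- c(64, 64)
  m <- draw_disc(dim_px, c(32, 32), 10)              # ~20 um at 1 um/px
  oracle_area <- sum(m > 0)
  masks <- label_mask_stack(array(m, c(1, dim_px)), pixel_size = 1)
  det <- masks_to_detections(masks, frame_interval = 4)
  expect_equal(nrow(det), 1L)
  expect_equal(det$area_px, oracle_area)
  expect_equal(det$diameter_um, 2 * sqrt(oracle_area / pi), tolerance = 1e-12)
  expect_gt(det$diameter_um, 18)
  expect_equal(det$size_class, "mother")
  expect_equal(det$centroid_row, 32, tolerance = 0.5)

  # single pixel at the detection grid's 0.865 um
  one <- label_mask_stack(array(c(1L, rep(0L, 24)), c(1, 5, 5)),
                          pixel_size = 0.865)
  det1 <- masks_to_detections(one, frame_interval = 4)
  expect_equal(det1$diameter_um, 2 * sqrt(0.865^2 / pi), tolerance = 1e-9)
  expect_equal(round(det1$diameter_um, 3), 0.976)
  expect_equal(det1$size_class, "daughter")

  empty <- label_mask_stack(array(0L, c(3, 8, 8)), pixel_size = 1)
  det0 <- masks_to_detections(empty, frame_interval = 4)
  expect_equal(nrow(det0), 0L)
  expect_equal(attr(det0, "n_frames"), 3L)
})

test_that("detection tables are invariant to instance relabelling", {
  m <- draw_disc(c(64, 64), c(20, 20), 8, value = 1L)
  m <- draw_disc(c(64, 64), c(45, 45), 8, value = 2L, base = m)
  swapped <- m
  swapped[m == 1L] <- 2L
  swapped[m == 2L] <- 1L
  d1 <- masks_to_detections(label_mask_stack(array(m, c(1, 64, 64)), 1),
                            frame_interval = 4)
  d2 <- masks_to_detections(label_mask_stack(array(swapped, c(1, 64, 64)), 1),
                            frame_interval = 4)
  cols <- c("area_px", "diameter_um", "size_class")
  expect_equal(dplyr::arrange(d1[cols], .data$area_px),
               dplyr::arrange(d2[cols], .data$area_px))
})

test_that("nuclei counting is fixed at the first frame", {
  masks <- array(0L, c(2, 40, 130))
  for (k in 1:126) masks[1, (k - 1) %% 40 + 1, (k - 1) %/% 40 * 4 + 1] <- k
  expect_equal(count_nuclei(label_mask_stack(masks, 1))$count, 126L)
  expect_equal(count_nuclei(50)$count, 50L)
  expect_equal(count_nuclei(50)$source, "ground-truth")
  expect_error(count_nuclei(-1), "non-negative")
  expect_error(count_nuclei("many"), "non-negative")
})

test_that("the classical detector finds rendered rings and rejects ellipses", {
  expect_equal(max(detect_round_cells_classical(matrix(0.4, 128, 128), 0.55)),
               0L)
  sc <- tiny_scenario(n_cells = 10, field = c(288, 288), duration = 56,
                      rounding_time_mean = 40, rounding_time_sd = 1,
                      min_separation_um = 33, seed = 12)
  sim <- render_video(sc)
  # pick the frame where the most cells are round simultaneously
  n_frames <- dim(sim$truth$masks$masks)[1]
  f <- which.max(vapply(seq_len(n_frames),
                        function(i) sum(sim$truth$masks$masks[i, , ] > 0),
                        numeric(1)))
  det <- detect_round_cells_classical(sim$video$frames[f, , ],
                                      pixel_size = 0.55)
  gt <- sim$truth$masks$masks[f, , ]
  expect_equal(max(det), length(setdiff(unique(as.vector(gt)), 0L)))
  # centroids within 2 px of ground truth
  d <- masks_to_detections(label_mask_stack(det, 0.55), frame_interval = 4)
  g <- masks_to_detections(label_mask_stack(gt, 0.55), frame_interval = 4)
  pr <- match_detections(d, g, max_dist_px = 2)
  expect_equal(unname(pr["recall"]), 1)

  # a 3:1 ellipse of similar area is rejected by circularity
  ell <- matrix(0.4, 128, 128)
  xy <- expand.grid(1:128, 1:128)
  inside <- ((xy[, 1] - 64) / 31)^2 + ((xy[, 2] - 64) / 10.5)^2 < 1
  ell[as.matrix(xy[inside, ])] <- 0.9
  expect_equal(max(detect_round_cells_classical(ell, 0.55)), 0L)
  expect_error(detect_round_cells_classical(ell, 0.55,
                                            diameter_range = c(20, 10)),
               "diameter_range")
})
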