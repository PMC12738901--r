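# Shared fixtures and oracles, all generated in code.

# Rasterise a filled disc into a matrix (independent oracle for mask areas).
draw_disc <- function(dim, centre, radius, value = 1L, base = NULL) {
  m <- base %||% matrix(0L, dim[1], dim[2])
  for (i in seq_len(dim[1])) {
    dj <- radius^2 - (i - centre[1])^2
    if (dj < 0) next
    j <- max(1, ceiling(centre[2] - sqrt(dj))):min(dim[2], floor(centre[2] + sqrt(dj)))
    m[i, j] <- value
  }
  m
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Greedy centroid matching of detections against ground truth; returns
# precision/recall over all frames.
match_detections <- function(det, gt, max_dist_px = 3) {
  tp <- 0; fp <- 0; fn <- 0
  for (f in unique(c(det$frame, gt$frame))) {
    d <- det[det$frame == f, ]
    g <- gt[gt$frame == f, ]
    if (nrow(g) == 0) { fp <- fp + nrow(d); next }
    if (nrow(d) == 0) { fn <- fn + nrow(g); next }
    dist2 <- outer(d$centroid_row, g$centroid_row, "-")^2 +
      outer(d$centroid_col, g$centroid_col, "-")^2
    used <- rep(FALSE, nrow(g))
    for (i in seq_len(nrow(d))) {
      j <- which.min(ifelse(used, Inf, dist2[i, ]))
      if (length(j) == 1 && dist2[i, j] <= max_dist_px^2 && !used[j]) {
        tp <- tp + 1; used[j] <- TRUE
      } else {
        fp <- fp + 1
      }
    }
    fn <- fn + sum(!used)
  }
  c(precision = tp / max(tp + fp, 1), recall = tp / max(tp + fn, 1))
}

# A small, fast scenario for tests that only need structure, not scale.
tiny_scenario <- function(...) {
  args <- utils::modifyList(
    list(n_cells = 12, field = c(256, 256), duration = 80,
         frame_interval = 4, noise_sd = 0, gradient_amplitude = 0,
         seed = 99L),
    list(...))
  do.call(synthetic_scenario, args)
}
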