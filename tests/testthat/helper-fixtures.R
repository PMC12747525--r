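# Fixtures built in code: fabricated feature tables, parked trajectories,
# random bout tables, and independent brute-force oracles.

# Feature table with every column at an inert default; override per column
# with scalars or length-n vectors.
make_feature_table <- function(n, fps = 30, ...) {
  cols <- list(frame = seq_len(n) - 1L,
               speed_mm_s = 0, speed_other_mm_s = 0, peak_speed_mm_s = 0,
               approach_speed_mm_s = 0, dist_mm = 10, facing_deg = 180,
               behind_deg = 0, ang_pos_rad = 0, ang_vel_rad_s = 0,
               sideways_frac = 0, wing_max_deg = 0,
               body_len_mm = 2.4, body_len_other_mm = 2.8)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cols)))
  cols[names(over)] <- over
  df <- as.data.frame(lapply(cols, function(v) rep(v, length.out = n)))
  structure(df, fps = fps, n_frames = n,
            class = c("feature_table", "data.frame"))
}

# Two stationary flies, well separated, inside a 13 mm arena.
make_parked_traj <- function(n, fps = 30, male_xy = c(-3, 0),
                             other_xy = c(3, 0)) {
  arena <- arena_config(fps = fps, arena_diameter_mm = 13,
                        duration_frames = n)
  frames <- seq_len(n) - 1L
  df <- rbind(
    data.frame(frame = frames, fly = "male", x_mm = male_xy[1],
               y_mm = male_xy[2], theta = 0, wing_left_deg = 0,
               wing_right_deg = 0, body_len_mm = 2.4),
    data.frame(frame = frames, fly = "other", x_mm = other_xy[1],
               y_mm = other_xy[2], theta = 0, wing_left_deg = 0,
               wing_right_deg = 0, body_len_mm = 2.8))
  trajectory_set(df, arena)
}

# Random normalized bout table for one behavior (uses the current RNG).
random_bout_table <- function(n_frames, behavior = "wing_extension",
                              max_bouts = 8L, fps = 30) {
  k <- sample.int(max_bouts + 1L, 1L) - 1L
  if (k == 0L) {
    return(bout_table(NULL, fps = fps, n_frames = n_frames))
  }
  starts <- sample.int(n_frames, k, replace = TRUE) - 1L
  lens <- if (behavior == "lunge") rep(1L, k) else sample.int(12L, k, replace = TRUE)
  ends <- pmin(starts + lens, n_frames)
  keep <- starts < ends
  normalize_bouts(bout_table(
    data.frame(behavior = behavior, fly = "male",
               start = starts[keep], end = ends[keep]),
    fps = fps, n_frames = n_frames))
}

# O(n*m) all-pairs interval-overlap oracle for bout-level matching.
oracle_match_bouts <- function(pred, truth, behavior) {
  pr <- pred[pred$behavior == behavior, , drop = FALSE]
  tr <- truth[truth$behavior == behavior, , drop = FALSE]
  overlaps <- function(a_s, a_e, b_s, b_e) {
    min(a_e, b_e) - max(a_s, b_s) > 0
  }
  hit_t <- vapply(seq_len(nrow(tr)), function(i) {
    any(vapply(seq_len(nrow(pr)), function(j) {
      overlaps(tr$start[i], tr$end[i], pr$start[j], pr$end[j])
    }, logical(1)))
  }, logical(1))
  hit_p <- vapply(seq_len(nrow(pr)), function(j) {
    any(vapply(seq_len(nrow(tr)), function(i) {
      overlaps(tr$start[i], tr$end[i], pr$start[j], pr$end[j])
    }, logical(1)))
  }, logical(1))
  list(tp = sum(hit_t), fp = sum(!hit_p), fn = sum(!hit_t),
       n_truth = nrow(tr), n_pred = nrow(pr))
}

# Brute-force persistence scan: runs of TRUE at least k long, by walking
# the vector frame by frame.
oracle_runs <- function(cand, k) {
  out <- NULL
  i <- 1L
  n <- length(cand)
  while (i <= n) {
    if (cand[i]) {
      j <- i
      while (j < n && cand[j + 1L]) j <- j + 1L
      if (j - i + 1L >= k) out <- rbind(out, c(i - 1L, j))
      i <- j + 1L
    } else i <- i + 1L
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

expect_bounds_close <- function(pred, truth, tol = 2L) {
  for (i in seq_len(nrow(truth))) {
    tb <- truth[i, ]
    cand <- pred[pred$behavior == tb$behavior & pred$end > tb$start &
                   pred$start < tb$end, , drop = FALSE]
    expect_equal(nrow(cand), 1L,
                 info = sprintf("%s [%d,%d): expected one overlapping bout",
                                tb$behavior, tb$start, tb$end))
    if (nrow(cand) == 1L) {
      expect_lte(abs(cand$start - tb$start), tol)
      expect_lte(abs(cand$end - tb$end), tol)
    }
  }
}
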