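test_that("wing extension needs a strictly exceeded angle and persistence", {
  p <- classifier_params()
  # exactly at the 30 degree threshold: never triggers
  f30 <- make_feature_table(300, wing_max_deg = 30)
  expect_equal(nrow(detect_wing_extension(f30, p)), 0L)

  wing <- rep(0, 300); wing[101:130] <- 45          # frames 100..129
  f <- make_feature_table(300, wing_max_deg = wing)
  bt <- detect_wing_extension(f, p)
  expect_equal(as.data.frame(bt)[, c("start", "end")],
               data.frame(start = 100L, end = 130L))

  wing10 <- rep(0, 300); wing10[101:110] <- 45      # 10 < round(0.5*30) = 15
  f10 <- make_feature_table(300, wing_max_deg = wing10)
  expect_equal(nrow(detect_wing_extension(f10, p)), 0L)
  expect_equal(nrow(oracle_runs(wing10 > 30, 15)), 0L)
})

test_that("wing persistence agrees with a brute-force run scan", {
  withr::local_seed(5)
  p <- classifier_params()
  any_runs <- 0L
  for (rep in 1:25) {
    wing <- rep(ifelse(runif(40) < 0.5, 45, 10), each = 10)  # 10-frame blocks
    f <- make_feature_table(400, wing_max_deg = wing)
    got <- as.data.frame(detect_wing_extension(f, p))
    want <- oracle_runs(wing > p$wing_angle_deg,
                        seconds_to_frames(p$wing_persist_s, 30))
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      any_runs <- any_runs + nrow(want)
      expect_equal(got$start, want[, 1])
      expect_equal(got$end, want[, 2])
    }
  }
  expect_gt(any_runs, 0L)   # the oracle comparison actually exercised runs
})

test_that("lunges are single-frame events collapsed at the peak-speed frame", {
  p <- classifier_params()
  quiet <- make_feature_table(200, peak_speed_mm_s = 150, dist_mm = 3,
                              facing_deg = 10)
  expect_equal(nrow(detect_lunge(quiet, p)), 0L)   # never reaches 200 mm/s

  pk <- rep(0, 200); pk[51:52] <- c(250, 240)      # 2-frame spike
  f <- make_feature_table(200, peak_speed_mm_s = pk, dist_mm = 3,
                          facing_deg = 10)
  bt <- detect_lunge(f, p)
  expect_equal(nrow(bt), 1L)
  expect_equal(bt$start, 50L)                      # the 250 mm/s frame
  expect_equal(bout_frames(bt), 1L)

  # exact speed tie: earliest frame wins
  pk2 <- rep(0, 200); pk2[81:82] <- 260
  f2 <- make_feature_table(200, peak_speed_mm_s = pk2, dist_mm = 3,
                           facing_deg = 10)
  expect_equal(detect_lunge(f2, p)$start, 80L)

  # spikes separated by more than the refractory gap stay distinct
  pk3 <- rep(0, 200); pk3[c(51, 60)] <- 250
  f3 <- make_feature_table(200, peak_speed_mm_s = pk3, dist_mm = 3,
                           facing_deg = 10)
  expect_equal(detect_lunge(f3, p)$start, c(50L, 59L))

  # a fast frame far away or facing away is not a lunge
  f4 <- make_feature_table(200, peak_speed_mm_s = 250, dist_mm = 8,
                           facing_deg = 10)
  expect_equal(nrow(detect_lunge(f4, p)), 0L)
  f5 <- make_feature_table(200, peak_speed_mm_s = 250, dist_mm = 3,
                           facing_deg = 90)
  expect_equal(nrow(detect_lunge(f5, p)), 0L)
})

test_that("following requires both flies walking and the distance band", {
  p <- classifier_params()
  base <- list(dist_mm = 3.5, behind_deg = 170, speed_mm_s = 5)
  # female standing still: no following regardless of geometry
  f <- do.call(make_feature_table, c(list(100), base,
                                     list(speed_other_mm_s = 0)))
  expect_equal(nrow(detect_following(f, p)), 0L)

  f2 <- do.call(make_feature_table, c(list(60), base,
                                      list(speed_other_mm_s = 5)))
  bt <- detect_following(f2, p)
  expect_equal(as.data.frame(bt)[, c("start", "end")],
               data.frame(start = 0L, end = 60L))

  # distance drifting 1.5 -> 6 mm: the bout is exactly the in-band stretch
  dist <- seq(1.5, 6, length.out = 200)
  f3 <- make_feature_table(200, dist_mm = dist, behind_deg = 170,
                           speed_mm_s = 5, speed_other_mm_s = 5)
  bt3 <- detect_following(f3, p)
  want <- oracle_runs(dist >= 2 & dist <= 5, p$follow_persist_frames)
  expect_equal(nrow(bt3), 1L)
  expect_equal(bt3$start, want[1, 1])
  expect_equal(bt3$end, want[1, 2])
})

test_that("circling needs sideways motion and splits at interruptions", {
  p <- classifier_params()
  # walking straight past the female: translation, not sideways drift
  straight <- make_feature_table(100, dist_mm = 3, ang_vel_rad_s = 1.5,
                                 sideways_frac = 0.05, speed_mm_s = 5)
  expect_equal(nrow(detect_circling(straight, p)), 0L)

  orbit <- make_feature_table(45, dist_mm = 3, ang_vel_rad_s = 2,
                              sideways_frac = 0.95, speed_mm_s = 6)
  bt <- detect_circling(orbit, p)
  expect_equal(as.data.frame(bt)[, c("start", "end")],
               data.frame(start = 0L, end = 45L))

  # orbit - 20-frame straight dash - orbit: two bouts split at the dash
  side <- rep(0.95, 100); side[41:60] <- 0.05
  f <- make_feature_table(100, dist_mm = 3, ang_vel_rad_s = 2,
                          sideways_frac = side, speed_mm_s = 6)
  bt2 <- detect_circling(f, p)
  expect_equal(as.data.frame(bt2)[, c("start", "end")],
               data.frame(start = c(0L, 60L), end = c(40L, 100L)))
})

test_that("mounting runs are banded into attempt and copulation by duration", {
  p <- classifier_params()
  mount_feat <- function(n_run) {
    dist <- rep(10, n_run + 20)
    dist[11:(10 + n_run)] <- 0.4       # thr = 0.5 * mean(2.4, 2.8) = 1.3
    make_feature_table(n_run + 20, dist_mm = dist)
  }
  expect_equal(nrow(detect_mounting(mount_feat(9), p)), 0L)
  expect_equal(detect_mounting(mount_feat(10), p)$behavior,
               "attempted_copulation")
  expect_equal(detect_mounting(mount_feat(1349), p)$behavior,
               "attempted_copulation")
  bt <- detect_mounting(mount_feat(1350), p)
  expect_equal(bt$behavior, "copulation")
  expect_equal(bout_frames(bt), 1350L)

  # close but fast contact is not mounting
  fast <- make_feature_table(60, dist_mm = 0.4, speed_mm_s = 5)
  expect_equal(nrow(detect_mounting(fast, p)), 0L)
})

test_that("attempted copulation and copulation partition the mounting runs", {
  withr::local_seed(8)
  p <- classifier_params(copul_min_frames = 60)  # scaled band for testing
  for (rep in 1:10) {
    dist <- ifelse(runif(500) < 0.5, 0.4, 10)
    f <- make_feature_table(500, dist_mm = dist)
    bt <- detect_mounting(f, p)
    att <- bt[bt$behavior == "attempted_copulation", ]
    cop <- bt[bt$behavior == "copulation", ]
    if (nrow(att) > 0 && nrow(cop) > 0) {
      for (i in seq_len(nrow(att))) {
        expect_true(all(att$end[i] <= cop$start | att$start[i] >= cop$end))
      }
    }
    runs <- oracle_runs(dist <= 1.3, p$attempt_min_frames)
    expect_equal(sort(bt$start), sort(runs[, 1]))
  }
})

test_that("duration floor retains the reference coverage fraction", {
  bt <- bout_table(data.frame(behavior = "wing_extension", fly = "male",
                              start = c(0L, 50L, 100L),
                              end = c(18L, 70L, 125L)),
                   fps = 30, n_frames = 200)
  kept <- apply_duration_floor(bt, reference_durations = rep(20L, 50),
                               coverage = 0.98)
  expect_equal(bout_frames(kept), c(20L, 25L))    # 18-frame bout removed

  kept_min <- apply_duration_floor(bt, reference_durations = c(30L, 5L, 12L),
                                   coverage = 1)
  expect_equal(nrow(kept_min), 3L)                # floor = min = 5

  # 1..100 reference at 98% coverage: floor is the 2nd smallest duration
  ref <- 1:100
  k <- max(1L, as.integer(ceiling(length(ref) * (1 - 0.98) - 1e-9)))
  floor_oracle <- sort(ref)[k]
  expect_equal(floor_oracle, 2L)
  bt2 <- bout_table(data.frame(behavior = "following", fly = "male",
                               start = c(0L, 10L), end = c(1L, 13L)),
                    fps = 30, n_frames = 40)
  kept2 <- apply_duration_floor(bt2, ref, 0.98)
  expect_equal(bout_frames(kept2), 3L)

  # lunges are exempt from the floor
  bl <- bout_table(data.frame(behavior = "lunge", fly = "male",
                              start = 5L, end = 6L), fps = 30, n_frames = 40)
  expect_equal(nrow(apply_duration_floor(bl, ref, 0.98)), 1L)

  expect_error(apply_duration_floor(bt, integer(0)), "non-empty")
})

test_that("detected frames always satisfy the candidate predicate", {
  withr::local_seed(42)
  p <- classifier_params()
  for (rep in 1:15) {
    n <- 300
    f <- make_feature_table(
      n,
      wing_max_deg = runif(n, 0, 60),
      peak_speed_mm_s = runif(n, 0, 300),
      dist_mm = runif(n, 0, 8),
      facing_deg = runif(n, 0, 180),
      behind_deg = runif(n, 0, 180),
      speed_mm_s = runif(n, 0, 6),
      speed_other_mm_s = runif(n, 0, 6),
      ang_vel_rad_s = runif(n, -3, 3),
      sideways_frac = runif(n, 0, 1))
    checks <- list(
      list(detect_wing_extension(f, p), f$wing_max_deg > 30),
      list(detect_following(f, p),
           f$dist_mm >= 2 & f$dist_mm <= 5 & f$behind_deg >= 120 &
             f$speed_mm_s >= 2 & f$speed_other_mm_s >= 2),
      list(detect_circling(f, p),
           f$dist_mm <= 5 & abs(f$ang_vel_rad_s) >= 1 &
             f$sideways_frac >= 0.5),
      list(detect_lunge(f, p),
           f$peak_speed_mm_s >= 200 & f$dist_mm <= 5 & f$facing_deg <= 45))
    for (chk in checks) {
      bt <- chk[[1]]; cand <- chk[[2]]
      for (i in seq_len(nrow(bt))) {
        expect_true(all(cand[(bt$start[i] + 1L):bt$end[i]]))
      }
    }
  }
})

test_that("raising persistence thresholds never adds bouts", {
  withr::local_seed(9)
  for (rep in 1:10) {
    wing <- ifelse(runif(300) < 0.5, 45, 10)
    f <- make_feature_table(300, wing_max_deg = wing)
    n_prev <- Inf
    for (persist in c(0.1, 0.3, 0.5, 0.8, 1.2)) {
      n_now <- nrow(detect_wing_extension(
        f, classifier_params(wing_persist_s = persist)))
      expect_lte(n_now, n_prev)
      n_prev <- n_now
    }
  }
})

test_that("classify_all composes detectors and lets copulation dominate", {
  # stationary flies far apart: nothing at all
  res <- classify_all(make_parked_traj(100))
  expect_equal(nrow(res$bouts), 0L)
  expect_false(any(res$ethogram))

  # copulation frames suppress concurrent courtship labels
  sched <- data.frame(behavior = "copulation", start_s = 2, duration_s = 56)
  sim <- simulate_session(sim_config("desk", seed = 3, schedule = sched))
  df <- as.data.frame(sim$traj)
  df$wing_left_deg[df$fly == "male"] <- 50    # wing up the whole session
  res2 <- classify_all(trajectory_set(df, attr(sim$traj, "arena")))
  eth <- res2$ethogram
  expect_true(any(eth[, "copulation"]))
  expect_false(any(eth[, "copulation"] & eth[, "wing_extension"]))
  expect_true(any(eth[, "wing_extension"]))   # outside copulation it stays
})

test_that("lunge counts map onto the aggression intensity categories", {
  expect_equal(as.character(aggression_category(c(0, 70, 71, 160, 161, 300, 301))),
               c("low", "low", "moderate", "moderate", "high", "high", "hyper"))
  expect_error(aggression_category(-1), "non-negative")
})

test_that("classifier thresholds round-trip through YAML config", {
  p <- classifier_params(wing_angle_deg = 25, follow_persist_frames = 20)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_classifier_params(p, path)
  back <- read_classifier_params(path)
  expect_equal(unclass(back), unclass(p))
  writeLines("not_a_threshold: 3", path)
  expect_error(read_classifier_params(path), "unknown classifier parameter")
})

test_that("invalid threshold combinations are rejected", {
  expect_error(classifier_params(wing_angle_deg = -5), "positive")
  expect_error(classifier_params(attempt_min_frames = 2000), "copul_min_frames")
  expect_error(classifier_params(duration_floor_coverage = 1.5), "\\(0, 1\\]")
})
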