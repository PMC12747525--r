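# Deterministic synthetic two-fly sessions with scheduled, rule-satisfying
# behavior bouts, plus an annotation corrupter with exact bookkeeping.
#
# Outside scheduled bouts both flies perform slow, home-anchored random
# walks near opposite arena walls, which keeps every detector predicate
# false by construction (speeds < 2 mm/s, inter-fly distance > 6 mm, wing
# angles < 20 degrees). Inside a scheduled bout the kinematics are
# overridden with a template that satisfies the corresponding rule with
# margin; two-frame straight-line transitions (partner oriented toward the
# male, male oriented along its own motion) join templates to the baseline
# without satisfying any predicate themselves.

#' Simulator configuration
#'
#' Presets fix the arena and session length: `aggression` (13 mm arena,
#' 20 min), `courtship` (11 mm, 15 min) and `desk` (11 mm, 60 s — small
#' enough that full test suites run in seconds). All presets record at
#' 30 fps.
#'
#' @param preset One of `"desk"`, `"courtship"`, `"aggression"`.
#' @param seed Integer seed; a session is bit-for-bit reproducible given
#'   the seed.
#' @param schedule Optional data frame with columns `behavior`, `start_s`,
#'   `duration_s` (seconds; `duration_s` is ignored for single-frame
#'   lunges). `NULL` uses the preset's default schedule. An empty data
#'   frame gives a pure-baseline session.
#' @param fps Frames per second (default 30).
#' @return A `sim_config` object.
#' @export
sim_config <- function(preset = c("desk", "courtship", "aggression"),
                       seed = 1L, schedule = NULL, fps = 30) {
  preset <- match.arg(preset)
  dims <- switch(preset,
                 desk = list(diameter = 11, seconds = 60),
                 courtship = list(diameter = 11, seconds = 15 * 60),
                 aggression = list(diameter = 13, seconds = 20 * 60))
  arena <- arena_config(fps = fps, arena_diameter_mm = dims$diameter,
                        duration_frames = round(dims$seconds * fps))
  if (is.null(schedule)) schedule <- default_schedule(preset)
  schedule <- as.data.frame(schedule)
  if (nrow(schedule) > 0L) {
    stopifnot(all(c("behavior", "start_s", "duration_s") %in% names(schedule)))
  }
  structure(list(preset = preset,
                 arena = arena,
                 seed = as.integer(seed),
                 schedule = schedule,
                 baseline = list(home_margin_mm = 1.3, wander_mm = 1.0,
                                 speed_mm_s = c(0.4, 1.4)),
                 margins = list(wing_deg = c(45, 70),
                                lunge_speed_mm_s = c(230, 245),
                                lunge_contact_mm = c(1.6, 1.8),
                                follow_gap_mm = c(2.8, 4.2),
                                follow_speed_mm_s = 5,
                                circle_radius_mm = 3,
                                circle_ang_vel_rad_s = 2,
                                mount_gap_mm = 0.4),
                 body_len_mm = c(male = 2.4, other = 2.8)),
            class = "sim_config")
}

#' Default bout schedule of a simulator preset
#'
#' `desk`: a 60 s mix of wing extension, following, circling, lunges and
#' attempted copulation (copulation, at >= 54 s per bout, cannot share a
#' 60 s session with other bouts and is scheduled explicitly when needed).
#' `courtship`: 15 min of courtship behaviors ending in a 60 s copulation.
#' `aggression`: 90 lunges spread over 20 min (a moderately aggressive
#' session).
#'
#' @param preset Preset name.
#' @return Data frame with columns `behavior`, `start_s`, `duration_s`.
#' @export
default_schedule <- function(preset = c("desk", "courtship", "aggression")) {
  preset <- match.arg(preset)
  if (preset == "desk") {
    return(data.frame(
      behavior = c("wing_extension", "following", "circling", "lunge",
                   "attempted_copulation", "lunge", "wing_extension",
                   "circling", "following", "attempted_copulation", "lunge"),
      start_s = c(4, 8, 12, 16, 20, 25, 30, 34, 38, 43, 48),
      duration_s = c(2, 1.5, 1.2, NA, 1.5, NA, 1.5, 1.2, 1.5, 1.2, NA)))
  }
  if (preset == "courtship") {
    court <- data.frame(
      behavior = rep(c("wing_extension", "following", "circling",
                       "attempted_copulation"), times = c(4, 3, 3, 2)),
      start_s = c(20, 100, 200, 300, 50, 150, 250, 70, 170, 270, 330, 390),
      duration_s = c(2.5, 2, 3, 2, 1.5, 2, 1.5, 1.2, 1.5, 1.2, 2, 1.5))
    return(rbind(court, data.frame(behavior = "copulation", start_s = 780,
                                   duration_s = 60)))
  }
  data.frame(behavior = "lunge", start_s = 10 + 13 * (0:89), duration_s = NA)
}

# Schedule in frames with per-behavior sanity checks. Durations must
# exceed the default persistence requirement by >= 20% so detector
# recovery is a deterministic expectation; windows (plus transition
# margins) must be disjoint and clear of the session edges.
prepare_schedule <- function(schedule, n_frames, fps, diameter_mm) {
  if (nrow(schedule) == 0L) {
    return(data.frame(behavior = character(), start = integer(),
                      end = integer()))
  }
  bad <- setdiff(unique(schedule$behavior), BEHAVIOR_SET)
  if (length(bad) > 0L) stop("unknown behavior(s): ", paste(bad, collapse = ", "))
  start <- seconds_to_frames(schedule$start_s, fps)
  n <- ifelse(schedule$behavior == "lunge", 1L,
              seconds_to_frames(ifelse(is.na(schedule$duration_s), 0,
                                       schedule$duration_s), fps))
  end <- start + n
  persist_floor <- ceiling(1.2 * seconds_to_frames(0.5, fps))
  for (i in seq_along(start)) {
    b <- schedule$behavior[i]
    ok <- switch(b,
      lunge = n[i] == 1L,
      wing_extension = n[i] >= persist_floor,
      circling = n[i] >= persist_floor,
      following = n[i] >= ceiling(1.2 * 25),
      attempted_copulation = n[i] >= 15L && n[i] <= floor(0.8 * 1350),
      copulation = n[i] >= ceiling(1.2 * 1350))
    if (!ok) {
      stop(sprintf("scheduled %s bout of %d frames does not clear the %s",
                   b, n[i],
                   "detector persistence/duration band with a 20% margin"))
    }
  }
  if (any(schedule$behavior == "lunge") && diameter_mm < 10.6) {
    stop("lunge simulation needs an arena of at least 10.6 mm diameter")
  }
  span_lo <- ifelse(schedule$behavior == "lunge", start - 7L,
                    ifelse(schedule$behavior == "wing_extension",
                           start, start - 3L))
  span_hi <- ifelse(schedule$behavior == "lunge", end + 5L,
                    ifelse(schedule$behavior == "wing_extension",
                           end, end + 2L))
  if (any(span_lo < 0L) || any(span_hi > n_frames)) {
    stop("schedule exceeds the session length (including transition margins)")
  }
  o <- order(start)
  if (any(span_lo[o][-1L] - span_hi[o][-length(o)] < 2L)) {
    stop("overlapping scheduled bouts: windows (plus transitions) must be disjoint")
  }
  data.frame(behavior = schedule$behavior[o], start = start[o], end = end[o])
}

# Slow, home-anchored persistent random walk; per-frame displacement is
# capped at 1.8 mm/s / fps so central-difference speed stays below the
# 2 mm/s walking threshold.
baseline_walk <- function(n_frames, fps, home, wander, speed_range) {
  x <- numeric(n_frames); y <- numeric(n_frames); th <- numeric(n_frames)
  heading <- runif(1, 0, 2 * pi)
  cap <- 1.8 / fps
  p <- home + c(runif(1, -0.3, 0.3), runif(1, -0.3, 0.3))
  x[1] <- p[1]; y[1] <- p[2]; th[1] <- heading
  for (t in 2:n_frames) {
    heading <- heading + rnorm(1, 0, 0.35)
    s <- runif(1, speed_range[1], speed_range[2]) / fps
    pn <- p + s * c(cos(heading), sin(heading)) + 0.02 * (home - p)
    off <- pn - home
    if (sqrt(sum(off^2)) > wander) {       # soft wall of the home disc
      pn <- home + off / sqrt(sum(off^2)) * wander
      heading <- heading + pi
    }
    d <- pn - p
    dn <- sqrt(sum(d^2))
    if (dn > cap) pn <- p + d / dn * cap
    th[t] <- if (dn > 0) atan2(pn[2] - p[2], pn[1] - p[1]) else th[t - 1]
    p <- pn
    x[t] <- p[1]; y[t] <- p[2]
  }
  list(x = x, y = y, theta = th)
}

#' Generate a synthetic two-fly session
#'
#' Deterministic given the config seed. Returns the trajectory and the
#' scheduled ground-truth bout table; running [classify_all()] on the
#' trajectory recovers the schedule (bout boundaries within two frames).
#'
#' @param cfg A [sim_config()].
#' @return List with `traj` (a [trajectory_set()]), `truth` (a normalized
#'   [bout_table()]) and `config` (the input).
#' @export
#' @examples
#' sim <- simulate_session(sim_config("desk", seed = 7))
#' nrow(sim$truth)
simulate_session <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  arena <- cfg$arena
  fps <- arena$fps
  nT <- arena$duration_frames
  R <- arena$arena_diameter_mm / 2
  sched <- prepare_schedule(cfg$schedule, nT, fps, arena$arena_diameter_mm)
  mg <- cfg$margins
  bl <- cfg$baseline
  I <- function(f) f + 1L   # 0-based frame -> R index

  state <- withr::with_seed(cfg$seed, {
    home_m <- c(-(R - bl$home_margin_mm), 0)
    home_o <- c(R - bl$home_margin_mm, 0)
    m <- baseline_walk(nT, fps, home_m, bl$wander_mm, bl$speed_mm_s)
    o <- baseline_walk(nT, fps, home_o, bl$wander_mm, bl$speed_mm_s)
    xm <- m$x; ym <- m$y; thm <- m$theta
    xo <- o$x; yo <- o$y; tho <- o$theta
    wlm <- runif(nT, 0, 12); wrm <- runif(nT, 0, 12)
    wlo <- runif(nT, 0, 12); wro <- runif(nT, 0, 12)

    set_m <- function(f, p, th) {
      xm[I(f)] <<- p[1]; ym[I(f)] <<- p[2]; thm[I(f)] <<- th
    }
    set_o <- function(f, p, th) {
      xo[I(f)] <<- p[1]; yo[I(f)] <<- p[2]; tho[I(f)] <<- th
    }
    # Straight-line two-frame transition. The male points along its own
    # motion (sideways fraction ~ 0, so no circling); the partner points at
    # the male (rear angle ~ 0, so no following).
    trans_m <- function(frames2, A, B) {
      th <- atan2(B[2] - A[2], B[1] - A[1])
      for (j in seq_along(frames2)) {
        set_m(frames2[j], A + (B - A) * j / (length(frames2) + 1), th)
      }
    }
    trans_o <- function(frames2, A, B) {
      for (j in seq_along(frames2)) {
        p <- A + (B - A) * j / (length(frames2) + 1)
        f <- frames2[j]
        set_o(f, p, atan2(ym[I(f)] - p[2], xm[I(f)] - p[1]))
      }
    }

    for (k in seq_len(nrow(sched))) {
      b <- sched$behavior[k]; s <- sched$start[k]; e <- sched$end[k]
      if (b == "wing_extension") {
        idx <- I(s):I(e - 1L)
        ang <- runif(length(idx), mg$wing_deg[1], mg$wing_deg[2])
        if (runif(1) < 0.5) wlm[idx] <- ang else wrm[idx] <- ang
        next
      }
      if (b == "lunge") {
        f <- s
        phi <- atan2(yo[I(f - 7L)], xo[I(f - 7L)])
        u <- c(cos(phi), sin(phi))
        v <- runif(1, mg$lunge_speed_mm_s[1], mg$lunge_speed_mm_s[2])
        d1 <- runif(1, mg$lunge_contact_mm[1], mg$lunge_contact_mm[2])
        d0 <- v / fps + d1
        q <- 4.9 * u; p0 <- q - d0 * u; p1 <- q - d1 * u
        A_m <- c(xm[I(f - 7L)], ym[I(f - 7L)])
        A_o <- c(xo[I(f - 7L)], yo[I(f - 7L)])
        trans_m(c(f - 6L, f - 5L), A_m, p0)
        for (ff in (f - 4L):(f - 1L)) set_m(ff, p0, phi)   # staging, far
        for (ff in f:(f + 2L)) set_m(ff, p1, phi)          # strike contact
        B_m <- c(xm[I(f + 5L)], ym[I(f + 5L)])
        trans_m(c(f + 3L, f + 4L), p1, B_m)
        trans_o(c(f - 6L, f - 5L), A_o, q)
        for (ff in (f - 4L):(f + 2L)) {
          set_o(ff, q, atan2(ym[I(ff)] - q[2], xm[I(ff)] - q[1]))
        }
        B_o <- c(xo[I(f + 5L)], yo[I(f + 5L)])
        trans_o(c(f + 3L, f + 4L), q, B_o)
        next
      }
      # remaining behaviors share the transition pattern around [s, e)
      frames <- s:(e - 1L)
      n <- length(frames)
      if (b == "following") {
        rc <- 3.5
        vv <- mg$follow_speed_mm_s
        om <- vv / rc * sample(c(-1, 1), 1)
        g <- runif(1, mg$follow_gap_mm[1], mg$follow_gap_mm[2])
        psi <- 2 * asin(g / (2 * rc))
        phi0 <- runif(1, 0, 2 * pi)
        phi <- phi0 + om * (seq_len(n) - 1L) / fps
        P_o <- cbind(rc * cos(phi), rc * sin(phi))
        th_o <- phi + sign(om) * pi / 2
        am <- phi - sign(om) * psi
        P_m <- cbind(rc * cos(am), rc * sin(am))
        th_m <- am + sign(om) * pi / 2
      } else if (b == "circling") {
        ro <- mg$circle_radius_mm
        om <- mg$circle_ang_vel_rad_s * sample(c(-1, 1), 1)
        a0 <- runif(1, 0, 2 * pi)
        am <- a0 + om * (seq_len(n) - 1L) / fps
        P_m <- cbind(ro * cos(am), ro * sin(am))
        th_m <- am + pi                        # body axis points at partner
        P_o <- cbind(rep(0, n), rep(0, n))
        th_o <- rep(runif(1, 0, 2 * pi), n)
      } else {                                 # mounting
        ua <- runif(1, 0, 2 * pi)
        ctr <- 2.0 * c(cos(ua), sin(ua))
        ga <- runif(1, 0, 2 * pi)
        pm <- ctr + mg$mount_gap_mm * c(cos(ga), sin(ga))
        P_o <- matrix(rep(ctr, each = n), ncol = 2)
        th_o <- rep(runif(1, 0, 2 * pi), n)
        P_m <- matrix(rep(pm, each = n), ncol = 2)
        th_m <- rep(atan2(ctr[2] - pm[2], ctr[1] - pm[1]), n)
      }
      A_m <- c(xm[I(s - 3L)], ym[I(s - 3L)])
      A_o <- c(xo[I(s - 3L)], yo[I(s - 3L)])
      trans_m(c(s - 2L, s - 1L), A_m, P_m[1L, ])
      for (j in seq_len(n)) set_m(frames[j], P_m[j, ], th_m[j])
      B_m <- c(xm[I(e + 2L)], ym[I(e + 2L)])
      trans_m(c(e, e + 1L), P_m[n, ], B_m)
      trans_o(c(s - 2L, s - 1L), A_o, P_o[1L, ])
      for (j in seq_len(n)) set_o(frames[j], P_o[j, ], th_o[j])
      B_o <- c(xo[I(e + 2L)], yo[I(e + 2L)])
      trans_o(c(e, e + 1L), P_o[n, ], B_o)
    }
    list(xm = xm, ym = ym, thm = thm, xo = xo, yo = yo, tho = tho,
         wlm = wlm, wrm = wrm, wlo = wlo, wro = wro)
  })

  frames <- seq.int(0L, nT - 1L)
  df <- rbind(
    data.frame(frame = frames, fly = "male",
               x_mm = state$xm, y_mm = state$ym, theta = state$thm,
               wing_left_deg = state$wlm, wing_right_deg = state$wrm,
               body_len_mm = cfg$body_len_mm[["male"]]),
    data.frame(frame = frames, fly = "other",
               x_mm = state$xo, y_mm = state$yo, theta = state$tho,
               wing_left_deg = state$wlo, wing_right_deg = state$wro,
               body_len_mm = cfg$body_len_mm[["other"]]))
  traj <- trajectory_set(df, arena)
  truth <- bout_table(
    if (nrow(sched) > 0L) {
      data.frame(behavior = sched$behavior, fly = "male",
                 start = sched$start, end = sched$end)
    } else NULL,
    fps = fps, n_frames = nT)
  list(traj = traj, truth = normalize_bouts(truth), config = cfg)
}

#' Corruption settings for benchmark predictions
#'
#' @param p_delete Probability a truth bout is dropped (becomes an FN).
#' @param n_insert Number of spurious bouts added in behavior-free regions
#'   (each an FP), distributed round-robin over the behaviors present.
#' @param p_split Probability a surviving bout (non-lunge, >= 3 frames) is
#'   split into two pieces separated by a one-frame gap (still one TP).
#' @param boundary_jitter_frames Maximum uniform shift applied to each
#'   piece boundary, clamped so the piece keeps >= 1 frame of overlap with
#'   its source bout and never touches a neighboring truth bout. Lunge
#'   events (single-frame) are exempt from splitting and jitter.
#' @param seed Integer seed.
#' @return A `corruption` object.
#' @export
corruption <- function(p_delete = 0, n_insert = 0L, p_split = 0,
                       boundary_jitter_frames = 0L, seed = 1L) {
  stopifnot(p_delete >= 0, p_delete <= 1, p_split >= 0, p_split <= 1,
            n_insert >= 0, boundary_jitter_frames >= 0)
  structure(list(p_delete = p_delete, n_insert = as.integer(n_insert),
                 p_split = p_split,
                 boundary_jitter_frames = as.integer(boundary_jitter_frames),
                 seed = as.integer(seed)),
            class = "corruption")
}

# sample() without its length-1 surprise
sample_int <- function(values, n = 1L) values[sample.int(length(values), n)]

#' Corrupt a ground-truth bout table with exact bookkeeping
#'
#' Produces a synthetic "prediction" from a truth table by deleting,
#' splitting, jittering and inserting bouts, together with the exact
#' bout-level TP/FP/FN counts these edits imply: deletions are FN,
#' insertions FP, splits and overlap-preserving jitter leave TP unchanged.
#' [match_bouts()] on the output must reproduce these counts exactly; this
#' is the central oracle for the evaluation module.
#'
#' @param truth A normalized [bout_table()].
#' @param corr A [corruption()].
#' @param n_frames Session length (defaults to the table's).
#' @return List with `pred` (normalized [bout_table()]) and `expected`
#'   (data frame: `behavior`, `tp`, `fp`, `fn`, `n_truth` per behavior
#'   present or inserted).
#' @export
corrupt_bouts <- function(truth, corr = corruption(),
                          n_frames = session_frames(truth)) {
  stopifnot(inherits(truth, "bout_table"), inherits(corr, "corruption"))
  fps <- session_fps(truth)
  j <- corr$boundary_jitter_frames
  behaviors <- unique(truth$behavior)
  if (length(behaviors) == 0L) behaviors <- "wing_extension"

  withr::with_seed(corr$seed, {
    pieces <- list()
    book <- list()
    for (b in behaviors) {
      tb <- truth[truth$behavior == b, , drop = FALSE]
      tb <- tb[order(tb$start), , drop = FALSE]
      nb <- nrow(tb)
      deleted <- if (nb > 0L) runif(nb) < corr$p_delete else logical(0)
      b_pieces <- list()
      for (i in seq_len(nb)) {
        if (deleted[i]) next
        ts <- tb$start[i]; te <- tb$end[i]
        lo <- if (i > 1L) tb$end[i - 1L] else 0L
        hi <- if (i < nb) tb$start[i + 1L] else n_frames
        segs <- matrix(c(ts, te), ncol = 2)
        if (b != "lunge" && te - ts >= 3L && runif(1) < corr$p_split) {
          m <- sample_int((ts + 1L):(te - 2L))
          segs <- matrix(c(ts, m, m + 1L, te), ncol = 2, byrow = TRUE)
        }
        if (b != "lunge" && j > 0L) {
          for (r in seq_len(nrow(segs))) {
            ns <- segs[r, 1L] + sample_int(-j:j)
            ne <- segs[r, 2L] + sample_int(-j:j)
            ns <- min(max(ns, lo), te - 1L)   # keep >= 1 frame inside truth
            ne <- max(min(ne, hi), ts + 1L)   # and off the neighbors
            if (ns < ne) segs[r, ] <- c(ns, ne)
          }
        }
        b_pieces[[length(b_pieces) + 1L]] <-
          data.frame(behavior = b, fly = tb$fly[i],
                     start = segs[, 1L], end = segs[, 2L])
      }
      pieces[[b]] <- if (length(b_pieces) > 0L) do.call(rbind, b_pieces) else
        data.frame(behavior = character(), fly = character(),
                   start = integer(), end = integer())
      book[[b]] <- data.frame(behavior = b, tp = sum(!deleted), fp = 0L,
                              fn = sum(deleted), n_truth = nb)
    }

    if (corr$n_insert > 0L) {
      targets <- behaviors[(seq_len(corr$n_insert) - 1L) %%
                             length(behaviors) + 1L]
      for (b in unique(targets)) {
        n_ins <- sum(targets == b)
        len <- if (b == "lunge") 1L else 5L
        occupied <- rbind(
          cbind(truth$start[truth$behavior == b],
                truth$end[truth$behavior == b]),
          cbind(pieces[[b]]$start, pieces[[b]]$end))
        for (r in seq_len(n_ins)) {
          free <- free_slots(occupied, n_frames, len)
          if (length(free) == 0L) {
            stop("no room for insertions: session has no free region of ",
                 len, " frames for behavior ", b)
          }
          st <- sample_int(free)
          pieces[[b]] <- rbind(pieces[[b]],
                               data.frame(behavior = b, fly = "male",
                                          start = st, end = st + len))
          occupied <- rbind(occupied, c(st, st + len))
          book[[b]]$fp <- book[[b]]$fp + 1L
        }
      }
    }

    pred <- normalize_bouts(bout_table(do.call(rbind, pieces),
                                       fps = fps, n_frames = n_frames))
    list(pred = pred, expected = do.call(rbind, c(book, make.row.names = FALSE)))
  })
}

# Start frames where an interval of `len` frames fits without overlapping
# or touching any occupied interval (1-frame buffer prevents
# adjacency-merging with existing predictions during normalization).
free_slots <- function(occupied, n_frames, len) {
  taken <- rep(FALSE, n_frames)
  for (r in seq_len(nrow(occupied))) {
    lo <- max(occupied[r, 1L] - 1L, 0L)
    hi <- min(occupied[r, 2L] + 1L, n_frames)
    if (hi > lo) taken[(lo + 1L):hi] <- TRUE
  }
  starts <- which(!taken) - 1L
  starts[vapply(starts, function(s) {
    s + len <= n_frames && all(!taken[(s + 1L):(s + len)])
  }, logical(1))]
}
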