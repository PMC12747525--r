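# Per-frame kinematic and dyadic features. These are the only quantities
# the behavior detectors consume.

#' Feature-extraction parameters
#'
#' @param smoothing_window_frames Odd window length for an optional centered
#'   moving average applied to positions before differencing. Default 1
#'   (no smoothing); tracker jitter, when present, can be damped with 3-5.
#' @param eps Small positive guard added to the sideways-fraction
#'   denominator so stationary frames give 0 rather than NaN.
#' @return A `feature_params` object.
#' @export
feature_params <- function(smoothing_window_frames = 1L, eps = 1e-9) {
  stopifnot(is.numeric(smoothing_window_frames),
            smoothing_window_frames >= 1,
            smoothing_window_frames %% 2 == 1,
            is.numeric(eps), eps > 0)
  structure(list(smoothing_window_frames = as.integer(smoothing_window_frames),
                 eps = eps),
            class = "feature_params")
}

# Central difference scaled by fps; one-sided at the endpoints.
central_diff <- function(p, fps) {
  n <- length(p)
  if (n < 2L) stop("central_diff needs at least 2 samples")
  v <- numeric(n)
  if (n > 2L) v[2:(n - 1L)] <- (p[3:n] - p[1:(n - 2L)]) / 2 * fps
  v[1L] <- (p[2L] - p[1L]) * fps
  v[n] <- (p[n] - p[n - 1L]) * fps
  v
}

# Wrap an angle difference into (-pi, pi].
wrap_pi <- function(d) {
  ((d + pi) %% (2 * pi)) - pi
}

# Angle in degrees, in [0, 180], between vectors (ux,uy) and (vx,vy);
# 0 where either vector is degenerate.
angle_between_deg <- function(ux, uy, vx, vy) {
  den <- sqrt((ux^2 + uy^2) * (vx^2 + vy^2))
  num <- ux * vx + uy * vy
  out <- numeric(length(den))
  ok <- den > 0
  out[ok] <- acos(pmin(1, pmax(-1, num[ok] / den[ok]))) * 180 / pi
  out
}

moving_average <- function(p, w) {
  if (w <= 1L) return(p)
  sm <- as.numeric(stats::filter(p, rep(1 / w, w), sides = 2))
  half <- (w - 1L) %/% 2L
  n <- length(p)
  sm[seq_len(half)] <- p[seq_len(half)]              # keep raw edges
  sm[(n - half + 1L):n] <- p[(n - half + 1L):n]
  sm
}

#' Compute per-frame kinematic and dyadic features
#'
#' Derives, for every frame of a two-fly session, the quantities the
#' rule-based detectors consume. Velocities use central differences scaled
#' by fps (one-sided at the endpoints). `peak_speed_mm_s` is the larger of
#' the two adjacent-frame displacement speeds at each frame; it resolves
#' impulsive single-frame events (lunges) that central differences, which
#' average displacement over two frame intervals, smooth away.
#'
#' Columns of the returned `feature_table` (one row per frame, focal male
#' perspective):
#' \describe{
#'   \item{speed_mm_s, speed_other_mm_s}{centroid speed of male / partner.}
#'   \item{peak_speed_mm_s}{male adjacent-frame displacement speed (see above).}
#'   \item{approach_speed_mm_s}{rate of decrease of inter-fly distance
#'     (positive = approaching).}
#'   \item{dist_mm}{inter-centroid distance.}
#'   \item{facing_deg}{angle in \[0, 180\] between the male's orientation and
#'     the male-to-partner vector (0 = looking straight at the partner).}
#'   \item{behind_deg}{angle in \[0, 180\] between the partner's orientation
#'     and the partner-to-male vector (180 = male directly behind).}
#'   \item{ang_pos_rad}{unwrapped angular position of the male in the
#'     partner-centered frame.}
#'   \item{ang_vel_rad_s}{time derivative of `ang_pos_rad`.}
#'   \item{sideways_frac}{|v_perp| / (|v_perp| + |v_par| + eps) of the male
#'     velocity relative to its body axis, in \[0, 1\].}
#'   \item{wing_max_deg}{max of the male's two wing angles.}
#'   \item{body_len_mm, body_len_other_mm}{body lengths.}
#' }
#'
#' @param traj A [trajectory_set()].
#' @param params A [feature_params()].
#' @return A `feature_table` data frame with `fps` and frame-count
#'   attributes; all values finite.
#' @export
compute_features <- function(traj, params = feature_params()) {
  stopifnot(inherits(traj, "trajectory_set"),
            inherits(params, "feature_params"))
  nT <- session_frames(traj)
  if (nT < 2L) stop("at least 2 frames required: velocities are undefined")
  fps <- session_fps(traj)

  m <- traj[traj$fly == "male", ]
  o <- traj[traj$fly == "other", ]

  w <- params$smoothing_window_frames
  mx <- moving_average(m$x_mm, w); my <- moving_average(m$y_mm, w)
  ox <- moving_average(o$x_mm, w); oy <- moving_average(o$y_mm, w)

  vxm <- central_diff(mx, fps); vym <- central_diff(my, fps)
  vxo <- central_diff(ox, fps); vyo <- central_diff(oy, fps)
  speed_m <- sqrt(vxm^2 + vym^2)
  speed_o <- sqrt(vxo^2 + vyo^2)

  step <- sqrt(diff(mx)^2 + diff(my)^2) * fps   # length T-1
  peak <- pmax(c(step[1L], step), c(step, step[nT - 1L]))

  dxo <- ox - mx; dyo <- oy - my
  dist <- sqrt(dxo^2 + dyo^2)
  approach <- -central_diff(dist, fps)

  facing <- angle_between_deg(cos(m$theta), sin(m$theta), dxo, dyo)
  behind <- angle_between_deg(cos(o$theta), sin(o$theta), -dxo, -dyo)

  raw_ang <- atan2(my - oy, mx - ox)
  ang_pos <- raw_ang[1L] + cumsum(c(0, wrap_pi(diff(raw_ang))))
  ang_vel <- central_diff(ang_pos, fps)

  v_par <- vxm * cos(m$theta) + vym * sin(m$theta)
  v_perp <- -vxm * sin(m$theta) + vym * cos(m$theta)
  sideways <- abs(v_perp) / (abs(v_perp) + abs(v_par) + params$eps)

  out <- data.frame(
    frame = m$frame,
    speed_mm_s = speed_m,
    speed_other_mm_s = speed_o,
    peak_speed_mm_s = peak,
    approach_speed_mm_s = approach,
    dist_mm = dist,
    facing_deg = facing,
    behind_deg = behind,
    ang_pos_rad = ang_pos,
    ang_vel_rad_s = ang_vel,
    sideways_frac = sideways,
    wing_max_deg = pmax(m$wing_left_deg, m$wing_right_deg),
    body_len_mm = m$body_len_mm,
    body_len_other_mm = o$body_len_mm
  )
  stopifnot(all(vapply(out, function(col) all(is.finite(col)), logical(1))))
  structure(out, fps = fps, n_frames = nT,
            class = c("feature_table", "data.frame"))
}

#' Export a feature table as CSV (one row per frame)
#' @param feat A `feature_table` from [compute_features()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_features <- function(feat, path) {
  stopifnot(inherits(feat, "feature_table"))
  utils::write.csv(as.data.frame(feat), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Rotate a whole session about the arena center
#'
#' Rigid rotation of both flies' positions and orientations; wing angles
#' and body lengths are untouched. Useful for checking the rotation
#' invariance of features and detectors.
#'
#' @param traj A [trajectory_set()].
#' @param angle_rad Rotation angle in radians (counter-clockwise).
#' @return A rotated [trajectory_set()].
#' @export
rotate_trajectory <- function(traj, angle_rad) {
  stopifnot(inherits(traj, "trajectory_set"))
  arena <- attr(traj, "arena")
  cx <- arena$arena_center_mm[1]; cy <- arena$arena_center_mm[2]
  df <- as.data.frame(traj)
  x0 <- df$x_mm - cx; y0 <- df$y_mm - cy
  ca <- cos(angle_rad); sa <- sin(angle_rad)
  df$x_mm <- cx + ca * x0 - sa * y0
  df$y_mm <- cy + sa * x0 + ca * y0
  df$theta <- df$theta + angle_rad
  trajectory_set(df, arena)
}
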