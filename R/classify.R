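# Rule-based detectors for the six behaviors, persistence filtering, the
# duration-floor post-filter and aggression-intensity categories.

#' Detector thresholds
#'
#' All tunable thresholds of the six rule-based detectors. Persistence
#' requirements that originate as frame counts at 25 fps (wing extension
#' and circling: 13 frames = 0.5 s) are stored in seconds and converted
#' with `round(seconds * fps)`, so a 30 fps session uses 15 frames;
#' following keeps its literal 25-frame requirement. Mounting duration
#' bands are stored in frames and assume 30 fps recordings
#' (10 frames = 0.33 s, 1350 frames = 45 s).
#'
#' @param wing_angle_deg Wing-extension threshold on the body-axis /
#'   wing-tip angle (degrees, strict `>`). Default 30.
#' @param wing_persist_s Minimum wing-extension run length (seconds).
#'   Default 0.5.
#' @param lunge_speed_mm_s Minimum peak centroid speed for a lunge (mm/s).
#'   Default 200.
#' @param lunge_max_dist_mm Maximum inter-fly distance at a lunge (mm).
#'   Default 5.
#' @param lunge_facing_deg Maximum facing angle at a lunge (degrees).
#'   Default 45.
#' @param lunge_refractory_frames Qualifying frames closer than this many
#'   frames collapse to one event. Default 3.
#' @param follow_min_mm,follow_max_mm Following distance band (mm).
#'   Defaults 2 and 5.
#' @param follow_speed_mm_s Minimum speed of *both* flies during following
#'   (mm/s). Default 2.
#' @param follow_persist_frames Minimum following run length (frames).
#'   Default 25.
#' @param follow_behind_deg Minimum rear angle: the male must sit in the
#'   rear sector of the female (degrees, 180 = directly behind).
#'   Default 120.
#' @param circle_max_dist_mm Maximum distance during circling (mm).
#'   Default 5.
#' @param circle_min_ang_vel_rad_s Minimum absolute angular velocity around
#'   the partner (rad/s). Default 1.
#' @param circle_min_sideways Minimum sideways fraction of the male's
#'   motion. Default 0.5.
#' @param circle_persist_s Minimum circling run length (seconds).
#'   Default 0.5.
#' @param mount_dist_frac_bodylen Mounting proximity threshold as a
#'   fraction of the mean body length of the pair. Default 0.5.
#' @param mount_max_speed_mm_s Maximum speed of both flies during mounting
#'   (mm/s). Default 2.
#' @param attempt_min_frames Minimum mounting run counted as attempted
#'   copulation (frames). Default 10.
#' @param copul_min_frames Mounting runs at least this long are copulation
#'   (frames). Default 1350.
#' @param duration_floor_coverage Fraction of reference (manual) bouts that
#'   must meet the duration floor of [apply_duration_floor()]. Default 0.98.
#' @return A `classifier_params` object.
#' @export
classifier_params <- function(wing_angle_deg = 30,
                              wing_persist_s = 0.5,
                              lunge_speed_mm_s = 200,
                              lunge_max_dist_mm = 5,
                              lunge_facing_deg = 45,
                              lunge_refractory_frames = 3L,
                              follow_min_mm = 2,
                              follow_max_mm = 5,
                              follow_speed_mm_s = 2,
                              follow_persist_frames = 25L,
                              follow_behind_deg = 120,
                              circle_max_dist_mm = 5,
                              circle_min_ang_vel_rad_s = 1,
                              circle_min_sideways = 0.5,
                              circle_persist_s = 0.5,
                              mount_dist_frac_bodylen = 0.5,
                              mount_max_speed_mm_s = 2,
                              attempt_min_frames = 10L,
                              copul_min_frames = 1350L,
                              duration_floor_coverage = 0.98) {
  p <- list(wing_angle_deg = wing_angle_deg,
            wing_persist_s = wing_persist_s,
            lunge_speed_mm_s = lunge_speed_mm_s,
            lunge_max_dist_mm = lunge_max_dist_mm,
            lunge_facing_deg = lunge_facing_deg,
            lunge_refractory_frames = as.integer(lunge_refractory_frames),
            follow_min_mm = follow_min_mm,
            follow_max_mm = follow_max_mm,
            follow_speed_mm_s = follow_speed_mm_s,
            follow_persist_frames = as.integer(follow_persist_frames),
            follow_behind_deg = follow_behind_deg,
            circle_max_dist_mm = circle_max_dist_mm,
            circle_min_ang_vel_rad_s = circle_min_ang_vel_rad_s,
            circle_min_sideways = circle_min_sideways,
            circle_persist_s = circle_persist_s,
            mount_dist_frac_bodylen = mount_dist_frac_bodylen,
            mount_max_speed_mm_s = mount_max_speed_mm_s,
            attempt_min_frames = as.integer(attempt_min_frames),
            copul_min_frames = as.integer(copul_min_frames),
            duration_floor_coverage = duration_floor_coverage)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1L && v > 0,
                  logical(1)))) {
    stop("all classifier thresholds must be single positive numbers")
  }
  if (p$attempt_min_frames >= p$copul_min_frames) {
    stop("attempt_min_frames must be < copul_min_frames")
  }
  if (p$duration_floor_coverage > 1) {
    stop("duration_floor_coverage must lie in (0, 1]")
  }
  if (p$follow_min_mm >= p$follow_max_mm) {
    stop("follow_min_mm must be < follow_max_mm")
  }
  structure(p, class = "classifier_params")
}

#' Read detector thresholds from a YAML config file
#'
#' The file holds a flat mapping mirroring [classifier_params()]
#' field-for-field; absent fields keep their defaults, unknown fields are
#' an error.
#'
#' @param path YAML file path.
#' @return A `classifier_params` object.
#' @export
read_classifier_params <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(classifier_params))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0L) {
    stop("unknown classifier parameter(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  }
  do.call(classifier_params, vals)
}

#' Write detector thresholds to a YAML config file
#' @param params A [classifier_params()].
#' @param path Output YAML path.
#' @return The path, invisibly.
#' @export
write_classifier_params <- function(params, path) {
  stopifnot(inherits(params, "classifier_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

# Runs of TRUE at least min_frames long, as a male bout table.
runs_to_bouts <- function(cand, behavior, min_frames, fps) {
  runs <- logical_runs(cand)
  runs <- runs[runs$end - runs$start >= min_frames, , drop = FALSE]
  if (nrow(runs) == 0L) {
    return(bout_table(NULL, fps = fps, n_frames = length(cand)))
  }
  bout_table(data.frame(behavior = behavior, fly = "male",
                        start = runs$start, end = runs$end),
             fps = fps, n_frames = length(cand))
}

#' Detect unilateral wing extension
#'
#' Candidate frames are those where the larger wing angle strictly exceeds
#' `wing_angle_deg`; runs shorter than `round(wing_persist_s * fps)` frames
#' are discarded. A constant angle of exactly 30 degrees never triggers.
#'
#' @param feat A `feature_table` from [compute_features()].
#' @param params A [classifier_params()].
#' @param fps Frames per second (defaults to the feature table's).
#' @return A [bout_table()] of `wing_extension` bouts.
#' @export
detect_wing_extension <- function(feat, params = classifier_params(),
                                  fps = session_fps(feat)) {
  stopifnot(inherits(feat, "feature_table"))
  cand <- feat$wing_max_deg > params$wing_angle_deg
  runs_to_bouts(cand, "wing_extension",
                seconds_to_frames(params$wing_persist_s, fps), fps)
}

#' Detect aggressive lunges
#'
#' A lunge is an impulsive strike: the attacker snaps onto a nearby, faced
#' opponent at very high speed. Qualifying frames satisfy
#' `peak_speed_mm_s >= lunge_speed_mm_s`, `dist_mm <= lunge_max_dist_mm`
#' and `facing_deg <= lunge_facing_deg`. Qualifying frames closer together
#' than `lunge_refractory_frames` collapse to a single event at the
#' peak-speed frame (earliest frame on exact ties). Every emitted bout is
#' one frame long.
#'
#' The body-pitch component of the classical lunge description (the fly
#' rearing up by ~45 degrees) is unobservable in planar centroid tracks and
#' is deliberately not part of this rule; proximity, facing and the speed
#' impulse stand in for it.
#'
#' @inheritParams detect_wing_extension
#' @return A [bout_table()] of single-frame `lunge` events.
#' @export
detect_lunge <- function(feat, params = classifier_params(),
                         fps = session_fps(feat)) {
  stopifnot(inherits(feat, "feature_table"))
  qual <- which(feat$peak_speed_mm_s >= params$lunge_speed_mm_s &
                feat$dist_mm <= params$lunge_max_dist_mm &
                feat$facing_deg <= params$lunge_facing_deg)
  nT <- session_frames(feat)
  if (length(qual) == 0L) return(bout_table(NULL, fps = fps, n_frames = nT))
  cluster <- cumsum(c(1L, diff(qual) > params$lunge_refractory_frames))
  events <- vapply(split(qual, cluster), function(idx) {
    idx[which.max(feat$peak_speed_mm_s[idx])]
  }, integer(1))
  starts <- feat$frame[events]
  bout_table(data.frame(behavior = "lunge", fly = "male",
                        start = starts, end = starts + 1L),
             fps = fps, n_frames = nT)
}

#' Detect following
#'
#' The male trails 2-5 mm behind the walking female while both move at
#' >= 2 mm/s; candidate frames additionally require the male to sit in the
#' female's rear sector (`behind_deg >= follow_behind_deg`). Runs of at
#' least `follow_persist_frames` frames are kept.
#'
#' @inheritParams detect_wing_extension
#' @return A [bout_table()] of `following` bouts.
#' @export
detect_following <- function(feat, params = classifier_params(),
                             fps = session_fps(feat)) {
  stopifnot(inherits(feat, "feature_table"))
  cand <- feat$dist_mm >= params$follow_min_mm &
    feat$dist_mm <= params$follow_max_mm &
    feat$behind_deg >= params$follow_behind_deg &
    feat$speed_mm_s >= params$follow_speed_mm_s &
    feat$speed_other_mm_s >= params$follow_speed_mm_s
  runs_to_bouts(cand, "following", params$follow_persist_frames, fps)
}

#' Detect circling
#'
#' Sideways drift of the male around the nearby female: candidate frames
#' satisfy `dist_mm <= circle_max_dist_mm`,
#' `|ang_vel_rad_s| >= circle_min_ang_vel_rad_s` and
#' `sideways_frac >= circle_min_sideways`; runs shorter than
#' `round(circle_persist_s * fps)` frames are discarded.
#'
#' @inheritParams detect_wing_extension
#' @return A [bout_table()] of `circling` bouts.
#' @export
detect_circling <- function(feat, params = classifier_params(),
                            fps = session_fps(feat)) {
  stopifnot(inherits(feat, "feature_table"))
  cand <- feat$dist_mm <= params$circle_max_dist_mm &
    abs(feat$ang_vel_rad_s) >= params$circle_min_ang_vel_rad_s &
    feat$sideways_frac >= params$circle_min_sideways
  runs_to_bouts(cand, "circling",
                seconds_to_frames(params$circle_persist_s, fps), fps)
}

#' Detect mounting: attempted copulation and copulation
#'
#' Trackers see mounting as a sustained near-merge of the two centroids at
#' low speed: candidate frames satisfy
#' `dist_mm <= mount_dist_frac_bodylen * mean pair body length` with both
#' speeds `<= mount_max_speed_mm_s`. Maximal runs of at least
#' `copul_min_frames` frames are `copulation`; runs in
#' `[attempt_min_frames, copul_min_frames)` are `attempted_copulation`;
#' shorter runs are discarded. A run of exactly `copul_min_frames` (45 s at
#' 30 fps) counts as copulation. Abdominal curling without mounting, part
#' of the classical attempted-copulation description, has no signature in
#' centroid tracks and is not detected.
#'
#' @inheritParams detect_wing_extension
#' @return A [bout_table()] with `attempted_copulation` and `copulation`
#'   bouts.
#' @export
detect_mounting <- function(feat, params = classifier_params(),
                            fps = session_fps(feat)) {
  stopifnot(inherits(feat, "feature_table"))
  pair_len <- mean(c(mean(feat$body_len_mm), mean(feat$body_len_other_mm)))
  thr <- params$mount_dist_frac_bodylen * pair_len
  cand <- feat$dist_mm <= thr &
    feat$speed_mm_s <= params$mount_max_speed_mm_s &
    feat$speed_other_mm_s <= params$mount_max_speed_mm_s
  runs <- logical_runs(cand)
  n <- runs$end - runs$start
  keep <- n >= params$attempt_min_frames
  runs <- runs[keep, , drop = FALSE]
  n <- n[keep]
  nT <- session_frames(feat)
  if (nrow(runs) == 0L) return(bout_table(NULL, fps = fps, n_frames = nT))
  behavior <- ifelse(n >= params$copul_min_frames,
                     "copulation", "attempted_copulation")
  bout_table(data.frame(behavior = behavior, fly = "male",
                        start = runs$start, end = runs$end),
             fps = fps, n_frames = nT)
}

#' Duration-floor post-filter
#'
#' Removes predicted bouts shorter than almost all manually annotated
#' bouts: the floor is the `(1 - coverage)` empirical quantile (lower
#' interpolation) of the reference durations, so a fraction `coverage` of
#' reference bouts meet the floor. Single-frame lunge events are exempt.
#'
#' @param bouts Predicted [bout_table()].
#' @param reference_durations Non-empty integer vector of manual bout
#'   durations (frames).
#' @param coverage Fraction in (0, 1]; default 0.98. `coverage = 1` uses
#'   the minimum reference duration as the floor.
#' @return The filtered [bout_table()].
#' @export
apply_duration_floor <- function(bouts, reference_durations,
                                 coverage = 0.98) {
  stopifnot(inherits(bouts, "bout_table"))
  if (length(reference_durations) == 0L) {
    stop("reference_durations must be non-empty")
  }
  if (!(coverage > 0 && coverage <= 1)) stop("coverage must lie in (0, 1]")
  floor_frames <- as.numeric(
    stats::quantile(reference_durations, probs = 1 - coverage, type = 1))
  keep <- bouts$behavior == "lunge" | bout_frames(bouts) >= floor_frames
  bout_table(as.data.frame(bouts)[keep, , drop = FALSE],
             fps = session_fps(bouts), n_frames = session_frames(bouts))
}

#' Run all six detectors on a session
#'
#' Extracts features, runs every detector, and returns the normalized bout
#' table together with its ethogram. Copulation dominates: frames labeled
#' `copulation` are cleared of simultaneous `wing_extension`, `following`
#' and `circling` labels, so a merged pair is not double-counted as active
#' courtship.
#'
#' @param traj A [trajectory_set()].
#' @param params A [classifier_params()].
#' @param feature_opts A [feature_params()].
#' @return A list with elements `bouts` (normalized [bout_table()]) and
#'   `ethogram` (the matching [ethogram()]).
#' @export
classify_all <- function(traj, params = classifier_params(),
                         feature_opts = feature_params()) {
  feat <- compute_features(traj, feature_opts)
  fps <- session_fps(feat)
  parts <- list(detect_lunge(feat, params, fps),
                detect_wing_extension(feat, params, fps),
                detect_following(feat, params, fps),
                detect_circling(feat, params, fps),
                detect_mounting(feat, params, fps))
  all_bouts <- do.call(rbind, lapply(parts, as.data.frame))
  bt <- bout_table(all_bouts, fps = fps, n_frames = session_frames(feat))
  eth <- ethogram_from_bouts(bt)
  cop <- eth[, "copulation"]
  eth[cop, c("wing_extension", "following", "circling")] <- FALSE
  bouts <- bouts_from_ethogram(eth)
  list(bouts = bouts, ethogram = eth)
}

#' Aggression-intensity category from a lunge count
#'
#' Sessions are binned by total lunge count: 0-70 `low`, 71-160 `moderate`,
#' 161-300 `high`, more than 300 `hyper`.
#'
#' @param lunge_count Non-negative integer count(s).
#' @return Factor with levels `low`, `moderate`, `high`, `hyper`.
#' @export
#' @examples
#' aggression_category(c(0, 70, 71, 160, 161, 300, 301))
aggression_category <- function(lunge_count) {
  if (any(!is.finite(lunge_count)) || any(lunge_count < 0)) {
    stop("lunge_count must be non-negative")
  }
  labels <- c("low", "moderate", "high", "hyper")
  idx <- findInterval(lunge_count, c(0, 71, 161, 301))
  factor(labels[idx], levels = labels)
}
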