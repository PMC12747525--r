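# Containers and I/O for two-fly trajectory sessions, bout tables and
# ethograms. All frame indices are 0-based; intervals are half-open
# [start, end), so a bout covers end - start frames.

BEHAVIOR_SET <- c("lunge", "wing_extension", "following", "circling",
                  "attempted_copulation", "copulation")
FLY_ROLES <- c("male", "other")

TRACK_COLUMNS <- c("frame", "fly", "x_mm", "y_mm", "theta",
                   "wing_left_deg", "wing_right_deg", "body_len_mm")

#' Behavior vocabulary
#'
#' The six behaviors the toolkit detects and evaluates: `lunge` (aggression;
#' a single-frame event), and the courtship behaviors `wing_extension`,
#' `following`, `circling`, `attempted_copulation` and `copulation`.
#'
#' @return Character vector of behavior names.
#' @export
#' @examples
#' behavior_names()
behavior_names <- function() BEHAVIOR_SET

#' Recording-session geometry and timing
#'
#' Describes one circular-arena recording: frame rate, arena diameter,
#' session length and arena center. Defaults match 30 fps smartphone
#' recordings in a 13 mm aggression arena.
#'
#' @param fps Frames per second (Hz), > 0. Default 30.
#' @param arena_diameter_mm Arena diameter in mm, > 0. Typical values:
#'   13 (aggression), 11 (courtship).
#' @param duration_frames Session length in frames, >= 1.
#' @param arena_center_mm Numeric length-2 vector, arena center in mm.
#' @return An `arena_config` object (list).
#' @export
#' @examples
#' arena_config(fps = 30, arena_diameter_mm = 11, duration_frames = 27000)
arena_config <- function(fps = 30, arena_diameter_mm = 13,
                         duration_frames = 60L * 30L,
                         arena_center_mm = c(0, 0)) {
  stopifnot(is.numeric(fps), length(fps) == 1L, fps > 0,
            is.numeric(arena_diameter_mm), length(arena_diameter_mm) == 1L,
            arena_diameter_mm > 0,
            is.numeric(duration_frames), length(duration_frames) == 1L,
            duration_frames >= 1,
            is.numeric(arena_center_mm), length(arena_center_mm) == 2L)
  structure(list(fps = fps,
                 arena_diameter_mm = arena_diameter_mm,
                 duration_frames = as.integer(duration_frames),
                 arena_center_mm = as.numeric(arena_center_mm)),
            class = "arena_config")
}

#' @export
print.arena_config <- function(x, ...) {
  cat(sprintf("<arena_config> %g fps, %g mm arena, %d frames (%.1f s)\n",
              x$fps, x$arena_diameter_mm, x$duration_frames,
              x$duration_frames / x$fps))
  invisible(x)
}

#' Validated per-frame two-fly pose table
#'
#' A `trajectory_set` is a data frame with one row per frame per fly and
#' columns `frame` (0-based, contiguous), `fly` (`"male"` focal /
#' `"other"` partner), `x_mm`, `y_mm` (centroid, arena-centered mm,
#' y up), `theta` (body orientation, radians, direction of the head),
#' `wing_left_deg`, `wing_right_deg` (angle between body axis and wing
#' tip line, degrees in \[0, 180)), and `body_len_mm` (> 0).
#' Both flies must be present at every frame and positions must lie
#' inside the arena disc.
#'
#' @param tracks Data frame with the columns above.
#' @param arena An [arena_config()].
#' @return A `trajectory_set` (data frame, rows ordered by frame then fly,
#'   with the arena stored as an attribute).
#' @export
trajectory_set <- function(tracks, arena) {
  stopifnot(inherits(arena, "arena_config"))
  missing_cols <- setdiff(TRACK_COLUMNS, names(tracks))
  if (length(missing_cols) > 0L) {
    stop("tracks format error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tracks <- as.data.frame(tracks)[, TRACK_COLUMNS]
  tracks$fly <- as.character(tracks$fly)
  bad_fly <- setdiff(unique(tracks$fly), FLY_ROLES)
  if (length(bad_fly) > 0L) {
    stop("unsupported fly identifier(s): ", paste(bad_fly, collapse = ", "),
         " (exactly two flies with roles 'male' and 'other' are supported)")
  }
  if (nrow(tracks) == 0L) stop("empty trajectory: at least one frame required")

  nT <- max(tracks$frame) + 1L
  for (role in FLY_ROLES) {
    fr <- sort(tracks$frame[tracks$fly == role])
    if (!identical(as.integer(fr), seq.int(0L, nT - 1L))) {
      missing_fr <- setdiff(seq.int(0L, nT - 1L), fr)
      if (length(missing_fr) > 0L) {
        stop(sprintf("trajectory validation error: gap at frame %d for fly '%s'",
                     missing_fr[1L], role))
      }
      stop("trajectory validation error: duplicated frames for fly '", role, "'")
    }
  }

  num_cols <- setdiff(TRACK_COLUMNS, "fly")
  for (cc in num_cols) {
    if (!all(is.finite(tracks[[cc]]))) {
      stop("trajectory validation error: non-finite values in column ", cc)
    }
  }
  r <- sqrt((tracks$x_mm - arena$arena_center_mm[1])^2 +
            (tracks$y_mm - arena$arena_center_mm[2])^2)
  if (any(r > arena$arena_diameter_mm / 2 + 1e-6)) {
    stop("trajectory validation error: positions outside the arena disc")
  }
  wings <- c(tracks$wing_left_deg, tracks$wing_right_deg)
  if (any(wings < 0 | wings >= 180)) {
    stop("trajectory validation error: wing angles must lie in [0, 180)")
  }
  if (any(tracks$body_len_mm <= 0)) {
    stop("trajectory validation error: body_len_mm must be > 0")
  }

  tracks <- tracks[order(tracks$frame, match(tracks$fly, FLY_ROLES)), ]
  rownames(tracks) <- NULL
  structure(tracks, arena = arena, n_frames = nT,
            class = c("trajectory_set", "data.frame"))
}

#' Number of frames in a session object
#'
#' @param x A `trajectory_set`, `bout_table`, `ethogram` or `feature_table`.
#' @return Integer frame count T.
#' @export
session_frames <- function(x) {
  nT <- attr(x, "n_frames")
  if (is.null(nT) && inherits(x, "ethogram")) nT <- nrow(x)
  if (is.null(nT)) stop("object carries no frame count")
  as.integer(nT)
}

#' Frame rate of a session object
#' @param x An object with an `fps` or arena attribute.
#' @return Frames per second.
#' @export
session_fps <- function(x) {
  fps <- attr(x, "fps")
  if (is.null(fps)) {
    ar <- attr(x, "arena")
    if (!is.null(ar)) fps <- ar$fps
  }
  if (is.null(fps)) stop("object carries no fps")
  fps
}

#' Read a two-fly tracks CSV
#'
#' Reads the documented tracker-export dialect (UTF-8, header row, columns
#' `frame,fly,x_mm,y_mm,theta,wing_left_deg,wing_right_deg,body_len_mm`)
#' and validates it. Frames are re-indexed to a 0-based contiguous range;
#' a gap in the frame sequence is an error naming the first missing frame.
#'
#' @param path CSV file path.
#' @param arena An [arena_config()] describing the recording.
#' @return A [trajectory_set()].
#' @export
read_tracks <- function(path, arena) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(TRACK_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("tracks format error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (length(unique(df$fly)) > 2L) {
    stop("unsupported: more than two flies in ", path)
  }
  uf <- sort(unique(df$frame))
  full <- seq.int(min(uf), max(uf))
  gap <- setdiff(full, uf)
  if (length(gap) > 0L) {
    stop(sprintf("trajectory validation error: gap at frame %d", gap[1L]))
  }
  df$frame <- as.integer(df$frame - min(uf))
  trajectory_set(df, arena)
}

#' Write a two-fly tracks CSV
#'
#' Inverse of [read_tracks()]: `read_tracks(write_tracks(x))` reproduces
#' `x` up to numeric formatting (<= 1e-9 relative).
#'
#' @param traj A [trajectory_set()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_tracks <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_set"))
  df <- as.data.frame(traj)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Labeled behavior intervals for one session
#'
#' A `bout_table` is a data frame with columns `behavior` (one of
#' [behavior_names()]), `fly` (`"male"`/`"other"`), `start`, `end`
#' (half-open 0-based frame interval) plus session metadata (`fps`, frame
#' count). Lunge bouts are single-frame events (`end - start == 1`).
#'
#' @param bouts Data frame with columns `behavior`, `fly`, `start`, `end`
#'   (zero rows allowed).
#' @param fps Frames per second of the session.
#' @param n_frames Total frames T in the session; all bouts must fit in
#'   `[0, T)`.
#' @return A `bout_table`.
#' @export
bout_table <- function(bouts, fps, n_frames) {
  stopifnot(is.numeric(fps), fps > 0, is.numeric(n_frames), n_frames >= 1)
  need <- c("behavior", "fly", "start", "end")
  if (is.null(bouts) || nrow(as.data.frame(bouts)) == 0L) {
    bouts <- data.frame(behavior = character(), fly = character(),
                        start = integer(), end = integer())
  }
  bouts <- as.data.frame(bouts)
  missing_cols <- setdiff(need, names(bouts))
  if (length(missing_cols) > 0L) {
    stop("bout table format error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bouts <- bouts[, need]
  bouts$behavior <- as.character(bouts$behavior)
  bouts$fly <- as.character(bouts$fly)
  bouts$start <- as.integer(bouts$start)
  bouts$end <- as.integer(bouts$end)
  bad_b <- setdiff(unique(bouts$behavior), BEHAVIOR_SET)
  if (length(bad_b) > 0L) {
    stop("unknown behavior(s): ", paste(bad_b, collapse = ", "))
  }
  bad_f <- setdiff(unique(bouts$fly), FLY_ROLES)
  if (length(bad_f) > 0L) {
    stop("unknown fly role(s): ", paste(bad_f, collapse = ", "))
  }
  if (nrow(bouts) > 0L) {
    if (any(bouts$start < 0L) || any(bouts$start >= bouts$end)) {
      stop("bout validation error: require 0 <= start < end")
    }
    if (any(bouts$end > n_frames)) {
      stop("bout range error: bout extends past frame ", n_frames)
    }
    lunges <- bouts$behavior == "lunge"
    if (any(bouts$end[lunges] - bouts$start[lunges] != 1L)) {
      stop("bout validation error: lunge bouts must be single-frame events")
    }
  }
  rownames(bouts) <- NULL
  structure(bouts, fps = fps, n_frames = as.integer(n_frames),
            class = c("bout_table", "data.frame"))
}

#' Bout durations in frames
#' @param bouts A [bout_table()].
#' @return Integer vector `end - start`.
#' @export
bout_frames <- function(bouts) {
  as.integer(bouts$end - bouts$start)
}

#' Read a bouts CSV (columns behavior,fly,start,end; half-open, 0-based)
#' @inheritParams bout_table
#' @param path CSV file path.
#' @return A [bout_table()].
#' @export
read_bouts <- function(path, fps, n_frames) {
  if (!file.exists(path)) stop("file not found: ", path)
  bout_table(utils::read.csv(path, stringsAsFactors = FALSE), fps, n_frames)
}

#' Write a bouts CSV
#' @param bouts A [bout_table()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_bouts <- function(bouts, path) {
  stopifnot(inherits(bouts, "bout_table"))
  utils::write.csv(as.data.frame(bouts), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-frame behavior matrix for the focal male
#'
#' A T x B logical matrix (`B = behavior_names()`) recording, for every
#' frame, whether the focal male fly is performing each behavior.
#'
#' @param mat Logical matrix; column names must be a subset of
#'   [behavior_names()] (missing behaviors are filled with all-FALSE
#'   columns).
#' @param fps Frames per second.
#' @return An `ethogram`.
#' @export
ethogram <- function(mat, fps) {
  stopifnot(is.matrix(mat), is.logical(mat), is.numeric(fps), fps > 0)
  bad <- setdiff(colnames(mat), BEHAVIOR_SET)
  if (length(bad) > 0L) stop("unknown behavior(s): ", paste(bad, collapse = ", "))
  full <- matrix(FALSE, nrow = nrow(mat), ncol = length(BEHAVIOR_SET),
                 dimnames = list(NULL, BEHAVIOR_SET))
  full[, colnames(mat)] <- mat
  structure(full, fps = fps, n_frames = nrow(full),
            class = "ethogram")
}

#' All-FALSE ethogram of a given length
#' @param n_frames Frame count T.
#' @param fps Frames per second.
#' @return An [ethogram()].
#' @export
empty_ethogram <- function(n_frames, fps) {
  ethogram(matrix(FALSE, nrow = n_frames, ncol = length(BEHAVIOR_SET),
                  dimnames = list(NULL, BEHAVIOR_SET)), fps)
}

#' @export
print.ethogram <- function(x, ...) {
  cat(sprintf("<ethogram> %d frames x %d behaviors, %g fps\n",
              nrow(x), ncol(x), attr(x, "fps")))
  pos <- colSums(x)
  for (b in colnames(x)) cat(sprintf("  %-22s %d positive frames\n", b, pos[b]))
  invisible(x)
}

#' Run-length encode an ethogram into bouts
#'
#' Maximal runs of consecutive TRUE frames in each behavior column become
#' half-open bouts attributed to the focal male.
#'
#' @param eth An [ethogram()].
#' @return A normalized [bout_table()].
#' @export
#' @examples
#' e <- empty_ethogram(12, 30)
#' e[c(4, 5, 6, 10), "wing_extension"] <- TRUE
#' bouts_from_ethogram(e)  # bouts [3,6) and [9,10)
bouts_from_ethogram <- function(eth) {
  stopifnot(inherits(eth, "ethogram"))
  out <- lapply(colnames(eth), function(b) {
    runs <- logical_runs(eth[, b])
    if (nrow(runs) == 0L) return(NULL)
    data.frame(behavior = b, fly = "male", start = runs$start, end = runs$end)
  })
  bouts <- do.call(rbind, out)
  bt <- bout_table(bouts, fps = attr(eth, "fps"), n_frames = nrow(eth))
  normalize_bouts(bt)
}

#' Paint bouts onto a per-frame ethogram
#'
#' Frame f is TRUE for behavior b iff some b-bout contains f (union over
#' bouts, regardless of the `fly` field; the ethogram describes the focal
#' male and all built-in detectors emit male bouts).
#'
#' @param bouts A [bout_table()].
#' @param n_frames Frame count T; defaults to the table's session length.
#' @return An [ethogram()].
#' @export
ethogram_from_bouts <- function(bouts, n_frames = session_frames(bouts)) {
  stopifnot(inherits(bouts, "bout_table"))
  if (nrow(bouts) > 0L && any(bouts$end > n_frames)) {
    stop("bout range error: bout extends past frame ", n_frames)
  }
  mat <- matrix(FALSE, nrow = n_frames, ncol = length(BEHAVIOR_SET),
                dimnames = list(NULL, BEHAVIOR_SET))
  for (i in seq_len(nrow(bouts))) {
    mat[(bouts$start[i] + 1L):bouts$end[i], bouts$behavior[i]] <- TRUE
  }
  ethogram(mat, fps = session_fps(bouts))
}

#' Normalize a bout table
#'
#' Sorts by (behavior, fly, start) and merges overlapping or frame-adjacent
#' (`end == next start`) bouts of the same behavior and fly. Lunge bouts,
#' being counted single-frame events, are exempt from adjacency merging:
#' only exact duplicates are dropped. Idempotent, and preserves the
#' per-frame indicator set.
#'
#' @param bouts A [bout_table()].
#' @return A normalized [bout_table()].
#' @export
normalize_bouts <- function(bouts) {
  stopifnot(inherits(bouts, "bout_table"))
  fps <- session_fps(bouts)
  nT <- session_frames(bouts)
  if (nrow(bouts) == 0L) return(bouts)
  pieces <- split(as.data.frame(bouts),
                  list(bouts$behavior, bouts$fly), drop = TRUE)
  merged <- lapply(pieces, function(g) {
    g <- g[order(g$start, g$end), ]
    if (g$behavior[1L] == "lunge") {
      return(g[!duplicated(g$start), ])
    }
    starts <- g$start; ends <- g$end
    out_s <- starts[1L]; out_e <- ends[1L]
    keep_s <- integer(0); keep_e <- integer(0)
    for (i in seq_along(starts)[-1L]) {
      if (starts[i] <= out_e) {           # overlap or adjacency: merge
        out_e <- max(out_e, ends[i])
      } else {
        keep_s <- c(keep_s, out_s); keep_e <- c(keep_e, out_e)
        out_s <- starts[i]; out_e <- ends[i]
      }
    }
    keep_s <- c(keep_s, out_s); keep_e <- c(keep_e, out_e)
    data.frame(behavior = g$behavior[1L], fly = g$fly[1L],
               start = keep_s, end = keep_e)
  })
  out <- do.call(rbind, merged)
  out <- out[order(match(out$behavior, BEHAVIOR_SET), out$start), ]
  bout_table(out, fps = fps, n_frames = nT)
}

#' Write an ethogram CSV (frame column + one 0/1 column per behavior)
#' @param eth An [ethogram()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_ethogram <- function(eth, path) {
  stopifnot(inherits(eth, "ethogram"))
  df <- data.frame(frame = seq_len(nrow(eth)) - 1L)
  for (b in colnames(eth)) df[[b]] <- as.integer(eth[, b])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ethogram CSV written by [write_ethogram()]
#' @param path CSV file path.
#' @param fps Frames per second.
#' @return An [ethogram()].
#' @export
read_ethogram <- function(path, fps) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  cols <- intersect(BEHAVIOR_SET, names(df))
  mat <- as.matrix(df[, cols, drop = FALSE]) != 0
  colnames(mat) <- cols
  ethogram(mat, fps)
}

# Maximal runs of TRUE in a logical vector as half-open 0-based intervals.
logical_runs <- function(x) {
  x <- as.logical(x)
  r <- rle(x)
  ends_1 <- cumsum(r$lengths)
  starts_1 <- ends_1 - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts_1[keep] - 1L, end = ends_1[keep])
}
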