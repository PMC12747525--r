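# Evaluation framework: bout-level and frame-level matching against
# manual annotations, precision/recall/F1, behavioral index, unit
# conversions and per-video regression.

new_match_counts <- function(level, tp, fp, fn, n_truth, n_pred) {
  structure(list(level = level, tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), n_truth = as.integer(n_truth),
                 n_pred = as.integer(n_pred)),
            class = "match_counts")
}

#' @export
print.match_counts <- function(x, ...) {
  cat(sprintf("<match_counts level=%s> tp=%d fp=%d fn=%d (truth %d, pred %d)\n",
              x$level, x$tp, x$fp, x$fn, x$n_truth, x$n_pred))
  invisible(x)
}

#' Bout-level matching of predictions against ground truth
#'
#' A ground-truth bout overlapped (>= 1 shared frame, half-open interval
#' intersection) by any predicted bout is one TP, regardless of how many
#' predictions cover it; a predicted bout spanning several truth bouts
#' yields one TP per truth bout covered. Predicted bouts overlapping no
#' truth bout are FP; truth bouts with no overlapping prediction are FN.
#' TP therefore counts truth bouts (`tp + fn == n_truth`) while FP counts
#' predicted bouts; bout-level precision mixes the two unit systems. This
#' asymmetric scheme is the field's bout-matching convention and is kept
#' literally; set `symmetric = TRUE` to instead count TP on the prediction
#' side for the precision numerator (tp_pred = predicted bouts overlapping
#' any truth bout).
#'
#' Touching bouts (`[5,10)` vs `[10,15)`) share no frame and do not
#' overlap.
#'
#' @param pred,truth Normalized [bout_table()]s over the same session
#'   length.
#' @param behavior Behavior name to score.
#' @param symmetric If TRUE, `tp` counts predicted bouts overlapping truth
#'   (default FALSE: the literal asymmetric convention).
#' @return A `match_counts` object (`level = "bout"`).
#' @export
match_bouts <- function(pred, truth, behavior, symmetric = FALSE) {
  stopifnot(inherits(pred, "bout_table"), inherits(truth, "bout_table"),
            behavior %in% BEHAVIOR_SET)
  if (session_frames(pred) != session_frames(truth)) {
    stop("prediction and truth cover different session lengths")
  }
  pr <- pred[pred$behavior == behavior, , drop = FALSE]
  tr <- truth[truth$behavior == behavior, , drop = FALSE]
  ir_p <- IRanges::IRanges(start = pr$start + 1L, end = pr$end)
  ir_t <- IRanges::IRanges(start = tr$start + 1L, end = tr$end)
  hit_t <- IRanges::countOverlaps(ir_t, ir_p) > 0L
  hit_p <- IRanges::countOverlaps(ir_p, ir_t) > 0L
  tp <- if (symmetric) sum(hit_p) else sum(hit_t)
  new_match_counts("bout", tp = tp, fp = sum(!hit_p), fn = sum(!hit_t),
                   n_truth = nrow(tr), n_pred = nrow(pr))
}

#' Frame-level matching of predictions against ground truth
#'
#' Per-frame confusion counts for one behavior: TP = predicted and true,
#' FP = predicted only, FN = true only.
#'
#' @param pred,truth [ethogram()]s of the same length.
#' @param behavior Behavior name to score.
#' @return A `match_counts` object (`level = "frame"`).
#' @export
match_frames <- function(pred, truth, behavior) {
  stopifnot(inherits(pred, "ethogram"), inherits(truth, "ethogram"),
            behavior %in% BEHAVIOR_SET)
  if (nrow(pred) != nrow(truth)) {
    stop("prediction and truth cover different session lengths")
  }
  p <- pred[, behavior]; t <- truth[, behavior]
  new_match_counts("frame",
                   tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t),
                   n_truth = sum(t), n_pred = sum(p))
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 P R / (P + R)`; 0 when both are 0.
#'
#' @param precision,recall Fractions in \[0, 1\].
#' @return F1 in \[0, 1\].
#' @export
#' @examples
#' f1_score(0.787, 0.731)  # 0.758 to three decimals
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Precision, recall and F1 from match counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`,
#' `f1 = 2PR/(P+R)`; each defined as 0 when its denominator is 0 (the
#' empty-session convention).
#'
#' @param counts A `match_counts` object from [match_bouts()] or
#'   [match_frames()].
#' @return A `behavior_metrics` list with `precision`, `recall`, `f1`
#'   (fractions in \[0, 1\]).
#' @export
metrics <- function(counts) {
  stopifnot(inherits(counts, "match_counts"))
  precision <- if (counts$tp + counts$fp > 0) {
    counts$tp / (counts$tp + counts$fp)
  } else 0
  recall <- if (counts$tp + counts$fn > 0) {
    counts$tp / (counts$tp + counts$fn)
  } else 0
  structure(list(precision = precision, recall = recall,
                 f1 = f1_score(precision, recall)),
            class = "behavior_metrics")
}

#' @export
print.behavior_metrics <- function(x, ...) {
  cat(sprintf("precision %.1f%%  recall %.1f%%  F1 %.1f%%\n",
              100 * x$precision, 100 * x$recall, 100 * x$f1))
  invisible(x)
}

#' Behavioral index: fraction of frames spent in a behavior
#'
#' The number of frames in which the focal male performs the behavior,
#' divided by the total number of frames in the recording.
#'
#' @param eth An [ethogram()].
#' @param behavior Behavior name.
#' @return Fraction in \[0, 1\].
#' @export
behavior_index <- function(eth, behavior) {
  stopifnot(inherits(eth, "ethogram"), behavior %in% BEHAVIOR_SET,
            nrow(eth) >= 1L)
  mean(eth[, behavior])
}

#' Convert a duration in seconds to a frame count
#'
#' `round(seconds * fps)` to the nearest integer; exact halves round to
#' even (base R convention).
#'
#' @param seconds Duration(s) >= 0.
#' @param fps Frames per second > 0.
#' @return Integer frame count(s).
#' @export
#' @examples
#' seconds_to_frames(45, 30)    # 1350
#' seconds_to_frames(0.33, 30)  # 10
seconds_to_frames <- function(seconds, fps) {
  stopifnot(all(seconds >= 0), fps > 0)
  as.integer(round(seconds * fps))
}

#' Convert a frame count to seconds
#' @param frames Frame count(s) >= 0.
#' @param fps Frames per second > 0.
#' @return Duration(s) in seconds.
#' @export
frames_to_seconds <- function(frames, fps) {
  stopifnot(all(frames >= 0), fps > 0)
  frames / fps
}

#' Ordinary least-squares fit of method scores against a reference
#'
#' Per-video method comparison: OLS with intercept of `y` on `x`, with
#' `r_squared = 1 - SSres/SStot`.
#'
#' @param x Reference scores (e.g. manual counts or indices); must not be
#'   constant.
#' @param y Predicted scores; same length as `x`, >= 3 points.
#' @return A `regression_fit` list with `slope`, `intercept`, `r_squared`
#'   and `n`.
#' @export
fit_regression <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 3L)
  if (stats::sd(x) == 0) stop("x is constant: regression undefined")
  fit <- stats::lm(y ~ x)
  r_squared <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r_squared,
                 n = length(x)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("y = %.4f x + %.4f   (R^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Full per-session evaluation report
#'
#' For every behavior, computes bout-level and frame-level match counts
#' and precision/recall/F1, plus behavioral indices for prediction and
#' truth. Ethograms default to being rebuilt from the bout tables.
#'
#' @param pred_bouts,truth_bouts Normalized [bout_table()]s over the same
#'   session.
#' @param pred_eth,truth_eth Optional [ethogram()]s (rebuilt from the bout
#'   tables when NULL).
#' @return A `session_report`: a nested list
#'   `behaviors$<name>$<bout|frame>` holding counts plus `precision`,
#'   `recall`, `f1`, `indices$<pred|truth>$<name>`, and `session`
#'   metadata (`n_frames`, `fps`).
#' @export
evaluate_session <- function(pred_bouts, truth_bouts,
                             pred_eth = NULL, truth_eth = NULL) {
  stopifnot(inherits(pred_bouts, "bout_table"),
            inherits(truth_bouts, "bout_table"))
  if (session_frames(pred_bouts) != session_frames(truth_bouts)) {
    stop("prediction and truth cover different session lengths")
  }
  if (is.null(pred_eth)) pred_eth <- ethogram_from_bouts(pred_bouts)
  if (is.null(truth_eth)) truth_eth <- ethogram_from_bouts(truth_bouts)

  per_behavior <- lapply(BEHAVIOR_SET, function(b) {
    cb <- match_bouts(pred_bouts, truth_bouts, b)
    cf <- match_frames(pred_eth, truth_eth, b)
    list(bout = c(unclass(cb)[c("tp", "fp", "fn", "n_truth", "n_pred")],
                  unclass(metrics(cb))),
         frame = c(unclass(cf)[c("tp", "fp", "fn", "n_truth", "n_pred")],
                   unclass(metrics(cf))))
  })
  names(per_behavior) <- BEHAVIOR_SET

  idx <- function(e) {
    out <- lapply(BEHAVIOR_SET, function(b) behavior_index(e, b))
    names(out) <- BEHAVIOR_SET
    out
  }
  structure(list(behaviors = per_behavior,
                 indices = list(pred = idx(pred_eth), truth = idx(truth_eth)),
                 session = list(n_frames = session_frames(pred_bouts),
                                fps = session_fps(pred_bouts))),
            class = "session_report")
}

#' Write a session report as JSON
#' @param report A `session_report` from [evaluate_session()].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "session_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
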