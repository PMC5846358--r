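#' Names of the seven movement parameters
#'
#' @return Character vector: speed (mm/s), acceleration (mm/s^2),
#'   locomotory_rate (mm/s), stop_number (count), stop_time (s),
#'   turning_rate (rad/s), meander (rad/mm).
#' @export
feature_names <- function() {
  c("speed", "acceleration", "locomotory_rate",
    "stop_number", "stop_time", "turning_rate", "meander")
}

# Wrap angles into (-pi, pi].
wrap_angle <- function(a) {
  w <- ((a + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

#' Per-step geometry of a segment
#'
#' Shared kernel for all seven movement parameters: one row per inter-frame
#' interval with the step length, heading (atan2 of the displacement) and
#' step speed. The heading of a zero-length step is undefined and flagged.
#'
#' @param segment A `"track_segment"` (or short `"daph_track"`) with at
#'   least 3 frames.
#' @return Data frame with columns `distance` (mm), `heading` (rad, `NA`
#'   where undefined), `step_speed` (mm/s) and `defined` (logical).
#' @export
step_geometry <- function(segment) {
  p <- track_points(segment)
  if (nrow(p) < 3L) stop("segment needs at least 3 frames")
  dt <- if (!is.null(segment$frame_interval)) segment$frame_interval else diff(p$t[1:2])
  dx <- diff(p$x)
  dy <- diff(p$y)
  d <- sqrt(dx^2 + dy^2)
  defined <- d > 0
  h <- rep(NA_real_, length(d))
  h[defined] <- atan2(dy[defined], dx[defined])
  data.frame(distance = d, heading = h, step_speed = d / dt, defined = defined)
}

#' Seven movement parameters of one segment
#'
#' Computes the canonical instantaneous movement parameters of a short
#' (typically 5-s) trajectory window:
#' \describe{
#'   \item{speed}{total path length / elapsed time (mm/s).}
#'   \item{acceleration}{mean absolute change in step speed per unit time
#'     (mm/s^2), one non-negative scalar per segment.}
#'   \item{locomotory_rate}{path length over moving steps only / moving time
#'     (mm/s); distinct from speed because the stop time is excluded from the
#'     denominator. 0 when every step is stopped.}
#'   \item{stop_number}{number of stop bouts, i.e. maximal runs of
#'     consecutive stopped steps.}
#'   \item{stop_time}{total stopped duration (s).}
#'   \item{turning_rate}{sum of absolute wrapped heading changes / elapsed
#'     time (rad/s).}
#'   \item{meander}{sum of absolute wrapped heading changes / path length
#'     (rad/mm); 0 for a motionless segment.}
#' }
#' A step is "stopped" when its speed falls below `stop_speed_threshold`.
#' Heading changes involving an undefined heading (zero-length step)
#' contribute zero angular change, keeping the output dense.
#'
#' @param segment A `"track_segment"` with >= 3 frames.
#' @param stop_speed_threshold Speed below which a step counts as stopped,
#'   in mm/s; default 1.0 (about one pixel of tracking jitter per frame).
#' @return Named numeric vector of length 7 (see [feature_names()]).
#' @examples
#' seg <- generate_segment(archetype_params("line"), seed = 1)
#' compute_features(seg)
#' @export
compute_features <- function(segment, stop_speed_threshold = 1.0) {
  if (stop_speed_threshold < 0) stop("stop_speed_threshold must be >= 0")
  g <- step_geometry(segment)
  dt <- if (!is.null(segment$frame_interval)) segment$frame_interval
        else diff(track_points(segment)$t[1:2])
  n_steps <- nrow(g)
  elapsed <- n_steps * dt
  total_dist <- sum(g$distance)

  speed <- total_dist / elapsed

  stopped <- g$step_speed < stop_speed_threshold
  stop_time <- sum(stopped) * dt
  runs <- rle(stopped)
  stop_number <- sum(runs$values)
  if (all(stopped)) {
    locomotory_rate <- 0
  } else {
    locomotory_rate <- sum(g$distance[!stopped]) / (elapsed - stop_time)
  }

  acceleration <- mean(abs(diff(g$step_speed))) / dt

  dh <- diff(g$heading)
  both_defined <- g$defined[-n_steps] & g$defined[-1L]
  turn <- abs(wrap_angle(dh))
  turn[!both_defined] <- 0
  total_turn <- sum(turn)
  turning_rate <- total_turn / elapsed
  meander <- if (total_dist > 0) total_turn / total_dist else 0

  c(speed = speed, acceleration = acceleration,
    locomotory_rate = locomotory_rate,
    stop_number = as.numeric(stop_number), stop_time = stop_time,
    turning_rate = turning_rate, meander = meander)
}

#' Feature matrix over many segments
#'
#' One row of the seven movement parameters per segment, with subject,
#' phase and segment-index metadata preserved. Optionally subsamples a
#' seeded random subset of rows, as done when selecting training segments
#' for the self-organizing map (1000 per phase in the original design).
#'
#' @param segments List of `"track_segment"` objects sharing one frame
#'   interval.
#' @param stop_speed_threshold Passed to [compute_features()].
#' @param n Optional number of rows to subsample (without replacement).
#' @param seed Optional integer seed for the subsample.
#' @return Data frame with columns `subject_id`, `phase`, `segment`, then
#'   the seven parameters; no missing values.
#' @export
build_feature_matrix <- function(segments, stop_speed_threshold = 1.0,
                                 n = NULL, seed = NULL) {
  if (length(segments) == 0L) stop("no segments supplied")
  dts <- vapply(segments, `[[`, numeric(1), "frame_interval")
  if (diff(range(dts)) > 1e-12)
    stop("all segments must share one frame interval")
  feats <- t(vapply(segments, compute_features, numeric(7),
                    stop_speed_threshold = stop_speed_threshold))
  meta <- data.frame(
    subject_id = vapply(segments, function(s) as.character(s$subject_id), character(1)),
    phase = vapply(segments, function(s) as.character(s$phase), character(1)),
    segment = vapply(segments, function(s) as.integer(s$index), integer(1))
  )
  out <- cbind(meta, as.data.frame(feats))
  if (!is.null(n)) {
    if (n > nrow(out)) stop("cannot subsample more rows than available")
    if (!is.null(seed)) set.seed(seed)
    out <- out[sample.int(nrow(out), n), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Write / read a feature matrix CSV
#'
#' Standard interchange format with header
#' `subject_id,phase,segment,speed,acceleration,locomotory_rate,stop_number,stop_time,turning_rate,meander`.
#'
#' @param features Data frame as returned by [build_feature_matrix()].
#' @param path File path.
#' @return `write_features` returns `path` invisibly; `read_features`
#'   returns the data frame.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
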