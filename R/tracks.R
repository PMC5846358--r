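#' Observation arena
#'
#' Rectangular 2-D arena in which a single organism is tracked. Coordinates
#' are continuous millimetres with the origin at the lower-left corner and
#' y increasing upward. The default 60 mm x 50 mm matches a typical confined
#' observation cage used for *Daphnia magna* biomonitoring.
#'
#' @param width Arena width in mm (x extent). Must be positive.
#' @param height Arena height in mm (y extent). Must be positive.
#' @return An object of class `"arena"`.
#' @examples
#' arena()          # 60 x 50 mm default cage
#' arena(100, 100)  # square arena
#' @export
arena <- function(width = 60, height = 50) {
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) || width <= 0)
    stop("arena width must be a single positive number")
  if (!is.numeric(height) || length(height) != 1L || !is.finite(height) || height <= 0)
    stop("arena height must be a single positive number")
  structure(list(width = as.numeric(width), height = as.numeric(height)),
            class = "arena")
}

#' @export
print.arena <- function(x, ...) {
  cat(sprintf("<arena %g mm x %g mm>\n", x$width, x$height))
  invisible(x)
}

#' Construct a movement track
#'
#' A track is the timestamped 2-D trajectory of one organism recorded at a
#' fixed frame interval (0.25 s by default, i.e. 4 frames/s). Timestamps must
#' be strictly increasing and uniformly spaced; gaps (tracking dropout) are a
#' validation error, not imputed.
#'
#' @param t Numeric vector of timestamps in seconds.
#' @param x,y Numeric coordinate vectors in mm, same length as `t`; must lie
#'   inside the arena.
#' @param subject_id Identifier of the recorded individual.
#' @param phase Observation phase, `"before"` or `"after"` treatment.
#' @param frame_interval Time between frames in seconds (default 0.25).
#' @param arena An [arena()] object.
#' @return An object of class `"daph_track"` with elements `points` (a
#'   data frame with columns `t`, `x`, `y`), `subject_id`, `phase`,
#'   `frame_interval` and `arena`.
#' @export
track <- function(t, x, y, subject_id = "subject1",
                  phase = c("before", "after"),
                  frame_interval = 0.25, arena = daphtrack::arena()) {
  phase <- match.arg(phase)
  tr <- structure(list(
    points = data.frame(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y)),
    subject_id = as.character(subject_id),
    phase = phase,
    frame_interval = as.numeric(frame_interval),
    arena = arena
  ), class = "daph_track")
  validate_track(tr)
  tr
}

#' Validate track invariants
#'
#' Checks that a track has at least two frames, strictly increasing and
#' uniformly spaced timestamps (within 1e-9 s of the frame interval), and
#' coordinates inside the arena.
#'
#' @param tr A `"daph_track"` object.
#' @return The track, invisibly; an error is signalled on the first violated
#'   invariant.
#' @export
validate_track <- function(tr) {
  stopifnot(inherits(tr, "daph_track"))
  p <- tr$points
  if (nrow(p) < 2L) stop("a track needs at least 2 points")
  if (anyNA(p)) stop("track contains missing values")
  dt <- diff(p$t)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  if (any(abs(dt - tr$frame_interval) > 1e-9))
    stop(sprintf("non-uniform time step: expected %g s between frames", tr$frame_interval))
  a <- tr$arena
  if (any(p$x < 0) || any(p$x > a$width))
    stop(sprintf("x coordinate outside arena [0, %g]", a$width))
  if (any(p$y < 0) || any(p$y > a$height))
    stop(sprintf("y coordinate outside arena [0, %g]", a$height))
  invisible(tr)
}

#' @export
print.daph_track <- function(x, ...) {
  dur <- x$points$t[nrow(x$points)] - x$points$t[1L]
  cat(sprintf("<track %s/%s: %d frames, %.2f s, %g s/frame, arena %g x %g mm>\n",
              x$subject_id, x$phase, nrow(x$points), dur, x$frame_interval,
              x$arena$width, x$arena$height))
  invisible(x)
}

#' Read a track from a CSV coordinate file
#'
#' Expects a UTF-8 CSV with header `frame,t_s,x_mm,y_mm` and `.` as the
#' decimal separator (one organism per file). Rows are sorted by time before
#' validation.
#'
#' @param path Path to the file.
#' @param subject_id,phase,frame_interval,arena Track metadata; see [track()].
#' @return A validated `"daph_track"`.
#' @export
read_track <- function(path, subject_id = "subject1",
                       phase = c("before", "after"),
                       frame_interval = 0.25, arena = daphtrack::arena()) {
  phase <- match.arg(phase)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("frame", "t_s", "x_mm", "y_mm")
  if (!all(need %in% names(raw)))
    stop("track file must have columns frame,t_s,x_mm,y_mm")
  num <- lapply(raw[need], function(col) suppressWarnings(as.numeric(col)))
  bad <- which(Reduce(`|`, lapply(num, is.na)))
  if (length(bad))
    stop(sprintf("malformed row at line %d of %s", bad[1L] + 1L, path))
  ord <- order(num$t_s)
  track(t = num$t_s[ord], x = num$x_mm[ord], y = num$y_mm[ord],
        subject_id = subject_id, phase = phase,
        frame_interval = frame_interval, arena = arena)
}

#' Write a track to a CSV coordinate file
#'
#' Writes the standard `frame,t_s,x_mm,y_mm` format with 15 significant
#' digits, so a read/write round trip reproduces coordinates to well below
#' 1e-6 mm.
#'
#' @param tr A validated `"daph_track"`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_track <- function(tr, path) {
  validate_track(tr)
  p <- tr$points
  df <- data.frame(frame = seq_len(nrow(p)) - 1L,
                   t_s = format(p$t, digits = 15, scientific = FALSE, trim = TRUE),
                   x_mm = format(p$x, digits = 15, scientific = FALSE, trim = TRUE),
                   y_mm = format(p$y, digits = 15, scientific = FALSE, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Total duration of a track in seconds
#' @param tr A `"daph_track"`.
#' @return Elapsed time between first and last frame, in seconds.
#' @export
track_duration <- function(tr) {
  p <- tr$points
  p$t[nrow(p)] - p$t[1L]
}

#' Cut a track into fixed-duration analysis windows
#'
#' Windows are consecutive and cover the track from its first frame; a
#' trailing partial window is discarded. A window of `window_s` seconds at
#' frame interval dt spans `window_s/dt` inter-frame intervals and therefore
#' `window_s/dt + 1` frames: adjacent windows share their boundary frame, and
#' distances are attributed per interval so nothing is double-counted.
#'
#' @param tr A `"daph_track"`.
#' @param window_s Window duration in seconds; must be a positive multiple of
#'   the frame interval and at least two frame intervals long. 5 s is used
#'   for movement-pattern segments and 600 s (10 min) for fractal analysis.
#' @return A list of `"track_segment"` objects. Each has elements `points`
#'   (data frame `t`, `x`, `y`), `start_index`/`end_index` (half-open frame
#'   range into the parent track, 1-based), `index` (window number),
#'   `frame_interval`, `subject_id`, `phase` and `arena`.
#' @examples
#' tr <- generate_session(composition = c(P1 = 1), duration_s = 20, seed = 1)
#' length(segment_track(tr, window_s = 5))  # 4 windows
#' @export
segment_track <- function(tr, window_s = 5) {
  validate_track(tr)
  dt <- tr$frame_interval
  if (window_s < 2 * dt)
    stop("window_s must span at least two frame intervals")
  ipw <- window_s / dt
  if (abs(ipw - round(ipw)) > 1e-9)
    stop("window_s must be a multiple of the frame interval")
  ipw <- as.integer(round(ipw))
  n_int <- nrow(tr$points) - 1L
  n_win <- n_int %/% ipw
  if (n_win < 1L) stop("track shorter than one window")
  lapply(seq_len(n_win), function(k) {
    i0 <- (k - 1L) * ipw + 1L            # first frame of window k
    i1 <- i0 + ipw                       # boundary frame, shared with k+1
    structure(list(
      points = tr$points[i0:i1, , drop = FALSE],
      start_index = i0, end_index = i1 + 1L,
      index = k,
      frame_interval = dt,
      subject_id = tr$subject_id,
      phase = tr$phase,
      arena = tr$arena
    ), class = "track_segment")
  })
}

#' @export
print.track_segment <- function(x, ...) {
  cat(sprintf("<segment %d of %s/%s: %d frames, %.2f s>\n",
              x$index, x$subject_id, x$phase, nrow(x$points),
              (nrow(x$points) - 1L) * x$frame_interval))
  invisible(x)
}

# Accept either a track or a segment and return its point data frame.
track_points <- function(obj) {
  if (inherits(obj, "daph_track") || inherits(obj, "track_segment"))
    return(obj$points)
  stop("expected a track or a track segment")
}

#' Plot a track
#'
#' Simple base-graphics path plot of a trajectory inside its arena.
#'
#' @param x A `"daph_track"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.daph_track <- function(x, ...) {
  p <- x$points
  graphics::plot(p$x, p$y, type = "l", asp = 1,
                 xlim = c(0, x$arena$width), ylim = c(0, x$arena$height),
                 xlab = "x (mm)", ylab = "y (mm)",
                 main = sprintf("%s (%s)", x$subject_id, x$phase), ...)
  graphics::rect(0, 0, x$arena$width, x$arena$height, border = "grey40")
  invisible(x)
}
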