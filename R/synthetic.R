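#' Kinematic parameters of a movement archetype
#'
#' Returns the correlated-random-walk parameters that produce one of the six
#' canonical 5-s movement shapes: straight fast **line**; smooth curving
#' **loop**; erratic **cross** (straight bursts with abrupt speed changes and
#' random sharp turns); **shaking** (alternating left/right turns over a
#' small area); **swirl** (slow tight circling with a fixed rotation sense);
#' and **stay** (near-motionless drift). Speeds are in mm/s, turn rates in
#' rad/s; `stop_fraction` is the fraction of steps forced into a stop bout.
#' Defaults are chosen so the six classes are well separated in the
#' seven-parameter feature space and phase-level mean speed and turning rate
#' come out in the few-mm/s and few-rad/s range typical of *D. magna*.
#'
#' @param pattern One of `"line"`, `"loop"`, `"cross"`, `"shaking"`,
#'   `"swirl"`, `"stay"`, or a pattern code `"P1"`..`"P6"`.
#' @param ... Named overrides of individual fields.
#' @return Object of class `"archetype_params"`: list with fields `pattern`,
#'   `speed_mean`, `speed_sd`, `turn_mean`, `turn_sd`, `turn_sign_mode`
#'   (`"fixed"`, `"alternating"` or `"none"`) and `stop_fraction`.
#' @export
archetype_params <- function(pattern, ...) {
  codes <- pattern_archetypes()
  if (pattern %in% names(codes)) pattern <- codes[[pattern]]
  defaults <- list(
    line    = list(speed_mean = 8.2, speed_sd = 0.6, turn_mean = 0.0, turn_sd = 0.1,
                   turn_sign_mode = "none", stop_fraction = 0.00),
    loop    = list(speed_mean = 5.8, speed_sd = 0.6, turn_mean = 3.0, turn_sd = 0.3,
                   turn_sign_mode = "fixed", stop_fraction = 0.00),
    cross   = list(speed_mean = 4.6, speed_sd = 2.2, turn_mean = 0.0, turn_sd = 3.5,
                   turn_sign_mode = "none", stop_fraction = 0.00),
    shaking = list(speed_mean = 2.6, speed_sd = 0.5, turn_mean = 8.0, turn_sd = 1.0,
                   turn_sign_mode = "alternating", stop_fraction = 0.05),
    swirl   = list(speed_mean = 1.6, speed_sd = 0.3, turn_mean = 3.0, turn_sd = 0.3,
                   turn_sign_mode = "fixed", stop_fraction = 0.10),
    stay    = list(speed_mean = 0.12, speed_sd = 0.06, turn_mean = 0.0, turn_sd = 0.3,
                   turn_sign_mode = "none", stop_fraction = 0.85)
  )
  if (!pattern %in% names(defaults))
    stop("unknown archetype: ", pattern)
  p <- utils::modifyList(defaults[[pattern]], list(...))
  p$pattern <- pattern
  validate_archetype(structure(p, class = "archetype_params"))
}

validate_archetype <- function(p) {
  if (p$speed_mean < 0 || p$speed_sd < 0) stop("speeds must be non-negative")
  if (p$turn_sd < 0) stop("turn_sd must be non-negative")
  if (p$stop_fraction < 0 || p$stop_fraction > 1)
    stop("stop_fraction must lie in [0, 1]")
  if (!p$turn_sign_mode %in% c("fixed", "alternating", "none"))
    stop("turn_sign_mode must be fixed, alternating or none")
  p
}

# fold an unbounded coordinate into [0, w] by specular reflection
# (triangle wave; preserves travelled path length exactly)
reflect_fold <- function(x, w) {
  g <- x %% (2 * w)
  w - abs(g - w)
}

# one correlated-random-walk block in *unfolded* coordinates.
# Returns per-step displacements and the final heading; caller accumulates.
crw_steps <- function(params, n_steps, heading0, dt) {
  sp <- pmax(stats::rnorm(n_steps, params$speed_mean, params$speed_sd), 0)
  dtheta <- switch(params$turn_sign_mode,
    none = stats::rnorm(n_steps, params$turn_mean, params$turn_sd) * dt,
    fixed = {
      sgn <- sample(c(-1, 1), 1L)
      sgn * abs(stats::rnorm(n_steps, params$turn_mean, params$turn_sd)) * dt
    },
    alternating = {
      sgn0 <- sample(c(-1, 1), 1L)
      sgn <- sgn0 * rep_len(c(1, -1), n_steps)
      sgn * abs(stats::rnorm(n_steps, params$turn_mean, params$turn_sd)) * dt
    })
  k <- round(params$stop_fraction * n_steps)
  if (k > 0) {
    start <- if (k >= n_steps) 1L else sample.int(n_steps - k + 1L, 1L)
    idx <- start:(start + k - 1L)
    sp[idx] <- abs(stats::rnorm(k, 0.08, 0.04))  # well below the 1 mm/s stop threshold
  }
  headings <- heading0 + cumsum(dtheta)
  list(dx = sp * dt * cos(headings), dy = sp * dt * sin(headings),
       heading_end = headings[n_steps])
}

#' Generate one synthetic archetype segment
#'
#' Simulates a 5-s (by default) correlated random walk with the kinematics
#' of one movement archetype, reflected specularly at the arena walls.
#' Deterministic for a fixed seed.
#'
#' @param params An [archetype_params()] object.
#' @param duration_s Segment duration in seconds (default 5).
#' @param frame_interval Frame interval in seconds (default 0.25).
#' @param start_pose Optional list with `x`, `y` (mm) and `heading` (rad);
#'   random within the arena when `NULL`.
#' @param seed Optional integer seed.
#' @param arena An [arena()].
#' @param subject_id,phase Metadata attached to the segment.
#' @return A `"track_segment"` whose `points` satisfy the track invariants;
#'   the generating archetype is attached as attribute `"pattern"`.
#' @examples
#' seg <- generate_segment(archetype_params("swirl"), seed = 42)
#' compute_features(seg)["turning_rate"]   # close to 3 rad/s
#' @export
generate_segment <- function(params, duration_s = 5, frame_interval = 0.25,
                             start_pose = NULL, seed = NULL,
                             arena = daphtrack::arena(),
                             subject_id = "synthetic", phase = "before") {
  stopifnot(inherits(params, "archetype_params"))
  n_steps <- duration_s / frame_interval
  if (abs(n_steps - round(n_steps)) > 1e-9 || n_steps < 1)
    stop("duration_s must cover at least one whole frame interval")
  n_steps <- as.integer(round(n_steps))
  if (n_steps + 1L < 2L) stop("segment needs at least 2 frames")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(start_pose))
    start_pose <- list(x = stats::runif(1, 0.25, arena$width - 0.25),
                       y = stats::runif(1, 0.25, arena$height - 0.25),
                       heading = stats::runif(1, -pi, pi))
  st <- crw_steps(params, n_steps, start_pose$heading, frame_interval)
  ux <- start_pose$x + cumsum(c(0, st$dx))
  uy <- start_pose$y + cumsum(c(0, st$dy))
  structure(list(
    points = data.frame(t = seq(0, by = frame_interval, length.out = n_steps + 1L),
                        x = reflect_fold(ux, arena$width),
                        y = reflect_fold(uy, arena$height)),
    start_index = 1L, end_index = n_steps + 2L, index = 1L,
    frame_interval = frame_interval,
    subject_id = subject_id, phase = phase, arena = arena
  ), class = "track_segment", pattern = params$pattern)
}

#' Labelled sets of archetype segments
#'
#' Convenience generator of `n_per_class` independent 5-s segments for each
#' of the six archetypes, with ground-truth labels — the raw material for
#' training and validating the movement-pattern classifier.
#'
#' @param n_per_class Segments per archetype.
#' @param seed Integer seed.
#' @param ... Passed to [generate_segment()].
#' @return List with `segments` (list of `"track_segment"`) and `labels`
#'   (character vector of pattern codes P1..P6).
#' @export
generate_archetype_set <- function(n_per_class, seed = 1, ...) {
  set.seed(seed)
  codes <- names(pattern_archetypes())
  segments <- list()
  labels <- character(0)
  for (code in codes) {
    par <- archetype_params(code)
    for (i in seq_len(n_per_class)) {
      seg <- generate_segment(par, ...)
      seg$index <- length(segments) + 1L
      segments[[length(segments) + 1L]] <- seg
      labels <- c(labels, code)
    }
  }
  list(segments = segments, labels = labels)
}

#' Generate a full observation session
#'
#' Chains seeded 5-s archetype blocks — drawn from a pattern composition by
#' multinomial sampling — into one continuous track with pose continuity,
#' reflected at the arena walls. Blocks are aligned to the segmentation
#' grid, so ground-truth labels map one-to-one onto the 5-s analysis
#' segments of [segment_track()].
#'
#' @param composition Named probability vector over patterns (names P1..P6
#'   or archetype names); must sum to 1 (within 1e-6) and is renormalized.
#' @param duration_s Session duration in seconds; a multiple of `block_s`.
#' @param arena An [arena()].
#' @param seed Optional integer seed.
#' @param subject_id,phase Track metadata.
#' @param frame_interval Frame interval in seconds (default 0.25).
#' @param block_s Archetype block duration (default 5 s).
#' @return A `"daph_track"` with attribute `"truth"`, a data frame
#'   `segment,pattern` of ground-truth block labels.
#' @export
generate_session <- function(composition, duration_s = 3600,
                             arena = daphtrack::arena(), seed = NULL,
                             subject_id = "synthetic", phase = "before",
                             frame_interval = 0.25, block_s = 5) {
  codes <- pattern_archetypes()
  nm <- names(composition)
  nm[nm %in% codes] <- names(codes)[match(nm[nm %in% codes], codes)]
  names(composition) <- nm
  if (!all(nm %in% names(codes))) stop("composition names must be patterns P1..P6")
  if (any(composition < 0)) stop("composition probabilities must be non-negative")
  if (abs(sum(composition) - 1) > 1e-6) stop("composition must sum to 1")
  full <- stats::setNames(numeric(length(codes)), names(codes))
  full[nm] <- composition
  composition <- full / sum(full)
  n_blocks <- duration_s / block_s
  if (abs(n_blocks - round(n_blocks)) > 1e-9 || n_blocks < 1)
    stop("duration_s must be a positive multiple of block_s")
  n_blocks <- as.integer(round(n_blocks))
  steps_per_block <- as.integer(round(block_s / frame_interval))
  if (!is.null(seed)) set.seed(seed)
  patterns <- sample(names(codes), n_blocks, replace = TRUE, prob = composition)
  par_list <- lapply(stats::setNames(nm = names(codes)), archetype_params)

  heading <- stats::runif(1, -pi, pi)
  dx <- dy <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    st <- crw_steps(par_list[[patterns[b]]], steps_per_block, heading, frame_interval)
    dx[[b]] <- st$dx; dy[[b]] <- st$dy
    heading <- st$heading_end
  }
  ux <- stats::runif(1, 0.25, arena$width - 0.25) + cumsum(c(0, unlist(dx)))
  uy <- stats::runif(1, 0.25, arena$height - 0.25) + cumsum(c(0, unlist(dy)))
  n_frames <- n_blocks * steps_per_block + 1L
  tr <- track(t = seq(0, by = frame_interval, length.out = n_frames),
              x = reflect_fold(ux, arena$width),
              y = reflect_fold(uy, arena$height),
              subject_id = subject_id, phase = phase,
              frame_interval = frame_interval, arena = arena)
  attr(tr, "truth") <- data.frame(segment = seq_len(n_blocks), pattern = patterns)
  tr
}

#' Default before/after pattern compositions
#'
#' Per-phase probabilities of the six movement patterns used by
#' [default_study()]. The dominant values — P1 (line) 25.4% falling to
#' 17.1%, P6 (stay) 14.7% rising to 22.5% — are the published composition
#' shift for a 10 mg/L toluene exposure; the P2–P5 values are package
#' defaults chosen to complete each composition to 1 while preserving the
#' reported directions (active patterns shrink, zig-zag/stop patterns grow).
#'
#' @return List with numeric vectors `before` and `after`, each summing
#'   to 1.
#' @export
study_compositions <- function() {
  list(
    before = c(P1 = 0.254, P2 = 0.230, P3 = 0.180, P4 = 0.100, P5 = 0.089, P6 = 0.147),
    after  = c(P1 = 0.171, P2 = 0.150, P3 = 0.120, P4 = 0.150, P5 = 0.184, P6 = 0.225)
  )
}

#' Generate a complete before/after study
#'
#' Ten subjects (by default), each with one before-treatment and one
#' after-treatment session drawn from the phase compositions of
#' [study_compositions()], with small per-subject jitter on the
#' probabilities to emulate individual variation. Fully deterministic for a
#' fixed seed.
#'
#' @param seed Integer seed.
#' @param duration_s Session duration in seconds (default 3600, i.e. 1-h
#'   desk-scale sessions; the original design is 24-h, `duration_s = 86400`).
#' @param subjects Number of subjects (default 10).
#' @param jitter_sd Standard deviation of the additive per-subject
#'   composition jitter (default 0.008).
#' @param arena An [arena()].
#' @return List with elements `before` and `after`, each a list of
#'   `"daph_track"` objects (with `"truth"` attributes) named by subject.
#' @export
default_study <- function(seed = 1, duration_s = 3600, subjects = 10,
                          jitter_sd = 0.008, arena = daphtrack::arena()) {
  comps <- study_compositions()
  set.seed(seed)
  out <- list(before = vector("list", subjects), after = vector("list", subjects))
  for (s in seq_len(subjects)) {
    sid <- sprintf("subject%02d", s)
    for (ph in c("before", "after")) {
      p <- jitter_composition(comps[[ph]], jitter_sd)
      out[[ph]][[s]] <- generate_session(p, duration_s = duration_s,
                                         arena = arena, seed = NULL,
                                         subject_id = sid, phase = ph)
    }
  }
  names(out$before) <- names(out$after) <- sprintf("subject%02d", seq_len(subjects))
  out
}

#' Jitter a pattern composition
#'
#' Adds independent Gaussian noise to each probability, floors at 0.001 and
#' renormalizes — the model of between-subject variation in pattern usage.
#'
#' @param composition Named probability vector.
#' @param sd Jitter standard deviation.
#' @return Jittered composition summing to 1.
#' @export
jitter_composition <- function(composition, sd = 0.008) {
  p <- pmax(composition + stats::rnorm(length(composition), 0, sd), 0.001)
  p / sum(p)
}

#' Ground-truth labels of a synthetic track
#'
#' @param tr A `"daph_track"` from [generate_session()].
#' @return Data frame `segment,pattern`, or an error for a track without
#'   truth labels.
#' @export
truth_labels <- function(tr) {
  tl <- attr(tr, "truth")
  if (is.null(tl)) stop("track carries no ground-truth labels")
  tl
}
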