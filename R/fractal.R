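#' Binary track image
#'
#' Wraps an M x M logical occupancy grid (M a power of 2) together with its
#' physical scale. Normally produced by [rasterize()]; the constructor is
#' exported so that analytically defined images (e.g. known fractals) can be
#' fed to [box_counts()] directly.
#'
#' @param grid Logical M x M matrix, `TRUE` where the track passes.
#' @param mm_per_pixel Physical size of one pixel (mm).
#' @return An object of class `"track_image"` with elements `grid`, `M`,
#'   `mm_per_pixel`.
#' @export
binary_track_image <- function(grid, mm_per_pixel = 1) {
  if (!is.matrix(grid) || !is.logical(grid)) stop("grid must be a logical matrix")
  M <- nrow(grid)
  if (ncol(grid) != M) stop("grid must be square")
  if (!is_power_of_2(M)) stop("image side must be a power of 2")
  structure(list(grid = grid, M = M, mm_per_pixel = mm_per_pixel),
            class = "track_image")
}

is_power_of_2 <- function(M) {
  M >= 1 && abs(log2(M) - round(log2(M))) < 1e-12
}

#' @export
print.track_image <- function(x, ...) {
  cat(sprintf("<track image %d x %d, %d occupied px, %.4g mm/px>\n",
              x$M, x$M, sum(x$grid), x$mm_per_pixel))
  invisible(x)
}

# round-half-up, deterministic (base round() uses banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

#' Rasterize a track onto a binary grid
#'
#' Maps a trajectory onto an M x M occupancy grid using a single isotropic
#' scale `s = (M - 1) / max(arena width, arena height)` anchored at the arena
#' origin, so the non-square arena is never stretched (which would distort
#' angles and the estimated dimension). With `raster_mode = "lines"`
#' (default) every pixel along the straight line between consecutive samples
#' is filled, producing an 8-connected curve as a continuous swimming path
#' would; `"points"` marks only the sampled positions.
#'
#' @param obj A `"daph_track"` or `"track_segment"`.
#' @param M Image side in pixels; a power of 2, at least 8 (default 256).
#' @param raster_mode `"lines"` or `"points"`.
#' @return A [binary_track_image()].
#' @export
rasterize <- function(obj, M = 256, raster_mode = c("lines", "points")) {
  raster_mode <- match.arg(raster_mode)
  if (!is_power_of_2(M) || M < 8) stop("M must be a power of 2, at least 8")
  p <- track_points(obj)
  a <- obj$arena
  if (is.null(a)) stop("object carries no arena")
  s <- (M - 1) / max(a$width, a$height)
  ix <- pmin(pmax(round_half_up(p$x * s) + 1L, 1L), M)
  iy <- pmin(pmax(round_half_up(p$y * s) + 1L, 1L), M)
  grid <- matrix(FALSE, M, M)
  if (raster_mode == "points" || nrow(p) == 1L) {
    grid[cbind(ix, iy)] <- TRUE
  } else {
    i0 <- ix[-length(ix)]; i1 <- ix[-1L]
    j0 <- iy[-length(iy)]; j1 <- iy[-1L]
    nsteps <- pmax(abs(i1 - i0), abs(j1 - j0))  # 0 for coincident pixels
    npts <- nsteps + 1L
    seg <- rep.int(seq_along(nsteps), npts)
    k <- sequence(npts) - 1L
    frac <- ifelse(nsteps[seg] == 0L, 0, k / pmax(nsteps[seg], 1L))
    ii <- i0[seg] + round_half_up(frac * (i1[seg] - i0[seg]))
    jj <- j0[seg] + round_half_up(frac * (j1[seg] - j0[seg]))
    grid[cbind(ii, jj)] <- TRUE
  }
  binary_track_image(grid, mm_per_pixel = 1 / s)
}

#' Count occupied boxes at a set of box sizes
#'
#' For each box size delta (in pixels, dividing M) the grid is partitioned
#' into (M/delta)^2 axis-aligned boxes anchored at the origin, and the number
#' N(delta) of boxes containing at least one occupied pixel is counted.
#'
#' @param image A [binary_track_image()] or a logical square matrix.
#' @param deltas Integer box sizes; default the dyadic schedule
#'   2, 4, ..., M/2.
#' @return A `"box_count_series"` data frame with columns `delta` and
#'   `count`, and attribute `M`.
#' @export
box_counts <- function(image, deltas = NULL) {
  if (is.matrix(image)) image <- binary_track_image(image)
  stopifnot(inherits(image, "track_image"))
  M <- image$M
  if (is.null(deltas)) deltas <- 2^seq(1L, as.integer(log2(M)) - 1L)
  deltas <- as.integer(deltas)
  if (any(deltas < 1L) || any(M %% deltas != 0L))
    stop("every delta must be a positive divisor of M")
  if (is.unsorted(deltas, strictly = TRUE)) deltas <- sort(unique(deltas))
  occ <- which(image$grid, arr.ind = TRUE) - 1L  # 0-based pixel coords
  if (nrow(occ) == 0L) stop("image has no occupied pixel")
  counts <- vapply(deltas, function(d) {
    nb <- M %/% d
    ids <- (occ[, 1L] %/% d) * nb + (occ[, 2L] %/% d)
    length(unique(ids))
  }, integer(1))
  box_count_series(deltas, counts, M)
}

#' Assemble a box-count series
#'
#' @param delta Strictly increasing box sizes in pixels.
#' @param count Occupied-box counts N(delta), non-increasing in delta.
#' @param M Image side in pixels.
#' @return A `"box_count_series"` data frame.
#' @export
box_count_series <- function(delta, count, M) {
  if (is.unsorted(delta, strictly = TRUE)) stop("deltas must be strictly increasing")
  if (any(diff(count) > 0)) stop("N(delta) must be non-increasing in delta")
  if (any(count < 1) || any(count > (M / delta)^2))
    stop("counts must lie in [1, (M/delta)^2]")
  structure(data.frame(delta = delta, count = count),
            M = M, class = c("box_count_series", "data.frame"))
}

#' Fit the box-counting dimension from a count series
#'
#' Ordinary least-squares slope of log N(delta) against log(1/delta).
#' Degenerate scales are excluded before fitting: points with N = 1 (the
#' whole object in one box) and fully saturated points with
#' N = (M/delta)^2 carry no scaling information. If the filter leaves fewer
#' than 3 points because *every* scale is fully saturated (a space-filling
#' image), the unfiltered fit is used instead, which returns exactly 2;
#' otherwise fewer than 3 usable points is an error.
#'
#' @param series A `"box_count_series"`.
#' @return An object of class `"fractal_result"`: list with `D` (slope),
#'   `fit_points` (data frame `log_inv_delta`, `log_count`), `r_squared`
#'   and `n_fit_points`.
#' @export
fit_dimension <- function(series) {
  stopifnot(inherits(series, "box_count_series"))
  M <- attr(series, "M")
  full <- (M / series$delta)^2
  usable <- series$count > 1 & series$count < full
  if (sum(usable) < 3L) {
    if (all(series$count == full) && nrow(series) >= 3L) {
      usable <- rep(TRUE, nrow(series))   # space-filling image
    } else {
      stop("fewer than 3 scales remain after the saturation filter")
    }
  }
  x <- log(1 / series$delta[usable])
  y <- log(series$count[usable])
  fit <- stats::lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  structure(list(
    D = unname(stats::coef(fit)[2L]),
    fit_points = data.frame(log_inv_delta = x, log_count = y),
    r_squared = r2,
    n_fit_points = sum(usable)
  ), class = "fractal_result")
}

#' @export
print.fractal_result <- function(x, ...) {
  cat(sprintf("<fractal dimension D = %.4f (r^2 = %.4f, %d scales)>\n",
              x$D, x$r_squared, x$n_fit_points))
  invisible(x)
}

#' Windowed fractal dimension of a long track
#'
#' Segments a track into fixed windows (10 min by default), rasterizes each
#' window and fits its box-counting dimension. For a planar track the result
#' ranges from about 1 (a straight path) to 2 (a path visiting the whole
#' arena evenly), so a drop in D signals reduced movement complexity.
#'
#' @param tr A `"daph_track"` at least one window long.
#' @param window_s Window duration in seconds (default 600).
#' @param M Raster size (default 256; the finest box of 2 px then spans
#'   about 0.47 mm in the default arena, below a typical per-frame
#'   displacement).
#' @param deltas Box-size schedule; default dyadic 2 ... M/2.
#' @param raster_mode Passed to [rasterize()].
#' @return List of `"fractal_result"`, one per window.
#' @export
track_fractal_dimension <- function(tr, window_s = 600, M = 256,
                                    deltas = NULL,
                                    raster_mode = c("lines", "points")) {
  raster_mode <- match.arg(raster_mode)
  segs <- segment_track(tr, window_s = window_s)
  lapply(segs, function(s)
    fit_dimension(box_counts(rasterize(s, M = M, raster_mode = raster_mode),
                             deltas = deltas)))
}

#' Tabulate windowed fractal results
#'
#' @param tr A `"daph_track"`.
#' @param ... Passed to [track_fractal_dimension()].
#' @return Data frame `subject_id,phase,window_index,D,r_squared,n_fit_points`.
#' @export
fractal_report <- function(tr, ...) {
  res <- track_fractal_dimension(tr, ...)
  data.frame(subject_id = tr$subject_id, phase = tr$phase,
             window_index = seq_along(res),
             D = vapply(res, `[[`, numeric(1), "D"),
             r_squared = vapply(res, `[[`, numeric(1), "r_squared"),
             n_fit_points = vapply(res, function(r) as.integer(r$n_fit_points), integer(1)))
}
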