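# Shared fixtures and independent oracles, built in code at test time.

# hand-built segment from raw coordinates (big arena so bounds never bite)
make_segment <- function(x, y, dt = 0.25, arena_obj = arena(1000, 1000)) {
  structure(list(
    points = data.frame(t = (seq_along(x) - 1) * dt, x = x, y = y),
    start_index = 1L, end_index = length(x) + 1L, index = 1L,
    frame_interval = dt, subject_id = "test", phase = "before",
    arena = arena_obj
  ), class = "track_segment")
}

# brute-force box counter: O(M^2) double loop over boxes
naive_box_count <- function(grid, delta) {
  M <- nrow(grid)
  n <- 0L
  for (bi in seq_len(M / delta)) {
    for (bj in seq_len(M / delta)) {
      rows <- ((bi - 1) * delta + 1):(bi * delta)
      cols <- ((bj - 1) * delta + 1):(bj * delta)
      if (any(grid[rows, cols])) n <- n + 1L
    }
  }
  n
}

# Sierpinski gasket occupancy on a 2^k grid via the bitwise-AND rule
sierpinski_grid <- function(M) {
  idx <- expand.grid(i = 0:(M - 1), j = 0:(M - 1))
  matrix(bitwAnd(idx$i, idx$j) == 0L, M, M)
}

# space-filling boustrophedon track in a square arena: every raster row of
# the M x M grid is swept edge to edge
boustrophedon_track <- function(M = 256, side = 60) {
  sc <- (M - 1) / side
  ys <- (0:(M - 1)) / sc
  px <- py <- numeric(0)
  for (j in seq_along(ys)) {
    px <- c(px, if (j %% 2 == 1) c(0, side) else c(side, 0))
    py <- c(py, ys[j], ys[j])
  }
  track(t = (seq_along(px) - 1) * 0.25, x = px, y = py,
        arena = arena(side, side))
}

# straight constant-speed diagonal track spanning the arena
diagonal_track <- function(n = 2401, arena_obj = arena()) {
  track(t = (seq_len(n) - 1) * 0.25,
        x = seq(0, arena_obj$width, length.out = n),
        y = seq(0, arena_obj$height, length.out = n),
        arena = arena_obj)
}
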