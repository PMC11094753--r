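# internal helpers shared across modules

# run `code` under a temporary RNG state when `seed` is given, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer or NULL.")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a reproducible per-stage seed (< 2^31) from a global seed
stage_seed <- function(seed, stage) {
  as.integer((abs(as.numeric(seed)) %% 1e6) * 1009 + 101 * stage + 7)
}

# accept a single geometry or a list of geometries
as_geometry_list <- function(geometries) {
  if (inherits(geometries, "plastid_geometry")) {
    return(list(geometries))
  }
  if (is.list(geometries) && length(geometries) > 0L &&
      all(vapply(geometries, inherits, logical(1), "plastid_geometry"))) {
    return(geometries)
  }
  abort("`geometries` must be a <plastid_geometry> or a non-empty list of them.")
}

# matrix of disc bodies: columns cx, cy, R
geometry_bodies <- function(geoms) {
  do.call(rbind, lapply(geoms, function(g) {
    c(cx = g$center[1], cy = g$center[2], R = g$body_radius)
  }))
}

# matrix of all stromule segments: columns x0, y0, x1, y1 (0 rows if none)
geometry_segments <- function(geoms) {
  segs <- lapply(geoms, function(g) as.matrix(g$segments))
  segs <- segs[vapply(segs, nrow, integer(1)) > 0L]
  if (length(segs) == 0L) {
    return(matrix(numeric(0), ncol = 4,
                  dimnames = list(NULL, c("x0", "y0", "x1", "y1"))))
  }
  do.call(rbind, segs)
}

# bounding box covering all bodies and segment vertices
geometry_bbox <- function(geoms) {
  bod <- geometry_bodies(geoms)
  xs <- c(bod[, "cx"] - bod[, "R"], bod[, "cx"] + bod[, "R"])
  ys <- c(bod[, "cy"] - bod[, "R"], bod[, "cy"] + bod[, "R"])
  seg <- geometry_segments(geoms)
  if (nrow(seg) > 0L) {
    xs <- c(xs, seg[, "x0"], seg[, "x1"])
    ys <- c(ys, seg[, "y0"], seg[, "y1"])
  }
  list(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}

# vectorized distance from points (px, py) to one segment
point_segment_distance <- function(px, py, x0, y0, x1, y1) {
  dx <- x1 - x0
  dy <- y1 - y0
  l2 <- dx * dx + dy * dy
  if (l2 == 0) {
    return(sqrt((px - x0)^2 + (py - y0)^2))
  }
  t <- ((px - x0) * dx + (py - y0) * dy) / l2
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2)
}

# TRUE for points inside or on any plastid body disc
in_plastid_body <- function(px, py, geometries) {
  geoms <- as_geometry_list(geometries)
  bod <- geometry_bodies(geoms)
  inside <- rep(FALSE, length(px))
  for (i in seq_len(nrow(bod))) {
    inside <- inside |
      ((px - bod[i, "cx"])^2 + (py - bod[i, "cy"])^2 <= bod[i, "R"]^2)
  }
  inside
}
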