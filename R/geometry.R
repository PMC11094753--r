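#' Construct a plastid body with a stromule arrangement
#'
#' Builds the geometric object all spatial computations consume: a disc-shaped
#' plastid body of radius `body_radius` (R, µm) plus zero-width stromule
#' polylines of total length `stromule_length` (l, µm) in one of four canonical
#' arrangements. The quasi-2D cortical cytoplasm of epidermal cells makes these
#' planar shapes a faithful projection of the real organelle.
#'
#' Arrangements at matched total length l:
#' * `"none"` — bare body, `stromule_length` must be 0.
#' * `"single"` — one radial segment of length l rooted at `extension_angle`.
#' * `"double"` — two segments of length l/2 rooted at diametrically opposite
#'   points of the body circle.
#' * `"branched"` — a stem of length l/3 extending radially, branching into two
#'   l/3 segments. With the default `branch_angle = 120` the three arms meeting
#'   at the junction are mutually separated by 120° (the observed optimum for
#'   stromule branch points). `branch_angle` is measured between each branch
#'   and the stem arm (the direction pointing back toward the body).
#'
#' @param config One of `"none"`, `"single"`, `"double"`, `"branched"`.
#' @param body_radius Body disc radius R in µm (default 2, the measured value).
#' @param stromule_length Total stromule length l in µm; defaults to 10 for
#'   stromule-bearing configurations and 0 for `"none"`.
#' @param extension_angle Orientation of the first stromule root, radians.
#' @param center Numeric length-2 body center (µm).
#' @param branch_angle Junction angle in degrees between the stem arm and each
#'   branch (`"branched"` only); 120 gives the equal three-way split.
#'
#' @return A `<plastid_geometry>`: list with `center`, `body_radius`, `config`,
#'   `stromule_length`, `extension_angle`, `branch_angle` and a `segments`
#'   tibble (`x0`, `y0`, `x1`, `y1`, one row per stromule segment).
#' @examples
#' plastid_geometry("branched", body_radius = 2, stromule_length = 10)
#' @export
plastid_geometry <- function(config = c("none", "single", "double", "branched"),
                             body_radius = 2,
                             stromule_length = NULL,
                             extension_angle = 0,
                             center = c(0, 0),
                             branch_angle = 120) {
  config <- match.arg(tolower(config[1]), c("none", "single", "double", "branched"))
  if (is.null(stromule_length)) {
    stromule_length <- if (config == "none") 0 else 10
  }
  if (!is.numeric(body_radius) || body_radius <= 0) {
    abort("`body_radius` must be a positive length (µm).")
  }
  if (!is.numeric(stromule_length) || stromule_length < 0) {
    abort("`stromule_length` must be non-negative (µm).")
  }
  if (config == "none" && stromule_length > 0) {
    abort("`config = \"none\"` requires `stromule_length = 0`.")
  }
  if (config != "none" && stromule_length == 0) {
    abort("Stromule-bearing configurations require `stromule_length > 0`.")
  }
  if (length(center) != 2L || !is.numeric(center)) {
    abort("`center` must be a numeric length-2 coordinate.")
  }
  R <- body_radius
  l <- stromule_length
  th <- extension_angle
  u <- c(cos(th), sin(th))
  seg <- function(p, q) c(x0 = p[1], y0 = p[2], x1 = q[1], y1 = q[2])
  segments <- switch(config,
    none = NULL,
    single = {
      root <- center + R * u
      rbind(seg(root, root + l * u))
    },
    double = {
      root1 <- center + R * u
      root2 <- center - R * u
      rbind(
        seg(root1, root1 + (l / 2) * u),
        seg(root2, root2 - (l / 2) * u)
      )
    },
    branched = {
      if (!is.numeric(branch_angle) || branch_angle <= 0 || branch_angle > 180) {
        abort("`branch_angle` must be in (0, 180] degrees.")
      }
      a <- branch_angle * pi / 180
      root <- center + R * u
      junction <- root + (l / 3) * u
      # branch directions: rotate the stem-arm direction (back toward the
      # body, angle th + pi) by +/- branch_angle; at 120 deg this places the
      # branches at th -/+ 60 deg and all three junction arms 120 deg apart
      b1 <- c(cos(th + pi - a), sin(th + pi - a))
      b2 <- c(cos(th + pi + a), sin(th + pi + a))
      rbind(
        seg(root, junction),
        seg(junction, junction + (l / 3) * b1),
        seg(junction, junction + (l / 3) * b2)
      )
    }
  )
  segments <- if (is.null(segments)) {
    tibble(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0), y1 = numeric(0))
  } else {
    as_tibble(as.data.frame(segments))
  }
  g <- structure(
    list(
      center = as.numeric(center),
      body_radius = R,
      config = config,
      stromule_length = l,
      extension_angle = extension_angle,
      branch_angle = if (config == "branched") branch_angle else NA_real_,
      segments = segments
    ),
    class = "plastid_geometry"
  )
  validate_plastid_geometry(g)
  g
}

# check the structural invariants of a plastid_geometry
validate_plastid_geometry <- function(g, tol = 1e-9) {
  seg <- as.matrix(g$segments)
  total <- if (nrow(seg) == 0L) 0 else {
    sum(sqrt((seg[, "x1"] - seg[, "x0"])^2 + (seg[, "y1"] - seg[, "y0"])^2))
  }
  if (abs(total - g$stromule_length) > tol) {
    abort("Stromule segment lengths do not sum to `stromule_length`.")
  }
  if (g$config %in% c("single", "double", "branched")) {
    roots <- switch(g$config,
      single = seg[1, c("x0", "y0"), drop = FALSE],
      double = seg[, c("x0", "y0"), drop = FALSE],
      branched = seg[1, c("x0", "y0"), drop = FALSE]
    )
    r <- sqrt((roots[, 1] - g$center[1])^2 + (roots[, 2] - g$center[2])^2)
    if (any(abs(r - g$body_radius) > tol)) {
      abort("Stromule root vertices must lie on the body circle.")
    }
  }
  if (g$config == "branched" && isTRUE(all.equal(g$branch_angle, 120))) {
    # the three arms leaving the junction must be pairwise 120 deg apart
    junction <- seg[1, c("x1", "y1")]
    arms <- rbind(
      seg[1, c("x0", "y0")] - junction,
      seg[2, c("x1", "y1")] - junction,
      seg[3, c("x1", "y1")] - junction
    )
    ang <- atan2(arms[, 2], arms[, 1])
    for (i in 1:2) for (j in (i + 1):3) {
      dth <- abs(ang[i] - ang[j]) %% (2 * pi)
      dth <- min(dth, 2 * pi - dth)
      if (abs(dth - 2 * pi / 3) > 1e-9) {
        abort("Branched arms must meet at pairwise 120° angles.")
      }
    }
  }
  invisible(g)
}

#' @export
print.plastid_geometry <- function(x, ...) {
  cat(sprintf(
    "<plastid_geometry> %s: R = %g µm, l = %g µm, center (%g, %g), %d segment(s)\n",
    toupper(x$config), x$body_radius, x$stromule_length,
    x$center[1], x$center[2], nrow(x$segments)
  ))
  invisible(x)
}

#' Distance from points to the nearest plastid element
#'
#' Euclidean distance (µm) from each query point to the nearest part of any
#' plastid in the scene: 0 inside or on a body disc, otherwise the minimum of
#' the distance to each body boundary and to every stromule segment. This is
#' the quantity the pixel-grid distance field stores, and its sublevel sets
#' define the interaction region.
#'
#' @param x,y Numeric vectors of point coordinates (µm), recycled to a common
#'   length.
#' @param geometries A `<plastid_geometry>` or non-empty list of them.
#' @return Numeric vector of non-negative distances (µm).
#' @examples
#' g <- plastid_geometry("none", body_radius = 2, stromule_length = 0)
#' scene_distance(c(0, 5), c(0, 0), g) # 0 inside, 3 at radial offset 5
#' @export
scene_distance <- function(x, y, geometries) {
  geoms <- as_geometry_list(geometries)
  n <- max(length(x), length(y))
  px <- rep_len(as.numeric(x), n)
  py <- rep_len(as.numeric(y), n)
  bod <- geometry_bodies(geoms)
  d <- rep(Inf, n)
  for (i in seq_len(nrow(bod))) {
    db <- pmax(sqrt((px - bod[i, "cx"])^2 + (py - bod[i, "cy"])^2) - bod[i, "R"], 0)
    d <- pmin(d, db)
  }
  seg <- geometry_segments(geoms)
  for (i in seq_len(nrow(seg))) {
    d <- pmin(d, point_segment_distance(
      px, py, seg[i, "x0"], seg[i, "y0"], seg[i, "x1"], seg[i, "y1"]
    ))
  }
  d
}

#' Does a ray encounter plastid material within reach D?
#'
#' Casts a ray of length `D` from each point at angle `theta` and reports
#' whether it intersects any plastid body disc or stromule segment. Tangent
#' contacts count as encounters (closed intersection test), and a point inside
#' a body reports `TRUE` for every angle. This is the primitive behind the
#' plastid-access raytracer.
#'
#' @inheritParams scene_distance
#' @param theta Ray angles in radians, recycled against `x`/`y`.
#' @param D Ray reach in µm (> 0).
#' @return Logical vector.
#' @examples
#' g <- plastid_geometry("none", body_radius = 2, stromule_length = 0)
#' ray_encounter(5, 0, pi, D = 5, geometries = g)  # aimed at the body: TRUE
#' ray_encounter(5, 0, 0, D = 5, geometries = g)   # aimed away: FALSE
#' @export
ray_encounter <- function(x, y, theta, D, geometries) {
  if (!is.numeric(D) || length(D) != 1L || D <= 0) {
    abort("`D` must be a single positive reach (µm).")
  }
  geoms <- as_geometry_list(geometries)
  n <- max(length(x), length(y), length(theta))
  px <- rep_len(as.numeric(x), n)
  py <- rep_len(as.numeric(y), n)
  th <- rep_len(as.numeric(theta), n)
  ct <- cos(th)
  st <- sin(th)
  hit <- rep(FALSE, n)

  bod <- geometry_bodies(geoms)
  for (i in seq_len(nrow(bod))) {
    dx <- bod[i, "cx"] - px
    dy <- bod[i, "cy"] - py
    b <- dx * ct + dy * st
    cc <- dx * dx + dy * dy - bod[i, "R"]^2
    disc <- b * b - cc
    ok <- disc >= 0
    sq <- sqrt(pmax(disc, 0))
    # closed test: entry root <= D and exit root >= 0 (tangency disc == 0 counts)
    hit <- hit | (ok & (b + sq >= 0) & (b - sq <= D))
  }

  seg <- geometry_segments(geoms)
  for (i in seq_len(nrow(seg))) {
    vx <- seg[i, "x1"] - seg[i, "x0"]
    vy <- seg[i, "y1"] - seg[i, "y0"]
    w1 <- seg[i, "x0"] - px
    w2 <- seg[i, "y0"] - py
    denom <- ct * vy - st * vx
    num_t <- w1 * vy - w2 * vx
    num_s <- w1 * st - w2 * ct
    gen <- abs(denom) > 1e-12
    t <- ifelse(gen, num_t / denom, NA_real_)
    s <- ifelse(gen, num_s / denom, NA_real_)
    hit_gen <- gen & !is.na(t) & t >= 0 & t <= D & s >= 0 & s <= 1
    # parallel ray: hit only if collinear with the segment and overlapping [0, D]
    par <- !gen & abs(num_s) <= 1e-9
    if (any(par)) {
      ta <- w1 * ct + w2 * st
      tb <- (seg[i, "x1"] - px) * ct + (seg[i, "y1"] - py) * st
      hit_par <- par & (pmax(ta, tb) >= 0) & (pmin(ta, tb) <= D)
      hit <- hit | hit_par
    }
    hit <- hit | hit_gen
  }
  hit
}
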