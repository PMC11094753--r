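# pixel grids and per-pixel fields

# build a pixel grid: either a square window of side `domain_extent` centered
# at `domain_center`, or the geometry bounding box padded by `margin`; pixel
# centers are arranged symmetrically about the window center so that
# mirror-symmetric scenes yield exactly mirror-symmetric fields
make_grid <- function(geometries = NULL, pixel_size, margin = 0,
                      domain_extent = NULL, domain_center = NULL) {
  if (!is.numeric(pixel_size) || pixel_size <= 0) {
    abort("`pixel_size` must be positive (µm).")
  }
  if (!is.null(domain_extent)) {
    ctr <- domain_center %||% c(0, 0)
    nx <- max(1L, as.integer(round(domain_extent / pixel_size)))
    ny <- nx
    cx <- ctr[1]
    cy <- ctr[2]
  } else {
    bb <- geometry_bbox(as_geometry_list(geometries))
    cx <- (bb$xmin + bb$xmax) / 2
    cy <- (bb$ymin + bb$ymax) / 2
    nx <- max(1L, as.integer(ceiling((bb$xmax - bb$xmin + 2 * margin) / pixel_size)))
    ny <- max(1L, as.integer(ceiling((bb$ymax - bb$ymin + 2 * margin) / pixel_size)))
  }
  xs <- cx + (seq_len(nx) - (nx + 1) / 2) * pixel_size
  ys <- cy + (seq_len(ny) - (ny + 1) / 2) * pixel_size
  list(xs = xs, ys = ys, pixel_size = pixel_size)
}

field_tibble <- function(grid, value, value_name, geometries, extra_attrs = list()) {
  out <- tibble(
    x = rep(grid$xs, times = length(grid$ys)),
    y = rep(grid$ys, each = length(grid$xs))
  )
  out[[value_name]] <- value
  attr(out, "pixel_size") <- grid$pixel_size
  attr(out, "nx") <- length(grid$xs)
  attr(out, "ny") <- length(grid$ys)
  attr(out, "geometries") <- geometries
  for (nm in names(extra_attrs)) attr(out, nm) <- extra_attrs[[nm]]
  out
}

#' Compute a pixel-grid distance field for a plastid scene
#'
#' Partitions the plane into square pixels and stores, at every pixel center,
#' the exact distance to the nearest plastid element ([scene_distance()]).
#' Pixel discretization therefore affects only area integration, never the
#' stored point values.
#'
#' @inheritParams scene_distance
#' @param pixel_size Pixel side length in µm (default 0.05, the resolution
#'   used for area work).
#' @param margin Padding (µm) added around the geometry bounding box when no
#'   explicit window is given; must be at least the largest proximity `d` you
#'   intend to integrate over.
#' @param domain_extent Optional side length (µm) of a square window; when
#'   given, overrides the automatic bounding box.
#' @param domain_center Center of the explicit window (default the origin).
#' @return A tibble with columns `x`, `y`, `distance` (class
#'   `<distance_field>`), with the pixel size stored as an attribute.
#' @examples
#' g <- plastid_geometry("none", body_radius = 2, stromule_length = 0)
#' f <- compute_distance_field(g, pixel_size = 0.2, margin = 1.5)
#' interaction_area(f, d = 1)
#' @export
compute_distance_field <- function(geometries, pixel_size = 0.05, margin = 5,
                                   domain_extent = NULL, domain_center = NULL) {
  geoms <- as_geometry_list(geometries)
  if (!is.null(domain_extent)) {
    bb <- geometry_bbox(geoms)
    ctr <- domain_center %||% c(0, 0)
    half <- domain_extent / 2
    if (bb$xmin < ctr[1] - half || bb$xmax > ctr[1] + half ||
        bb$ymin < ctr[2] - half || bb$ymax > ctr[2] + half) {
      abort("Geometry extends outside the requested window; enlarge `domain_extent`.")
    }
  }
  grid <- make_grid(geoms, pixel_size, margin, domain_extent, domain_center)
  px <- rep(grid$xs, times = length(grid$ys))
  py <- rep(grid$ys, each = length(grid$xs))
  d <- scene_distance(px, py, geoms)
  out <- field_tibble(grid, d, "distance", geoms, list(margin = margin))
  class(out) <- c("distance_field", class(out))
  out
}

#' Interaction area within proximity d
#'
#' The "interaction region" of a plastid scene is the planar area within a
#' given distance `d` of the plastid boundary, excluding the plastid interior.
#' Measured on the pixel grid as (number of pixels with 0 < distance <= d) x
#' pixel area.
#'
#' @param field A `<distance_field>` from [compute_distance_field()].
#' @param d Proximity distance(s) in µm (each >= 0).
#' @return A tibble with columns `d` and `area_um2`, one row per `d`.
#' @export
interaction_area <- function(field, d) {
  if (!inherits(field, "distance_field")) {
    abort("`field` must be a <distance_field>.")
  }
  if (any(!is.finite(d)) || any(d < 0)) {
    abort("`d` must be non-negative and finite (µm).")
  }
  px2 <- attr(field, "pixel_size")^2
  dist <- field$distance
  tibble(
    d = as.numeric(d),
    area_um2 = vapply(d, function(di) sum(dist > 0 & dist <= di) * px2, numeric(1))
  )
}

#' Plastid (body) area on the pixel grid
#'
#' Area of the region occupied by plastid interiors (pixels at distance 0),
#' reported separately from the interaction region.
#'
#' @inheritParams interaction_area
#' @return Area in µm².
#' @export
plastid_area <- function(field) {
  if (!inherits(field, "distance_field")) {
    abort("`field` must be a <distance_field>.")
  }
  sum(field$distance == 0) * attr(field, "pixel_size")^2
}

#' Compute a plastid-access field by angular raytracing
#'
#' For every pixel center, rays are cast at angles 0, `angle_step`,
#' 2 `angle_step`, ... strictly below 2*pi (63 rays at the default 0.1 rad
#' step), and the fraction of rays that encounter plastid material within a
#' reach `D` is recorded. This "plastid access" approximates the proportion of
#' the perimeter of a small organelle at that point that could be in contact
#' with the plastid.
#'
#' Pixels inside a body have access 1; pixels farther than `D` from every
#' element have access 0 and are skipped (their rays cannot reach anything),
#' which keeps the raytracing cost proportional to the size of the reachable
#' band rather than the whole window.
#'
#' @inheritParams compute_distance_field
#' @param D Ray reach in µm (default 1).
#' @param pixel_size Pixel side length in µm (default 0.1; raytracing is the
#'   costly field, so a coarser default than for areas).
#' @param angle_step Angular increment in radians (default 0.1).
#' @return A tibble with columns `x`, `y`, `access` (class `<access_field>`);
#'   `D`, the ray count and the pixel size are stored as attributes.
#' @export
compute_access_field <- function(geometries, D = 1, pixel_size = 0.1,
                                 angle_step = 0.1, margin = NULL,
                                 domain_extent = NULL, domain_center = NULL) {
  if (!is.numeric(D) || D <= 0) abort("`D` must be positive (µm).")
  if (!is.numeric(angle_step) || angle_step <= 0) {
    abort("`angle_step` must be positive (radians).")
  }
  geoms <- as_geometry_list(geometries)
  margin <- margin %||% (D + 2 * pixel_size)
  grid <- make_grid(geoms, pixel_size, margin, domain_extent, domain_center)
  px <- rep(grid$xs, times = length(grid$ys))
  py <- rep(grid$ys, each = length(grid$xs))
  dist <- scene_distance(px, py, geoms)
  thetas <- seq(0, 2 * pi, by = angle_step)
  thetas <- thetas[thetas < 2 * pi * (1 - 1e-12)]
  access <- numeric(length(px))
  access[in_plastid_body(px, py, geoms)] <- 1
  band <- which(dist > 0 & dist <= D)
  if (length(band) > 0L) {
    hits <- integer(length(band))
    bx <- px[band]
    by <- py[band]
    for (th in thetas) {
      hits <- hits + ray_encounter(bx, by, th, D, geoms)
    }
    access[band] <- hits / length(thetas)
  }
  out <- field_tibble(grid, access, "access", geoms,
                      list(D = D, n_rays = length(thetas)))
  class(out) <- c("access_field", class(out))
  out
}

#' Summarize interaction capacity of a plastid scene
#'
#' Runs the distance-field and access-field simulations over a common square
#' window and assembles the per-scene quantities: interaction areas for each
#' proximity `d`, histograms of distance and access over the non-plastid
#' domain, the maximum access, and the mean distance. Deterministic given the
#' scene and settings.
#'
#' @inheritParams compute_distance_field
#' @param d Proximity distances in µm (default `c(0.5, 1, 2, 5)`).
#' @param D Access reach in µm (default 1).
#' @param access_pixel_size Pixel size for the access field (default 0.1).
#' @param angle_step Ray angular increment in radians (default 0.1).
#' @param domain_extent Square window side in µm (default 40); the same window
#'   is used for both fields so summaries of different scenes are comparable.
#' @return An `<interaction_summary>`: list with `areas` (tibble `d`,
#'   `area_um2`), `plastid_area_um2`, `distance_hist`, `access_hist` (tibbles
#'   `lower`, `upper`, `count`), `max_access`, `mean_distance`, and the
#'   settings used.
#' @export
summarize_scene <- function(geometries, d = c(0.5, 1, 2, 5), D = 1,
                            pixel_size = 0.05, access_pixel_size = 0.1,
                            angle_step = 0.1, domain_extent = 40,
                            domain_center = NULL) {
  geoms <- as_geometry_list(geometries)
  bb <- geometry_bbox(geoms)
  ctr <- domain_center %||% c(0, 0)
  half <- domain_extent / 2
  if (bb$xmin - max(d) < ctr[1] - half || bb$xmax + max(d) > ctr[1] + half ||
      bb$ymin - max(d) < ctr[2] - half || bb$ymax + max(d) > ctr[2] + half) {
    warn(paste(
      "The window does not contain the geometry plus the largest proximity d;",
      "interaction regions will be clipped at the window edge."
    ))
  }
  df <- compute_distance_field(geoms, pixel_size = pixel_size,
                               domain_extent = domain_extent,
                               domain_center = domain_center)
  af <- compute_access_field(geoms, D = D, pixel_size = access_pixel_size,
                             angle_step = angle_step,
                             domain_extent = domain_extent,
                             domain_center = domain_center)
  areas <- interaction_area(df, d)
  out_d <- df$distance[df$distance > 0]
  acc_out <- af$access[!in_plastid_body(af$x, af$y, geoms)]
  dist_breaks <- seq(0, max(out_d) + 0.5, by = 0.5)
  acc_breaks <- seq(0, 1, by = 0.05)
  structure(
    list(
      areas = areas,
      plastid_area_um2 = plastid_area(df),
      distance_hist = bin_counts(out_d, dist_breaks),
      access_hist = bin_counts(acc_out, acc_breaks),
      max_access = max(af$access[!in_plastid_body(af$x, af$y, geoms)], 0),
      mean_distance = mean(out_d),
      settings = list(
        d = d, D = D, pixel_size = pixel_size,
        access_pixel_size = access_pixel_size, angle_step = angle_step,
        domain_extent = domain_extent
      )
    ),
    class = "interaction_summary"
  )
}

# histogram counts on half-open bins (lower, upper], first bin closed at 0
bin_counts <- function(x, breaks) {
  cuts <- cut(x, breaks = breaks, include.lowest = TRUE, right = TRUE)
  cnt <- as.integer(table(cuts))
  tibble(
    lower = breaks[-length(breaks)],
    upper = breaks[-1],
    count = cnt
  )
}

#' @export
print.interaction_summary <- function(x, ...) {
  cat("<interaction_summary>\n")
  cat(sprintf("  plastid area: %.3f µm² | mean distance: %.3f µm | max access: %.3f\n",
              x$plastid_area_um2, x$mean_distance, x$max_access))
  print(x$areas)
  invisible(x)
}

#' @rdname summarize_scene
#' @param x An `<interaction_summary>`.
#' @param ... Unused.
#' @method tidy interaction_summary
#' @export
tidy.interaction_summary <- function(x, ...) {
  x$areas
}

#' @rdname summarize_scene
#' @method glance interaction_summary
#' @export
glance.interaction_summary <- function(x, ...) {
  tibble(
    plastid_area_um2 = x$plastid_area_um2,
    mean_distance_um = x$mean_distance,
    max_access = x$max_access,
    D = x$settings$D,
    pixel_size = x$settings$pixel_size,
    domain_extent = x$settings$domain_extent
  )
}
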