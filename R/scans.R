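#' Scan interaction capacity of a plastid pair over separations
#'
#' Places two plastids with centers separated horizontally by each value in
#' `separations` and measures the union interaction region (and optionally an
#' access summary) of the pair. The extension angle of each plastid's first
#' stromule is randomized independently per simulation instance; the same
#' per-instance angles are reused at every separation (common random numbers)
#' so that the dependence on separation is not masked by angle resampling.
#' Union areas are measured on a single distance field of the two-plastid
#' scene, so overlapping regions are never double counted.
#'
#' @param separations Center-to-center distances in µm (default 5-25 µm in
#'   5 µm steps, the measured range of characteristic plastid spacings).
#' @param config Stromule arrangement for both plastids (default `"single"`).
#' @param n_instances Number of random-angle instances per separation
#'   (default 100).
#' @param seed Optional integer seed for the instance angles.
#' @param body_radius,stromule_length Geometry parameters R and l (µm).
#' @param d Proximity distance in µm for the union interaction area.
#' @param pixel_size Pixel size in µm for the distance fields.
#' @param access Also compute the mean maximum access per separation
#'   (default `FALSE`; raytracing dominates the cost).
#' @param D,angle_step Access-field settings, used when `access = TRUE`.
#' @return A tibble with one row per separation: `separation_um`, `d`,
#'   `mean_area_um2`, `sd_area_um2`, `n_instances`, `bodies_overlap` (TRUE
#'   when separation < 2R) and, when `access = TRUE`, `mean_max_access`.
#' @export
pair_separation_scan <- function(separations = seq(5, 25, by = 5),
                                 config = "single",
                                 n_instances = 100,
                                 seed = NULL,
                                 body_radius = 2,
                                 stromule_length = 10,
                                 d = 1,
                                 pixel_size = 0.1,
                                 access = FALSE,
                                 D = 1,
                                 angle_step = 0.1) {
  if (any(separations <= 0)) abort("`separations` must be positive (µm).")
  if (n_instances < 1) abort("`n_instances` must be at least 1.")
  angles <- with_seed(seed, matrix(runif(2 * n_instances, 0, 2 * pi), nrow = 2))
  one_sep <- function(s) {
    areas <- numeric(n_instances)
    max_acc <- numeric(n_instances)
    for (i in seq_len(n_instances)) {
      g1 <- plastid_geometry(config, body_radius, stromule_length,
                             extension_angle = angles[1, i],
                             center = c(-s / 2, 0))
      g2 <- plastid_geometry(config, body_radius, stromule_length,
                             extension_angle = angles[2, i],
                             center = c(s / 2, 0))
      fld <- compute_distance_field(list(g1, g2), pixel_size = pixel_size,
                                    margin = d + 2 * pixel_size)
      areas[i] <- interaction_area(fld, d)$area_um2
      if (access) {
        af <- compute_access_field(list(g1, g2), D = D,
                                   pixel_size = pixel_size,
                                   angle_step = angle_step)
        max_acc[i] <- max(af$access[!in_plastid_body(af$x, af$y, list(g1, g2))], 0)
      }
    }
    row <- tibble(
      separation_um = s,
      d = d,
      mean_area_um2 = mean(areas),
      sd_area_um2 = stats::sd(areas),
      n_instances = n_instances,
      bodies_overlap = s < 2 * body_radius
    )
    if (access) row$mean_max_access <- mean(max_acc)
    row
  }
  out <- purrr::map_dfr(separations, one_sep)
  if (any(out$bodies_overlap)) {
    warn("Some separations place the two body discs in overlap (separation < 2R).")
  }
  out
}

#' Scan interaction area over stromule branch angle
#'
#' Builds Y-shaped stromules (a stem of length l/3 plus two branches of length
#' l/3) at each candidate branch angle, measures the interaction region at
#' proximity `d` on the pixel grid, and reports the angle that maximizes it.
#' The branch angle is measured between the stem arm (pointing back toward the
#' body) and each branch, so 120 degrees corresponds to the equal three-way
#' split of directions at the junction. Ties in the argmax are broken toward
#' 120 degrees.
#'
#' All angles are measured on one shared pixel grid (the union bounding box
#' of every candidate geometry, padded by `d`): the body and stem then
#' contribute identical pixels at every angle, so the comparison across
#' angles is affected only by the branch boundaries and the flat optimum is
#' resolved reliably at the default resolution.
#'
#' @param body_radius,stromule_length Geometry parameters R and l (µm);
#'   defaults 2 and 10.
#' @param d Proximity distance in µm (default 1).
#' @param angles Candidate branch angles in degrees, each in (0, 180]
#'   (default a 5-degree grid from 60 to 180).
#' @param pixel_size Pixel size in µm (default 0.05).
#' @return A tibble with columns `angle_deg`, `area_um2` and `optimum`
#'   (logical, TRUE for the maximizing angle); the optimal angle is also
#'   stored in the `"optimal_angle"` attribute.
#' @examples
#' scan <- branch_angle_scan(angles = seq(90, 150, by = 30), pixel_size = 0.2)
#' attr(scan, "optimal_angle")
#' @export
branch_angle_scan <- function(body_radius = 2, stromule_length = 10, d = 1,
                              angles = seq(60, 180, by = 5),
                              pixel_size = 0.05) {
  if (length(angles) == 0L) abort("`angles` must be a non-empty grid.")
  if (any(angles <= 0 | angles > 180)) {
    abort("`angles` must lie in (0, 180] degrees.")
  }
  geoms <- lapply(angles, function(a) {
    plastid_geometry("branched", body_radius, stromule_length,
                     extension_angle = 0, branch_angle = a)
  })
  grid <- make_grid(geoms, pixel_size, margin = d + 2 * pixel_size)
  px <- rep(grid$xs, times = length(grid$ys))
  py <- rep(grid$ys, each = length(grid$xs))
  areas <- vapply(geoms, function(g) {
    dist <- scene_distance(px, py, g)
    sum(dist > 0 & dist <= d) * pixel_size^2
  }, numeric(1))
  best <- max(areas)
  cand <- which(areas == best)
  # tie-break toward 120 degrees
  opt <- angles[cand[which.min(abs(angles[cand] - 120))]]
  out <- tibble(
    angle_deg = as.numeric(angles),
    area_um2 = areas,
    optimum = angles == opt
  )
  attr(out, "optimal_angle") <- opt
  out
}
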