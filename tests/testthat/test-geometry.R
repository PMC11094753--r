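test_that("stromule arrangements satisfy their structural invariants", {
  R <- 2
  l <- 10

  none <- plastid_geometry("none", R, 0)
  expect_equal(nrow(none$segments), 0)

  single <- plastid_geometry("single", R, l, extension_angle = 0.7)
  seg <- as.matrix(single$segments)
  root_r <- unname(sqrt(seg[1, "x0"]^2 + seg[1, "y0"]^2))
  expect_equal(root_r, R, tolerance = 1e-12)
  expect_equal(
    unname(sqrt((seg[1, "x1"] - seg[1, "x0"])^2 + (seg[1, "y1"] - seg[1, "y0"])^2)),
    l, tolerance = 1e-12
  )

  double <- plastid_geometry("double", R, l, extension_angle = 0)
  seg <- as.matrix(double$segments)
  # roots diametrically opposite, each segment l/2
  expect_equal(unname(seg[, c("x0", "y0")]), rbind(c(R, 0), c(-R, 0)))
  lens <- sqrt((seg[, "x1"] - seg[, "x0"])^2 + (seg[, "y1"] - seg[, "y0"])^2)
  expect_equal(unname(lens), c(l / 2, l / 2))

  branched <- plastid_geometry("branched", R, l, extension_angle = 0)
  seg <- as.matrix(branched$segments)
  lens <- sqrt((seg[, "x1"] - seg[, "x0"])^2 + (seg[, "y1"] - seg[, "y0"])^2)
  expect_equal(unname(lens), rep(l / 3, 3), tolerance = 1e-12)
  # all three arms leaving the junction pairwise 120 degrees apart
  junction <- seg[1, c("x1", "y1")]
  arms <- rbind(
    seg[1, c("x0", "y0")] - junction,
    seg[2, c("x1", "y1")] - junction,
    seg[3, c("x1", "y1")] - junction
  )
  ang <- sort(atan2(arms[, 2], arms[, 1]) %% (2 * pi))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  expect_equal(unname(gaps), rep(2 * pi / 3, 3), tolerance = 1e-9)

  # arbitrary extension angles keep the total length conserved
  for (a in seq(0, 2 * pi, length.out = 7)) {
    g <- plastid_geometry("branched", R, l, extension_angle = a)
    seg <- as.matrix(g$segments)
    expect_equal(
      sum(sqrt((seg[, "x1"] - seg[, "x0"])^2 + (seg[, "y1"] - seg[, "y0"])^2)),
      l, tolerance = 1e-9
    )
  }
})

test_that("invalid geometry arguments are rejected", {
  expect_error(plastid_geometry("spiral"), "arg")
  expect_error(plastid_geometry("single", stromule_length = -1), "non-negative")
  expect_error(plastid_geometry("none", stromule_length = 5), "stromule_length = 0")
  expect_error(plastid_geometry("single", stromule_length = 0), "stromule_length > 0")
  expect_error(plastid_geometry("none", body_radius = 0, stromule_length = 0), "positive")
})

test_that("scene_distance matches closed-form cases", {
  gn <- plastid_geometry("none", 2, 0)
  # interior, boundary, and radial offsets
  expect_equal(scene_distance(c(0, 1, 2, 5), c(0, 0, 0, 0), gn), c(0, 0, 0, 3))
  # perpendicular foot on an isolated segment midpoint
  gfar <- plastid_geometry("single", 2, 10, center = c(-100, 0))
  # segment spans x in [-98, -88]; probe above its midpoint
  expect_equal(scene_distance(-93, 0.7, gfar), 0.7, tolerance = 1e-12)
})

test_that("scene_distance is 1-Lipschitz and decomposes over geometries", {
  scenes <- standard_scenes()
  multi <- list(scenes$single,
                plastid_geometry("branched", center = c(9, 4)))
  set.seed(42)
  p <- matrix(runif(400, -15, 15), ncol = 2)
  q <- p + matrix(rnorm(400, 0, 0.5), ncol = 2)
  dp <- scene_distance(p[, 1], p[, 2], multi)
  dq <- scene_distance(q[, 1], q[, 2], multi)
  step <- sqrt(rowSums((p - q)^2))
  expect_true(all(abs(dp - dq) <= step + 1e-12))
  # min-decomposition across geometries
  d1 <- scene_distance(p[, 1], p[, 2], multi[[1]])
  d2 <- scene_distance(p[, 1], p[, 2], multi[[2]])
  expect_equal(dp, pmin(d1, d2))
})

test_that("ray encounters reproduce the disc-subtence cone", {
  gn <- plastid_geometry("none", 2, 0)
  # from (5, 0) a disc of radius 2 at the origin subtends half-angle asin(2/5)
  half <- asin(2 / 5)
  frac <- dense_ray_access(5, 0, gn, D = 100, n_rays = 2e4)
  expect_equal(frac, half / pi, tolerance = 5e-4)
  # rays just inside / outside the cone behave correctly
  expect_true(ray_encounter(5, 0, pi - half + 1e-6, D = 100, geometries = gn))
  expect_false(ray_encounter(5, 0, pi - half - 1e-6, D = 100, geometries = gn))
  # pointing straight away never encounters
  expect_false(ray_encounter(5, 0, 0, D = 100, geometries = gn))
  # starting inside a body encounters at every angle
  expect_true(all(ray_encounter(0.5, 0, seq(0, 6, 0.3), D = 0.1, geometries = gn)))
})

test_that("exactly tangent rays count as encounters", {
  # 3-4-5 configuration exact in floating point: ray along +x from the
  # origin is tangent to the circle of radius 3 centered at (0, 3)
  gt <- plastid_geometry("none", 3, 0, center = c(0, 3))
  expect_true(ray_encounter(0, 0, 0, D = 5, geometries = gt))
  # shifting the circle up by any amount breaks tangency
  gt2 <- plastid_geometry("none", 3, 0, center = c(0, 3 + 1e-9))
  expect_false(ray_encounter(0, 0, 0, D = 5, geometries = gt2))
})

test_that("rays within reach D hit segments, beyond D do not", {
  gfar <- plastid_geometry("single", 2, 10, center = c(-100, 0))
  # probe above the segment midpoint (-93, 0): straight down hits at t = 0.7
  expect_true(ray_encounter(-93, 0.7, -pi / 2, D = 0.7, geometries = gfar))
  expect_false(ray_encounter(-93, 0.7, -pi / 2, D = 0.69, geometries = gfar))
  # collinear ray along the segment line
  expect_true(ray_encounter(-87, 0, pi, D = 2, geometries = gfar))
  expect_false(ray_encounter(-87, 0, 0, D = 50, geometries = gfar))
})
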