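test_that("distance field stores exact point distances and zero inside bodies", {
  g <- plastid_geometry("single", 2, 10)
  fld <- compute_distance_field(g, pixel_size = 0.2, margin = 1)
  expect_equal(fld$distance, scene_distance(fld$x, fld$y, g))
  inside <- (fld$x^2 + fld$y^2) <= 4
  expect_true(all(fld$distance[inside] == 0))
  expect_true(all(fld$distance >= 0))
  # min decomposition: field of a composite scene is the elementwise min
  body_only <- plastid_geometry("none", 2, 0)
  d_body <- scene_distance(fld$x, fld$y, body_only)
  seg_far <- scene_distance(fld$x, fld$y, g) # full scene
  expect_true(all(seg_far <= d_body + 1e-12))
})

test_that("simulated annulus area converges to the closed form", {
  g <- plastid_geometry("none", 2, 0)
  exact <- annulus_oracle(2, 1)
  a_05 <- interaction_area(
    compute_distance_field(g, pixel_size = 0.05, margin = 1.3), 1
  )$area_um2
  expect_lt(abs(a_05 / exact - 1), 0.02)
  a_02 <- interaction_area(
    compute_distance_field(g, pixel_size = 0.02, margin = 1.3), 1
  )$area_um2
  expect_lt(abs(a_02 / exact - 1), 0.005)
})

test_that("interaction areas are monotone in d, zero at d = 0, and subadditive", {
  g <- plastid_geometry("single", 2, 10)
  fld <- compute_distance_field(g, pixel_size = 0.05, margin = 2.2)
  areas <- interaction_area(fld, c(0, 0.5, 1, 2))
  expect_equal(areas$area_um2[1], 0)
  expect_true(all(diff(areas$area_um2) > 0))
  # subadditivity vs the analytic disc annulus + segment stadium
  upper <- annulus_oracle(2, 1) + segment_dilation_area(10, 1)
  lower <- annulus_oracle(2, 1)
  a1 <- areas$area_um2[areas$d == 1]
  expect_gt(a1, lower)
  expect_lt(a1, upper)
  expect_error(interaction_area(fld, -1), "non-negative")
})

test_that("access field is a proportion field with the documented structure", {
  g <- plastid_geometry("single", 2, 10)
  af <- compute_access_field(g, D = 1, pixel_size = 0.25, margin = 2)
  expect_equal(attr(af, "n_rays"), 63) # 0.1-rad scan strictly below 2*pi
  expect_true(all(af$access >= 0 & af$access <= 1))
  inside <- (af$x^2 + af$y^2) <= 4
  expect_true(all(af$access[inside] == 1))
  far <- scene_distance(af$x, af$y, g) > 1
  expect_true(all(af$access[far] == 0))
})

test_that("access matches the dense-ray oracle and the half-plane limit", {
  g <- plastid_geometry("single", 2, 10)
  af <- compute_access_field(g, D = 1, pixel_size = 0.5, margin = 1.2)
  probe <- which(af$access > 0 & af$access < 1)
  probe <- probe[round(seq(1, length(probe), length.out = 6))]
  for (i in probe) {
    oracle <- dense_ray_access(af$x[i], af$y[i], g, D = 1)
    expect_lt(abs(af$access[i] - oracle), 2 / 63)
  }
  # a point just beside the midpoint of a long isolated segment sees half
  # of all directions
  glong <- plastid_geometry("single", 2, 100, center = c(-52, 0))
  expect_equal(dense_ray_access(0, 0.01, glong, D = 5), 0.5, tolerance = 0.01)
})

test_that("access is monotone non-decreasing in reach D at every pixel", {
  g <- plastid_geometry("branched", 2, 10)
  a1 <- compute_access_field(g, D = 0.5, pixel_size = 0.25,
                             domain_extent = 20, domain_center = c(3, 0))
  a2 <- compute_access_field(g, D = 1, pixel_size = 0.25,
                             domain_extent = 20, domain_center = c(3, 0))
  a3 <- compute_access_field(g, D = 2, pixel_size = 0.25,
                             domain_extent = 20, domain_center = c(3, 0))
  expect_true(all(a2$access - a1$access >= 0))
  expect_true(all(a3$access - a2$access >= 0))
})

test_that("scene summaries conserve pixel counts and order the geometries", {
  scenes <- standard_scenes()
  sums <- lapply(scenes, summarize_scene,
                 d = c(0.5, 1, 2), D = 1, pixel_size = 0.1,
                 access_pixel_size = 0.2, domain_extent = 36)
  for (s in sums) {
    # distance histogram counts every non-interior pixel exactly once
    n_out <- sum(s$distance_hist$count)
    n_tot <- round(s$settings$domain_extent / s$settings$pixel_size)^2
    expect_equal(n_out + s$plastid_area_um2 / s$settings$pixel_size^2, n_tot)
    expect_true(all(s$access_hist$count >= 0))
  }
  # stromule extension brings the cytoplasm closer on average
  expect_lt(sums$single$mean_distance, sums$none$mean_distance)
  # area ordering at matched total length, every d
  for (k in seq_along(sums$none$areas$d)) {
    a <- vapply(sums, function(s) s$areas$area_um2[k], numeric(1))
    expect_true(a[["single"]] >= a[["branched"]])
    expect_true(a[["branched"]] >= a[["none"]])
  }
  # tidy/glance views
  expect_named(tidy(sums$single), c("d", "area_um2"))
  expect_equal(nrow(glance(sums$single)), 1)
})

test_that("windows too small for the geometry are rejected or flagged", {
  g <- plastid_geometry("single", 2, 10)
  expect_error(
    compute_distance_field(g, pixel_size = 0.2, domain_extent = 10),
    "outside the requested window"
  )
  expect_warning(
    summarize_scene(g, d = 5, pixel_size = 0.2, access_pixel_size = 0.4,
                    domain_extent = 26),
    "clipped"
  )
})
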