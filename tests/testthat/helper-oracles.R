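# independent oracles used across test files

# dense-ray access oracle: fraction of n_rays uniformly spaced directions
# whose ray of length D encounters the scene, at a much finer angular
# resolution than the production 0.1-rad scan
dense_ray_access <- function(x, y, geometries, D, n_rays = 1e4) {
  thetas <- seq(0, 2 * pi, length.out = n_rays + 1)[-(n_rays + 1)]
  mean(ray_encounter(x, y, thetas, D, geometries))
}

# closed-form area within d of a disc of radius R (annulus), the analytic
# oracle for NONE interaction areas
annulus_oracle <- function(R, d) pi * ((R + d)^2 - R^2)

# a small standard scene set at matched total stromule length
standard_scenes <- function(R = 2, l = 10) {
  list(
    none = plastid_geometry("none", R, 0),
    single = plastid_geometry("single", R, l),
    double = plastid_geometry("double", R, l),
    branched = plastid_geometry("branched", R, l)
  )
}
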