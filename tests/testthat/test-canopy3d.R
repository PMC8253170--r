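test_that("scene GAI counts lamina fully and stems/ears half", {
  # one unit-area lamina triangle over a unit footprint
  v1 <- rbind(c(0, 0, 0.1)); v2 <- rbind(c(2, 0, 0.1)); v3 <- rbind(c(0, 1, 0.1))
  sc <- triangle_scene(v1, v2, v3, "lamina", footprint = c(1, 1))
  expect_equal(scene_gai(sc), 1)
  sc_stem <- triangle_scene(v1, v2, v3, "stem", footprint = c(1, 1))
  expect_equal(scene_gai(sc_stem), 0.5)
  empty <- triangle_scene(matrix(0, 0, 3), matrix(0, 0, 3), matrix(0, 0, 3),
                          character(0), footprint = c(1, 1))
  expect_equal(scene_gai(empty), 0)
  expect_error(triangle_scene(v1, v2, rbind(c(0, 1, -1)), "lamina", c(1, 1)),
               "ground")
})

test_that("generator hits its GAI target and obeys per-organ distributions", {
  sc <- gs31_scene(3)
  expect_lt(abs(scene_gai(sc) - 1.2) / 1.2, 0.02)
  # stems near the prescribed inclination
  expect_lt(abs(rad2deg(scene_theta_mean(sc, "stem")) - 75), 2)
  # erectophile generator (chi = 0.5): mean inclination near 70 degrees,
  # matching the density's first moment (72.1 degrees) within Monte-Carlo
  # noise; the empirical chi/mean-angle relation would say 70
  sc70 <- generate_canopy(gai = 1, arrangement = "uniform",
    lamina_dist = angle_distribution("ellipsoidal", chi = 0.5),
    organ_shares = c(lamina = 1, stem = 0, ear = 0),
    tri_area = 2e-4, n_rows = 3, row_length = 0.5, seed = 9)
  expect_lt(abs(rad2deg(scene_theta_mean(sc70, "lamina")) - 72.1), 1)
  # horizontal elements score zero inclination
  flat <- planar_cover_scene(0.3)
  expect_equal(rad2deg(scene_theta_mean(flat, "lamina")), 0, tolerance = 1e-9)
  # same seed, same scene, bit for bit
  expect_identical(gs31_scene(3)$v1, sc$v1)
  # angle sample of a generated scene passes a KS test against its own
  # family
  samp <- scene_angle_sample(sc70, "lamina")
  res <- ks_fit_test(samp, angle_distribution("ellipsoidal", chi = 0.5),
                     reference_n = 4 * length(samp$angles), seed = 11)
  expect_gt(res$p_value, 0.01)
  expect_error(generate_canopy(gai = 1, n_rows = 0), "infeasible")
})

test_that("ray-cast gap fraction: planar cover, empty scenes, determinism", {
  # non-overlapping 30% horizontal cover seen from near-nadir
  flat <- planar_cover_scene(0.3)
  gf <- gap_fraction(flat, list(elevation = deg2rad(89.9), azimuth = 0),
                     n_rays = 2e4, seed = 5)
  expect_lt(abs(as.numeric(gf) - 0.7), 0.01)
  # empty scene: everything escapes
  empty <- triangle_scene(matrix(0, 0, 3), matrix(0, 0, 3), matrix(0, 0, 3),
                          character(0), footprint = c(1, 1))
  expect_equal(as.numeric(gap_fraction(empty,
    list(elevation = 0.5, azimuth = 0), n_rays = 1e4, seed = 1)), 1)
  # identical seeds reproduce bit for bit
  sc <- gs31_scene(4)
  g1 <- gap_fraction(sc, list(elevation = 0.6, azimuth = 1), n_rays = 1e4,
                     seed = 7)
  g2 <- gap_fraction(sc, list(elevation = 0.6, azimuth = 1), n_rays = 1e4,
                     seed = 7)
  expect_identical(as.numeric(g1), as.numeric(g2))
  expect_error(gap_fraction(sc, list(elevation = -0.1, azimuth = 0)),
               "elevation")
  expect_error(gap_fraction(sc, list(elevation = 0.5, azimuth = 0),
                            n_rays = 100), "n_rays")
})

test_that("adding elements never opens new gaps", {
  s1 <- gs31_scene(6)
  extra <- planar_cover_scene(0.1, ncell = 5, height = 0.3)
  s2 <- triangle_scene(rbind(s1$v1, extra$v1 * c(0.7, 0.7, 1)),
                       rbind(s1$v2, extra$v2 * c(0.7, 0.7, 1)),
                       rbind(s1$v3, extra$v3 * c(0.7, 0.7, 1)),
                       c(s1$organ, extra$organ), footprint = s1$footprint)
  for (b in c(0.4, 1.0)) {
    g1 <- gap_fraction(s1, list(elevation = b, azimuth = 0.3), n_rays = 1e4,
                       seed = 3)
    g2 <- gap_fraction(s2, list(elevation = b, azimuth = 0.3), n_rays = 1e4,
                       seed = 3)
    expect_lte(as.numeric(g2), as.numeric(g1))
  }
})

test_that("gap-fraction inversion: slab oracle and unclumped identity", {
  # a strip covering half the footprint in every direction inverts to
  # -ln(0.5) under the normalized ring sum
  slab <- half_slab_scene()
  eg <- scene_effective_gai(slab, n_azimuth = 2, n_rays = 1e4, seed = 2)
  expect_equal(as.numeric(eg), -log(0.5), tolerance = 0.02)
  # ring and Gauss quadratures agree on a smooth scene
  eg_g <- scene_effective_gai(slab, n_azimuth = 2, n_rays = 1e4, seed = 2,
                              method = "gauss")
  expect_lt(abs(as.numeric(eg_g) - as.numeric(eg)) / as.numeric(eg), 0.02)

  # unclumped random canopy: effective GAI equals measured GAI
  sc <- uniform_scene(8, chi = 1, gai = 1)
  su <- scene_summary(sc, n_azimuth = 2, n_rays = 1e4, seed = 13)
  expect_lt(abs(su$cgai - 1), 0.05)
  expect_equal(su$gai_mes, 1, tolerance = 0.02)
})

test_that("scenes round-trip through OBJ text files", {
  sc <- gs31_scene(12)
  path <- withr::local_tempfile(fileext = ".obj")
  write_obj(sc, path)
  sc2 <- read_obj(path)
  expect_equal(sc2$v1, sc$v1, tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(sc2$organ, sc$organ)
  expect_equal(sc2$footprint, sc$footprint, tolerance = 1e-6)
  expect_equal(scene_gai(sc2), scene_gai(sc), tolerance = 1e-3)
})
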