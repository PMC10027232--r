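test_that("a leafless stem spans exactly the spec height", {
  ps <- plant_spec(height = 80)
  pc <- generate_plant(ps, seed = 1)
  expect_equal(max(pc$z) - min(pc$z), 80, tolerance = 1e-9)
})

test_that("a horizontal flat leaf has no vertical spread and full reach", {
  lf <- leaf_spec(growth_height = 40, azimuth = 0, length = 30, width = 5,
                  inclination = 0, arch = 0)
  ps <- plant_spec(height = 80, leaves = lf)
  pc <- generate_plant(ps, seed = 2)
  leaf <- pc[pc$part == "leaf", ]
  expect_lt(diff(range(leaf$z)), 1e-9)
  # XY reach from the stem axis: stem radius + midrib length
  expect_equal(max(sqrt(leaf$x^2 + leaf$y^2)), 31, tolerance = 0.2)
})

test_that("seeded generation is exactly reproducible", {
  ps <- random_plant_spec(5)
  a <- generate_plant(ps, noise_sd = 0.3, seed = 99)
  b <- generate_plant(ps, noise_sd = 0.3, seed = 99)
  expect_identical(a, b)

  sc <- scene_spec(n_rows = 1, n_cols = 2, seed = 3)
  s1 <- generate_scene(sc)
  s2 <- generate_scene(sc)
  expect_identical(s1$cloud, s2$cloud)
  expect_identical(s1$truth$plants, s2$truth$plants)
})

test_that("scene ground truth labels partition the cloud", {
  sc <- scene_spec(n_rows = 2, n_cols = 3, seed = 4, n_outliers = 50)
  scn <- generate_scene(sc)
  expect_equal(nrow(scn$truth$labels), nrow(scn$cloud))
  expect_setequal(unique(scn$truth$labels$role),
                  c("plant", "ground", "sphere", "outlier"))
  expect_equal(sort(unique(scn$truth$labels$instance[
    scn$truth$labels$role == "plant"])), 1:6)
  expect_equal(nrow(scn$truth$plants), 6)
})

test_that("flat noiseless ground lies exactly on the plane", {
  sc <- scene_spec(n_rows = 1, n_cols = 2, ground_slope = 0,
                   ground_roughness = 0, noise_sd = 0, n_outliers = 0,
                   seed = 5)
  scn <- generate_scene(sc)
  gz <- scn$cloud$z[scn$truth$labels$role == "ground"]
  expect_lt(max(abs(gz)), 1e-12)
})

test_that("noisy ground points stay near the true plane on average", {
  sc <- scene_spec(n_rows = 1, n_cols = 2, ground_slope = 0,
                   ground_roughness = 0, noise_sd = 0.5, n_outliers = 0,
                   seed = 6)
  scn <- generate_scene(sc)
  gz <- scn$cloud$z[scn$truth$labels$role == "ground"]
  expect_lt(mean(abs(gz)), 0.6)
})

test_that("spheres rest tangent to the soil plane", {
  sc <- scene_spec(n_rows = 1, n_cols = 2, ground_slope = 3,
                   ground_roughness = 0, noise_sd = 0, n_outliers = 0,
                   seed = 7)
  scn <- generate_scene(sc)
  nrm <- scn$truth$plane$normal
  for (i in seq_len(nrow(scn$truth$spheres))) {
    ctr <- as.numeric(scn$truth$spheres[i, c("x", "y", "z")])
    expect_equal(sum(ctr * nrm), scn$truth$spheres$diameter[i] / 2,
                 tolerance = 1e-9)
  }
})

test_that("spec validation rejects impossible geometry", {
  expect_error(leaf_spec(40, 0, length = 4, width = 5, inclination = 10),
               "length > width")
  expect_error(leaf_spec(40, 0, length = 30, width = 5, inclination = 95),
               "0, 90")
  expect_error(plant_spec(height = -1), "positive")
  expect_error(plant_spec(height = 50,
                          leaves = leaf_spec(60, 0, 30, 5, 20)),
               "below the plant height")
  expect_error(generate_plant(plant_spec(80), density = 0), "positive")
})

test_that("scenes round-trip through the on-disk format", {
  sc <- scene_spec(n_rows = 1, n_cols = 2, seed = 8, n_outliers = 20)
  scn <- generate_scene(sc)
  dir <- withr::local_tempdir()
  write_scene(scn, dir)
  expect_true(all(file.exists(file.path(
    dir, c("cloud.ply", "labels.csv", "plants.csv", "leaves.csv",
           "scene_spec.yaml")))))
  spec2 <- read_scene_spec(file.path(dir, "scene_spec.yaml"))
  scn2 <- generate_scene(spec2)
  expect_equal(scn2$cloud, scn$cloud)
  yaml::write_yaml(list(bogus_key = 1), file.path(dir, "bad.yaml"))
  expect_error(read_scene_spec(file.path(dir, "bad.yaml")), "unknown")
})

test_that("random plant specs respect their declared ranges", {
  for (s in 1:10) {
    ps <- random_plant_spec(s)
    expect_gte(ps$height, 45); expect_lte(ps$height, 92)
    expect_true(all(ps$leaves$growth_height < ps$height))
    expect_true(all(ps$leaves$inclination >= 0 &
                      ps$leaves$inclination <= 60))
    expect_true(all(diff(sort(ps$leaves$growth_height)) > 4))
  }
})
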