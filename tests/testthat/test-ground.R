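make_sloped_scene <- function(seed, slope_deg = 5, frac_off = 0.2,
                              n = 2000) {
  withr::with_seed(seed, {
    n_g <- round(n * (1 - frac_off))
    gx <- runif(n_g, 0, 100); gy <- runif(n_g, 0, 100)
    gz <- tan(slope_deg * pi / 180) * gy
    n_p <- n - n_g
    px <- runif(n_p, 0, 100); py <- runif(n_p, 0, 100)
    pz <- tan(slope_deg * pi / 180) * py + runif(n_p, 5, 60)
    list(cloud = point_cloud(c(gx, px), c(gy, py), c(gz, pz)),
         normal = c(0, -sin(slope_deg * pi / 180),
                    cos(slope_deg * pi / 180)),
         is_ground = c(rep(TRUE, n_g), rep(FALSE, n_p)))
  })
}

test_that("a dominant exact plane is recovered to numerical precision", {
  pc <- withr::with_seed(1, point_cloud(
    x = c(runif(1000, 0, 50), runif(50, 0, 50)),
    y = c(runif(1000, 0, 50), runif(50, 0, 50)),
    z = c(rep(0, 1000), runif(50, 10, 40))))
  pl <- ransac_plane(pc, distance_threshold = 0.5, seed = 1)
  expect_equal(unname(pl$normal), c(0, 0, 1), tolerance = 1e-6)
  expect_gte(pl$n_inliers, 1000)
  expect_lt(pl$rms, 1e-9)
})

test_that("tilted planes with outliers are recovered within 0.5 degrees", {
  sc <- make_sloped_scene(seed = 2)
  pl <- ransac_plane(sc$cloud, distance_threshold = 0.5, iterations = 500,
                     seed = 42)
  ang <- acos(min(1, sum(pl$normal * sc$normal))) * 180 / pi
  expect_lt(ang, 0.5)
})

test_that("plane fitting input contracts hold", {
  expect_error(ransac_plane(point_cloud(x = 1:2, y = 1:2, z = 1:2)),
               "at least 3")
  expect_error(ransac_plane(random_cloud(10, 1), distance_threshold = 0),
               "positive")
  line <- point_cloud(x = 1:10, y = 1:10, z = 1:10)
  expect_error(ransac_plane(line, seed = 1), "collinear")
})

test_that("leveling is rigid and idempotent", {
  sc <- make_sloped_scene(seed = 3)
  pl <- ransac_plane(sc$cloud, 0.5, seed = 1)
  lv <- level_scene(sc$cloud, pl)
  # rigidity: pairwise distances preserved
  i <- c(1, 500); j <- c(900, 1500)
  d0 <- sqrt((sc$cloud$x[i] - sc$cloud$x[j])^2 +
               (sc$cloud$y[i] - sc$cloud$y[j])^2 +
               (sc$cloud$z[i] - sc$cloud$z[j])^2)
  d1 <- sqrt((lv$x[i] - lv$x[j])^2 + (lv$y[i] - lv$y[j])^2 +
               (lv$z[i] - lv$z[j])^2)
  expect_equal(d1, d0, tolerance = 1e-9)
  tr <- leveling_transform(lv)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-12)
  expect_equal(crossprod(tr$rotation), diag(3), tolerance = 1e-12)
  # ground points land on Z = 0
  expect_lt(max(abs(lv$z[sc$is_ground])), 1e-6)
  # releveling with the refit plane is the identity
  pl2 <- ransac_plane(lv, 0.5, seed = 2)
  lv2 <- level_scene(lv, pl2)
  expect_equal(cbind(lv2$x, lv2$y, lv2$z), cbind(lv$x, lv$y, lv$z),
               tolerance = 1e-6)
})

test_that("an already-level cloud levels to itself", {
  pc <- random_cloud(100, seed = 4)
  pl <- list(normal = c(0, 0, 1), d = 0)
  lv <- level_scene(pc, pl)
  expect_equal(cbind(lv$x, lv$y, lv$z), cbind(pc$x, pc$y, pc$z),
               tolerance = 1e-12)
  expect_equal(leveling_transform(lv)$rotation, diag(3))
})

test_that("ground removal honours the margin and keeps labels", {
  sc <- make_sloped_scene(seed = 5)
  pl <- ransac_plane(sc$cloud, 0.5, seed = 1)
  lv <- level_scene(sc$cloud, pl)
  lv$label <- as.integer(!sc$is_ground)
  out <- remove_ground(lv, plane = NULL, margin = 1)
  expect_true(all(out$z > 1))
  expect_true(all(out$label == 1L))
  expect_error(remove_ground(lv, margin = -1), "non-negative")
})

test_that("unleveled removal against the plane matches leveled removal", {
  sc <- make_sloped_scene(seed = 6)
  pl <- ransac_plane(sc$cloud, 0.5, seed = 1)
  direct <- remove_ground(sc$cloud, plane = pl, margin = 1)
  lv <- level_scene(sc$cloud, pl)
  leveled <- remove_ground(lv, plane = NULL, margin = 1)
  expect_equal(nrow(direct), nrow(leveled))
})
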