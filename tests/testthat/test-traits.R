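test_that("plant height is Zmax minus Zmin (or the ground reference)", {
  pc <- point_cloud(x = c(0, 1, 2), y = 0, z = c(0, 20, 48.56))
  expect_equal(plant_height(pc), 48.56)
  expect_equal(plant_height(pc, ground_level = 0), 48.56)
  pc2 <- pc; pc2$z <- pc2$z + 5
  expect_equal(plant_height(pc2, ground_level = 0), 53.56)
  expect_error(plant_height(pc, instance = 1), "instance")
  expect_warning(h <- plant_height(point_cloud(0, 0, 7)), "single-point")
  expect_equal(h, 0)
})

test_that("plant height is invariant to rotation about Z and XY shifts", {
  pc <- generate_plant(random_plant_spec(1), seed = 21)
  h0 <- plant_height(pc)
  th <- 1.1
  rot <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  m <- cbind(pc$x, pc$y) %*% t(rot)
  moved <- point_cloud(m[, 1] + 50, m[, 2] - 30, pc$z)
  expect_equal(plant_height(moved), h0, tolerance = 1e-9)
})

test_that("a noiseless synthetic plant recovers its spec height", {
  ps <- plant_spec(height = 80, leaves = leaf_spec(40, 10, 30, 5, 30))
  pc <- generate_plant(ps, seed = 22)
  expect_equal(plant_height(pc, ground_level = 0), 80, tolerance = 0.51)
})

test_that("leaves of a well separated plant are found one-to-one", {
  ps <- random_plant_spec(8)
  pc <- generate_plant(ps, seed = 23)
  leaves <- extract_leaves(as_point_cloud(pc[, c("x", "y", "z")]))
  expect_equal(length(leaves), nrow(ps$leaves))
  # point sets match the generator's leaf labels (leaves ordered by height)
  ord <- order(ps$leaves$growth_height)
  for (i in seq_along(leaves)) {
    true_ids <- pc$leaf_id[leaves[[i]]$indices]
    true_ids <- true_ids[!is.na(true_ids)]
    expect_equal(unique(true_ids), ord[i])
    # and nearly all of that leaf's off-stem points are captured
    expect_gt(length(true_ids) / sum(pc$leaf_id == ord[i], na.rm = TRUE),
              0.9)
  }
})

test_that("a leafless stem yields no leaf segments", {
  pc <- generate_plant(plant_spec(height = 70), seed = 24)
  leaves <- extract_leaves(as_point_cloud(pc[, c("x", "y", "z")]))
  expect_length(leaves, 0)
})

test_that("opposite leaves at one growth height split azimuthally", {
  lf <- leaf_spec(c(40, 40), c(0, 180), c(28, 26), c(5, 5), c(30, 35))
  ps <- plant_spec(height = 80, leaves = lf)
  pc <- generate_plant(ps, seed = 25)
  leaves <- extract_leaves(as_point_cloud(pc[, c("x", "y", "z")]))
  expect_length(leaves, 2)
})

test_that("leaf length is the midrib arc length, at least the chord", {
  straight <- structure(list(midrib = tibble::tibble(
    x = seq(0, 30, 1), y = 0, z = 0)), class = "leaf_segment")
  expect_equal(leaf_length(straight), 30)
  th <- seq(0, pi / 2, length.out = 100)
  quarter <- structure(list(midrib = tibble::tibble(
    x = 10 * sin(th), y = 0, z = 10 * (1 - cos(th)))),
    class = "leaf_segment")
  expect_equal(leaf_length(quarter), pi / 2 * 10, tolerance = 0.01)
  chord <- sqrt(sum((c(10, 0, 10))^2))
  expect_gte(leaf_length(quarter), chord)
  expect_error(leaf_length(structure(list(midrib = tibble::tibble(
    x = 1, y = 1, z = 1)), class = "leaf_segment")), "degenerate")
})

test_that("leaf width recovers the taper maximum on synthetic leaves", {
  ps <- plant_spec(height = 80,
                   leaves = leaf_spec(40, 45, 30, 6, 25))
  pc <- generate_plant(ps, seed = 26)
  leaves <- extract_leaves(as_point_cloud(pc[, c("x", "y", "z")]))
  expect_length(leaves, 1)
  expect_equal(leaf_width(leaves[[1]]), 6, tolerance = 0.45)
})

test_that("inclination follows the complement convention", {
  # horizontal midrib: stem-leaf angle 90, inclination 0
  flat <- structure(list(midrib = tibble::tibble(
    x = seq(1, 20, 0.5), y = 0, z = 40)), class = "leaf_segment")
  expect_equal(leaf_inclination(flat), 0, tolerance = 1e-6)
  # 45 degree midrib
  s <- seq(0, 20, 0.5)
  mid45 <- structure(list(midrib = tibble::tibble(
    x = 1 + s / sqrt(2), y = 0, z = 40 + s / sqrt(2))),
    class = "leaf_segment")
  expect_equal(leaf_inclination(mid45), 45, tolerance = 1e-6)
  expect_error(leaf_inclination(structure(list(midrib = tibble::tibble(
    x = 1, y = 1, z = 1)), class = "leaf_segment")), "degenerate")
})

test_that("growth height is the attachment height and warns below ground", {
  leaf <- structure(list(attachment = c(5, 5, 40)), class = "leaf_segment")
  expect_equal(leaf_growth_height(leaf), 40)
  below <- structure(list(attachment = c(0, 0, -2)), class = "leaf_segment")
  expect_warning(gh <- leaf_growth_height(below), "leveling")
  expect_equal(gh, -2)
  expect_error(leaf_growth_height(structure(list(), class = "leaf_segment")),
               "attachment")
})

test_that("extract_traits emits one row per leaf with stable schema", {
  ps <- random_plant_spec(9)
  pc <- generate_plant(ps, seed = 27)
  cloud <- as_point_cloud(pc[, c("x", "y", "z")])
  cloud$instance <- 1L
  tr <- extract_traits(cloud)
  expect_named(tr, c("plant_id", "height_cm", "leaf_id", "length_cm",
                     "width_cm", "inclination_deg", "growth_height_cm"))
  expect_equal(nrow(tr), nrow(ps$leaves))
  expect_true(all(tr$growth_height_cm <= tr$height_cm))
  expect_true(all(tr$inclination_deg >= 0 & tr$inclination_deg <= 90))
})
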