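test_that("noiseless sphere samples are fitted exactly", {
  pc <- sphere_points(200, c(3, -2, 14), 12.5, seed = 1)
  fit <- fit_sphere(pc)
  expect_equal(fit$radius, 12.5, tolerance = 1e-6)
  expect_equal(unname(fit$center), c(3, -2, 14), tolerance = 1e-6)
  expect_lt(fit$rms, 1e-9)
})

test_that("a noisy upper hemisphere is still fitted to within the noise", {
  pc <- withr::with_seed(2, {
    p <- sphere_points(800, c(0, 0, 10), 10)
    p <- p[p$z >= 10, ]
    p$x <- p$x + rnorm(nrow(p), 0, 0.1)
    p$y <- p$y + rnorm(nrow(p), 0, 0.1)
    p$z <- p$z + rnorm(nrow(p), 0, 0.1)
    p
  })
  fit <- fit_sphere(pc)
  expect_lt(abs(fit$radius - 10), 0.1)
})

test_that("degenerate sphere inputs raise", {
  expect_error(fit_sphere(point_cloud(x = 1:3, y = 1:3, z = 1:3)),
               "insufficient")
  flat <- point_cloud(x = runif(20), y = runif(20), z = 0)
  expect_error(fit_sphere(flat), "degenerate|no sphere")
})

test_that("sphere fitting is rigid-motion equivariant", {
  pc <- sphere_points(300, c(0, 0, 0), 7, seed = 3)
  base <- fit_sphere(pc)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  m <- cbind(pc$x, pc$y, pc$z) %*% t(rot)
  moved <- point_cloud(x = m[, 1] + 5, y = m[, 2] - 3, z = m[, 3] + 11)
  fit <- fit_sphere(moved)
  expect_equal(fit$radius, base$radius, tolerance = 1e-9)
  expect_equal(unname(fit$center),
               as.numeric(rot %*% unname(base$center)) + c(5, -3, 11),
               tolerance = 1e-8)
})

test_that("scale calibration combines sphere ratios", {
  expect_equal(calibrate_scale(c(25, 20), c(25, 20))$scale, 1)
  cal <- calibrate_scale(c(24, 19.2), c(25, 20))
  expect_equal(cal$scale, 25 / 24, tolerance = 1e-12)
  expect_error(calibrate_scale(numeric(), numeric()), "at least one")
  expect_error(calibrate_scale(c(25), c(25, 20)), "same length")
  expect_error(calibrate_scale(c(-1), c(25)), "positive")
  # scale-equivariance: scaling fitted diameters by s divides the factor by s
  expect_equal(calibrate_scale(2 * c(24, 19.2), c(25, 20))$scale,
               cal$scale / 2, tolerance = 1e-12)
})

test_that("apply_scale rescales about the centroid", {
  pc <- random_cloud(100, seed = 4)
  out <- apply_scale(pc, 2)
  expect_equal(mean(out$x), mean(pc$x), tolerance = 1e-9)
  expect_equal(diff(range(out$z)), 2 * diff(range(pc$z)), tolerance = 1e-9)
  fitd <- c(24, 19.2)
  cal <- calibrate_scale(fitd, c(25, 20))
  expect_equal(cal$scale * fitd, c(25, 20), tolerance = 1e-12)
})

test_that("DLT solves exact correspondences to numerical precision", {
  cs <- random_camera_correspondences(seed = 10)
  model <- solve_dlt(cs)
  expect_lt(model$rms, 1e-8)
  proj <- project_dlt(model, cs)
  expect_lt(max(abs(proj$x - cs$x), abs(proj$y - cs$y)), 1e-6)
})

test_that("DLT rejects underdetermined and coplanar configurations", {
  cs <- random_camera_correspondences(seed = 11)
  expect_error(solve_dlt(cs[1:5, ]), "at least 6")
  flat <- cs[1:10, ]
  flat$Z <- 7
  flat$x <- flat$X * 3 + 1  # arbitrary planar image points
  flat$y <- flat$Y * 3 + 2
  expect_error(solve_dlt(flat), "coplanar")
})

test_that("a constant-projection parameter vector maps everywhere the same", {
  l <- setNames(rep(0, 11), paste0("l", 1:11))
  l["l4"] <- -5; l["l8"] <- -7
  model <- structure(list(l = l, rms = 0, n = 0), class = "dlt_model")
  proj <- project_dlt(model, tibble::tibble(X = c(0, 9), Y = c(1, -4),
                                            Z = c(2, 8)))
  expect_equal(proj$x, c(5, 5))
  expect_equal(proj$y, c(7, 7))
})

test_that("vanishing DLT denominators raise", {
  l <- setNames(c(rep(0, 8), 1, 0, 0), paste0("l", 1:11))
  model <- structure(list(l = l, rms = 0, n = 0), class = "dlt_model")
  expect_error(project_dlt(model, tibble::tibble(X = -1, Y = 0, Z = 0)),
               "denominator")
})

test_that("correspondences and models round-trip through files", {
  cs <- random_camera_correspondences(seed = 12)
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(cs, f)
  cs2 <- read_correspondences(f)
  expect_equal(as.data.frame(cs2), as.data.frame(cs), tolerance = 1e-12)
  model <- solve_dlt(cs)
  j <- withr::local_tempfile(fileext = ".json")
  write_dlt_model(model, j)
  vals <- jsonlite::read_json(j)
  expect_equal(vals$l1, unname(model$l["l1"]), tolerance = 1e-12)
  expect_equal(vals$n, nrow(cs))
})
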