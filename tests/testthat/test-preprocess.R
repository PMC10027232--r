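test_that("the single far outlier is removed and only it", {
  pc <- withr::with_seed(1, point_cloud(
    x = c(rnorm(100, 0, 1), 100), y = c(rnorm(100, 0, 1), 0),
    z = c(rnorm(100, 0, 1), 0)))
  pc$label <- c(rep(1L, 100), 9L)
  out <- statistical_outlier_removal(pc, k = 10, std_ratio = 1)
  expect_equal(nrow(out), 100)
  expect_false(9L %in% out$label)
  rep <- filter_report(out)
  expect_equal(rep$points_before, 101)
  expect_equal(rep$points_after, 100)
})

test_that("an unreachable threshold removes nothing", {
  pc <- random_cloud(500, seed = 2)
  out <- statistical_outlier_removal(pc, k = 5, std_ratio = 1e9)
  expect_equal(nrow(out), 500)
})

test_that("removal count is non-increasing in std_ratio", {
  pc <- random_cloud(800, seed = 3)
  counts <- vapply(c(0.5, 1, 2, 4), function(sr)
    nrow(statistical_outlier_removal(pc, k = 8, std_ratio = sr)),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("mean kNN distances match a brute-force oracle", {
  for (s in 1:3) {
    pc <- random_cloud(400, seed = 100 + s, lim = 10)
    ours <- phenocloud:::cpp_knn_mean_dist(cbind(pc$x, pc$y, pc$z), 6L)
    expect_equal(ours, oracle_knn_mean_dist(pc, 6), tolerance = 1e-9)
  }
})

test_that("k must be smaller than the cloud", {
  pc <- random_cloud(5, seed = 4)
  expect_error(statistical_outlier_removal(pc, k = 10), "smaller")
  expect_error(statistical_outlier_removal(pc, k = 0), "at least 1")
})

test_that("voxel down-sampling keeps separated points and merges close ones", {
  corners <- expand.grid(x = c(0, 2), y = c(0, 2), z = c(0, 2))
  pc <- point_cloud(corners$x, corners$y, corners$z)
  expect_equal(nrow(voxel_downsample(pc, 1)), 8)

  clump <- withr::with_seed(5, point_cloud(runif(100, 0, 0.9),
                                           runif(100, 0, 0.9),
                                           runif(100, 0, 0.9)))
  out <- voxel_downsample(clump, 1)
  expect_equal(nrow(out), 1)
  expect_equal(out$x, mean(clump$x), tolerance = 1e-12)

  two <- point_cloud(c(0.1, 0.4), c(0, 0), c(0, 0))
  expect_equal(voxel_downsample(two, 1)$x, 0.25)
})

test_that("voxel output equals the brute-force oracle", {
  for (s in 1:5) {
    pc <- random_cloud(2000, seed = 200 + s)
    for (edge in c(0.5, 2, 7)) {
      out <- voxel_downsample(pc, edge)
      expect_equal(sorted_matrix(out), unname(oracle_voxel(pc, edge)),
                   tolerance = 1e-9)
    }
  }
})

test_that("every voxel centroid lies inside its half-open box", {
  pc <- random_cloud(3000, seed = 6)
  edge <- 1.7
  out <- voxel_downsample(pc, edge)
  mins <- c(min(pc$x), min(pc$y), min(pc$z))
  for (d in 1:3) {
    v <- list(out$x, out$y, out$z)[[d]]
    idx <- floor((v - mins[d]) / edge)
    expect_true(all(v >= mins[d] + idx * edge - 1e-9))
    expect_true(all(v < mins[d] + (idx + 1) * edge + 1e-9))
  }
})

test_that("majority labels survive voxel pooling", {
  pc <- point_cloud(x = c(0.1, 0.2, 0.3, 5), y = 0, z = 0,
                    label = c(1, 1, 2, 3))
  out <- voxel_downsample(pc, 1)
  expect_equal(sort(out$label), c(1L, 3L))
  # tie goes to the smallest id
  tie <- point_cloud(x = c(0.1, 0.2), y = 0, z = 0, label = c(7, 4))
  expect_equal(voxel_downsample(tie, 1)$label, 4L)
})

test_that("compression summaries follow the report", {
  expect_equal(compression_summary(
    tibble::tibble(points_before = 100, points_after = 36)), 36)
  expect_equal(compression_summary(
    tibble::tibble(points_before = 14685679, points_after = 521477)),
    3.5509, tolerance = 1e-4)
  expect_error(compression_summary(
    tibble::tibble(points_before = 0, points_after = 0)), "empty")
  expect_error(voxel_downsample(random_cloud(10, 7), 0), "positive")
})
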