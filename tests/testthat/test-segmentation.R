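test_that("plot assignment uses half-open rectangles", {
  pm <- tibble::tibble(plot_id = c(1, 2), variety = c("A", "B"),
                       xmin = c(0, 100), xmax = c(100, 200),
                       ymin = 0, ymax = 100)
  pc <- point_cloud(x = c(50, 100, 150, 250), y = c(10, 10, 10, 10),
                    z = 0)
  out <- assign_plots(pc, pm)
  # x = 100 is xmax of plot 1 and xmin of plot 2: belongs to plot 2
  expect_equal(out$plot_id, c(1L, 2L, 2L, 0L))
})

test_that("synthetic per-plot counts match the generator bookkeeping", {
  sc <- scene_spec(n_rows = 1, n_cols = 2, plant_spacing = 100,
                   noise_sd = 0, ground_roughness = 0, n_outliers = 0,
                   seed = 1)
  scn <- generate_scene(sc)
  pm <- tibble::tibble(plot_id = c(1, 2), variety = "V",
                       xmin = c(-50, 50), xmax = c(50, 150),
                       ymin = -50, ymax = 50)
  plant_pts <- scn$cloud[scn$truth$labels$role == "plant", ]
  inst <- scn$truth$labels$instance[scn$truth$labels$role == "plant"]
  out <- assign_plots(plant_pts, pm)
  # every point of plant 1 is in plot 1, plant 2 in plot 2 (leaves may
  # overhang; compare majority assignment)
  majority <- vapply(split(out$plot_id, inst), function(v)
    as.integer(names(which.max(table(v)))), integer(1))
  expect_equal(unname(majority), c(1L, 2L))
})

test_that("two separated plants give exactly two matching instances", {
  ps1 <- random_plant_spec(1)
  ps2 <- random_plant_spec(2)
  pc1 <- generate_plant(ps1, seed = 11)
  pc2 <- generate_plant(ps2, seed = 12)
  pc2$x <- pc2$x + 120
  pc <- as_point_cloud(rbind(pc1[, c("x", "y", "z")],
                             pc2[, c("x", "y", "z")]))
  seg <- segment_plants(pc, cell_size = 5, min_points = 50)
  inst <- plant_instances(seg)
  expect_equal(nrow(inst), 2)
  # index sets match the construction: instance split at the row boundary
  expect_equal(sort(unique(seg$instance[seq_len(nrow(pc1))])),
               seg$instance[1])
  expect_equal(sort(unique(seg$instance[nrow(pc1) + seq_len(nrow(pc2))])),
               seg$instance[nrow(pc1) + 1])
  # stem bases land near the true stem positions
  expect_lt(min(abs(inst$base_x - 0)), 2)
  expect_lt(min(abs(inst$base_x - 120)), 2)
})

test_that("one plant is one instance and empty clouds are empty lists", {
  pc <- generate_plant(random_plant_spec(3), seed = 13)
  seg <- segment_plants(as_point_cloud(pc[, c("x", "y", "z")]),
                        cell_size = 5, min_points = 50)
  expect_equal(nrow(plant_instances(seg)), 1)
  expect_true(all(seg$instance == 1L))

  empty <- segment_plants(point_cloud(), 5, 50)
  expect_equal(nrow(plant_instances(empty)), 0)
})

test_that("instances partition the retained points", {
  pc <- withr::with_seed(4, {
    a <- generate_plant(random_plant_spec(4))
    b <- generate_plant(random_plant_spec(5))
    b$x <- b$x + 90
    dust <- point_cloud(runif(10, 30, 60), runif(10, 200, 230),
                        runif(10, 0, 5))
    as_point_cloud(rbind(a[, c("x", "y", "z")], b[, c("x", "y", "z")],
                         as.data.frame(dust)))
  })
  seg <- segment_plants(pc, cell_size = 5, min_points = 50)
  inst <- plant_instances(seg)
  expect_equal(nrow(inst), 2)
  expect_equal(sum(seg$instance > 0), sum(inst$n_points))
  expect_equal(sum(seg$instance == 0), 10)  # dust discarded, not dropped
  expect_equal(nrow(seg), nrow(pc))
})

test_that("touching canopies trigger the span warning", {
  a <- generate_plant(random_plant_spec(6), seed = 14)
  b <- generate_plant(random_plant_spec(7), seed = 15)
  b$x <- b$x + 10  # overlapping
  pc <- as_point_cloud(rbind(a[, c("x", "y", "z")], b[, c("x", "y", "z")]))
  expect_warning(segment_plants(pc, cell_size = 5, min_points = 50,
                                plant_spacing = 10), "touching")
  expect_error(segment_plants(pc, cell_size = 0), "positive")
})
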