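# shared brute-force oracles and generators for the test suite

# random point cloud in a box
random_cloud <- function(n, seed, lim = 50) {
  withr::with_seed(seed, point_cloud(
    x = runif(n, -lim, lim), y = runif(n, -lim, lim), z = runif(n, 0, lim)))
}

# brute-force voxel down-sampling oracle: hash integer voxel indices,
# average per bucket
oracle_voxel <- function(cloud, edge) {
  mins <- c(min(cloud$x), min(cloud$y), min(cloud$z))
  ix <- floor((cloud$x - mins[1]) / edge)
  iy <- floor((cloud$y - mins[2]) / edge)
  iz <- floor((cloud$z - mins[3]) / edge)
  key <- paste(ix, iy, iz)
  xs <- tapply(cloud$x, key, mean)
  ys <- tapply(cloud$y, key, mean)
  zs <- tapply(cloud$z, key, mean)
  m <- cbind(as.numeric(xs), as.numeric(ys), as.numeric(zs))
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

sorted_matrix <- function(cloud) {
  m <- cbind(cloud$x, cloud$y, cloud$z)
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# brute-force mean kNN distance
oracle_knn_mean_dist <- function(cloud, k) {
  m <- cbind(cloud$x, cloud$y, cloud$z)
  d <- as.matrix(stats::dist(m))
  vapply(seq_len(nrow(m)), function(i) {
    mean(sort(d[i, -i])[seq_len(k)])
  }, numeric(1))
}

# uniform points on a sphere surface
sphere_points <- function(n, center, radius, seed = NULL) {
  gen <- function() {
    u <- runif(n, -1, 1)
    phi <- runif(n, 0, 2 * pi)
    r_xy <- sqrt(pmax(0, 1 - u^2))
    point_cloud(x = center[1] + radius * r_xy * cos(phi),
                y = center[2] + radius * r_xy * sin(phi),
                z = center[3] + radius * u)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# project 3D points through a random full-rank pinhole camera and return
# DLT-style correspondences
random_camera_correspondences <- function(seed, n_extra = 4) {
  withr::with_seed(seed, {
    obj <- rbind(as.matrix(expand.grid(X = c(0, 40), Y = c(0, 40),
                                       Z = c(0, 40))),
                 matrix(runif(3 * n_extra, 5, 35), ncol = 3,
                        dimnames = list(NULL, c("X", "Y", "Z"))))
    f <- runif(1, 800, 1600)
    cx <- runif(1, 300, 700); cy <- runif(1, 200, 500)
    kmat <- matrix(c(f, 0, cx, 0, f, cy, 0, 0, 1), 3, 3, byrow = TRUE)
    ax <- runif(3, -0.3, 0.3)
    rx <- matrix(c(1, 0, 0, 0, cos(ax[1]), -sin(ax[1]),
                   0, sin(ax[1]), cos(ax[1])), 3, 3, byrow = TRUE)
    ry <- matrix(c(cos(ax[2]), 0, sin(ax[2]), 0, 1, 0,
                   -sin(ax[2]), 0, cos(ax[2])), 3, 3, byrow = TRUE)
    rz <- matrix(c(cos(ax[3]), -sin(ax[3]), 0, sin(ax[3]), cos(ax[3]), 0,
                   0, 0, 1), 3, 3, byrow = TRUE)
    rot <- rx %*% ry %*% rz
    tvec <- c(runif(2, -20, 20), runif(1, 150, 250))
    p <- kmat %*% cbind(rot, tvec)
    ph <- p %*% t(cbind(obj, 1))
    tibble::tibble(x = ph[1, ] / ph[3, ], y = ph[2, ] / ph[3, ],
                   X = obj[, 1], Y = obj[, 2], Z = obj[, 3])
  })
}
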