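#' RANSAC soil-plane fit
#'
#' Random-sampling-consensus plane fitting: minimal samples of 3 points are
#' drawn for the stated number of iterations; the plane with the largest
#' inlier consensus (|signed distance| <= `distance_threshold`) wins and is
#' refit by total least squares (smallest principal direction) on its
#' inliers. The normal is oriented with a positive Z component.
#'
#' @param cloud A point-cloud data frame with at least 3 points.
#' @param distance_threshold Inlier distance threshold in cm (default 1).
#' @param iterations Number of random samples (default 1000).
#' @param seed Optional integer seed for the sampler.
#' @return An object of class `plane_model`: unit `normal`, offset `d`
#'   (so that `normal . p + d = 0` on the plane), `inliers` (row indices)
#'   and the inlier RMS distance (cm).
#' @export
ransac_plane <- function(cloud, distance_threshold = 1, iterations = 1000,
                         seed = NULL) {
  cloud <- as_point_cloud(cloud)
  if (nrow(cloud) < 3) abort("plane fitting needs at least 3 points.")
  if (distance_threshold <= 0) abort("distance threshold must be positive.")
  run <- function() ransac_plane_impl(pc_matrix(cloud), distance_threshold,
                                      iterations)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

ransac_plane_impl <- function(p, thr, iterations) {
  n <- nrow(p)
  best_count <- -1L
  best_nrm <- NULL
  best_d <- NA_real_
  attempts_left <- iterations * 10  # guard against all-collinear sampling
  it <- 0
  while (it < iterations && attempts_left > 0) {
    attempts_left <- attempts_left - 1
    idx <- sample.int(n, 3)
    v1 <- p[idx[2], ] - p[idx[1], ]
    v2 <- p[idx[3], ] - p[idx[1], ]
    nrm <- c(v1[2] * v2[3] - v1[3] * v2[2],
             v1[3] * v2[1] - v1[1] * v2[3],
             v1[1] * v2[2] - v1[2] * v2[1])
    len <- sqrt(sum(nrm^2))
    if (len < 1e-12) next  # collinear sample
    it <- it + 1
    nrm <- nrm / len
    d <- -sum(nrm * p[idx[1], ])
    count <- sum(abs(p %*% nrm + d) <= thr)
    if (count > best_count) {
      best_count <- count
      best_nrm <- nrm
      best_d <- d
    }
  }
  if (is.null(best_nrm)) {
    abort("all RANSAC samples were collinear; cannot fit a plane.")
  }
  inl <- which(abs(p %*% best_nrm + best_d) <= thr)
  # total least-squares refit on the consensus set
  if (length(inl) >= 3) {
    q <- p[inl, , drop = FALSE]
    ctr <- colMeans(q)
    ev <- eigen(crossprod(sweep(q, 2, ctr)), symmetric = TRUE)
    nrm <- ev$vectors[, 3]
    d <- -sum(nrm * ctr)
    inl <- which(abs(p %*% nrm + d) <= thr)
  } else {
    nrm <- best_nrm
    d <- best_d
  }
  if (nrm[3] < 0) {
    nrm <- -nrm
    d <- -d
  }
  dist <- as.numeric(p[inl, , drop = FALSE] %*% nrm + d)
  structure(list(normal = setNames(nrm, c("x", "y", "z")), d = d,
                 inliers = inl, rms = sqrt(mean(dist^2)),
                 n_inliers = length(inl), n = n),
            class = "plane_model")
}

#' @export
print.plane_model <- function(x, ...) {
  cat(sprintf(
    "Plane: normal (%.4f, %.4f, %.4f), d = %.3f; %d/%d inliers, RMS %.3f cm\n",
    x$normal[1], x$normal[2], x$normal[3], x$d, x$n_inliers, x$n, x$rms))
  invisible(x)
}

#' @export
tidy.plane_model <- function(x, ...) {
  tibble::tibble(normal_x = x$normal[["x"]], normal_y = x$normal[["y"]],
                 normal_z = x$normal[["z"]], d = x$d,
                 n_inliers = x$n_inliers, n = x$n, rms = x$rms)
}

#' Level a scene on its fitted soil plane
#'
#' Applies the rigid transform that rotates the plane normal onto +Z (about
#' the axis normal x z, through the centroid of the plane's projection) and
#' translates the plane to Z = 0. Pairwise distances are preserved exactly.
#'
#' @param cloud A point-cloud data frame.
#' @param plane A [ransac_plane()] result (or any list with unit `normal`
#'   and offset `d`).
#' @return The leveled cloud, with the `leveling_transform` (rotation 3x3
#'   and translation 3-vector) attached as an attribute; retrieve it with
#'   [leveling_transform()].
#' @export
level_scene <- function(cloud, plane) {
  cloud <- as_point_cloud(cloud)
  nrm <- unname(plane$normal)
  nrm <- nrm / sqrt(sum(nrm^2))
  rot <- rotation_to_z(nrm)
  p <- pc_matrix(cloud)
  q <- p %*% t(rot)
  # after rotation the plane is z = -d (for unit normal), shift it to 0
  tz <- plane$d
  q[, 3] <- q[, 3] + tz
  out <- cloud
  out$x <- q[, 1]; out$y <- q[, 2]; out$z <- q[, 3]
  attr(out, "leveling_transform") <- list(rotation = rot,
                                          translation = c(0, 0, tz))
  out
}

#' Retrieve the rigid transform attached by [level_scene()]
#'
#' @param cloud A cloud returned by [level_scene()].
#' @return A list with `rotation` (3x3 orthonormal, det +1) and
#'   `translation` (3-vector, cm).
#' @export
leveling_transform <- function(cloud) {
  tr <- attr(cloud, "leveling_transform")
  if (is.null(tr)) abort("no leveling transform attached to this cloud.")
  tr
}

# proper rotation taking unit vector n onto (0, 0, 1) (Rodrigues)
rotation_to_z <- function(n) {
  z <- c(0, 0, 1)
  v <- c(n[2] * z[3] - n[3] * z[2],
         n[3] * z[1] - n[1] * z[3],
         n[1] * z[2] - n[2] * z[1])
  s <- sqrt(sum(v^2))
  c_ <- sum(n * z)
  if (s < 1e-15) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # 180 deg flip about X
  }
  vx <- matrix(c(0, -v[3], v[2],
                 v[3], 0, -v[1],
                 -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

#' Remove ground points
#'
#' Points on or below the plane, and within `margin` above it, are removed;
#' points more than `margin` above the plane are retained with all per-point
#' columns intact. When `plane` is NULL the cloud is assumed leveled and the
#' plane Z = 0 is used.
#'
#' @param cloud A point-cloud data frame.
#' @param plane A [ransac_plane()] result, or NULL for a leveled cloud.
#' @param margin Height band above the plane that is still treated as soil
#'   (cm, >= 0; default 1).
#' @return The cloud restricted to above-ground points, with the removal
#'   indices attached as attribute `ground_indices`.
#' @export
remove_ground <- function(cloud, plane = NULL, margin = 1) {
  if (margin < 0) abort("margin must be non-negative.")
  cloud <- as_point_cloud(cloud)
  height <- if (is.null(plane)) {
    cloud$z
  } else {
    as.numeric(pc_matrix(cloud) %*% unname(plane$normal) + plane$d)
  }
  keep <- height > margin
  out <- cloud[keep, , drop = FALSE]
  attr(out, "ground_indices") <- which(!keep)
  out
}
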