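#' Least-squares sphere fit
#'
#' Fits a sphere to a point set by the algebraic linear least-squares solve,
#' then refines centre and radius by Gauss-Newton on the geometric distance
#' residuals (at most 50 iterations, tolerance 1e-10). Used to verify the
#' scanned size of the calibration spheres (25 cm and 20 cm diameter targets)
#' placed in the field.
#'
#' @param cloud A point-cloud data frame with at least 4 non-coplanar points.
#' @param refine Run the Gauss-Newton geometric refinement (default TRUE).
#' @return An object of class `sphere_fit`: centre (cm), radius (cm), RMS
#'   residual (cm), and the point count used.
#' @export
fit_sphere <- function(cloud, refine = TRUE) {
  p <- pc_matrix(as_point_cloud(cloud))
  n <- nrow(p)
  if (n < 4) abort("insufficient points: sphere fitting needs at least 4.")
  a <- cbind(2 * p, 1)
  b <- rowSums(p^2)
  qr_a <- qr(a)
  if (qr_a$rank < 4) {
    abort("degenerate configuration: points are coplanar or coincident.")
  }
  sol <- qr.coef(qr_a, b)
  center <- sol[1:3]
  radius <- sqrt(sol[4] + sum(center^2))
  if (!is.finite(radius) || radius <= 0) {
    abort("degenerate configuration: algebraic fit produced no sphere.")
  }
  if (refine) {
    theta <- c(center, radius)
    for (it in seq_len(50)) {
      d <- sqrt(rowSums((p - matrix(theta[1:3], n, 3, byrow = TRUE))^2))
      res <- d - theta[4]
      jac <- cbind(-(p - matrix(theta[1:3], n, 3, byrow = TRUE)) / d, -1)
      step <- tryCatch(qr.solve(jac, -res), error = function(e) rep(0, 4))
      theta <- theta + step
      if (sqrt(sum(step^2)) < 1e-10) break
    }
    center <- theta[1:3]
    radius <- theta[4]
  }
  d <- sqrt(rowSums((p - matrix(center, n, 3, byrow = TRUE))^2))
  structure(list(center = setNames(unname(center), c("x", "y", "z")),
                 radius = unname(radius),
                 rms = unname(sqrt(mean((d - radius)^2))),
                 n = n),
            class = "sphere_fit")
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf(
    "Sphere fit: centre (%.3f, %.3f, %.3f) cm, radius %.4f cm, RMS %.2e cm, n = %d\n",
    x$center[1], x$center[2], x$center[3], x$radius, x$rms, x$n))
  invisible(x)
}

#' @export
tidy.sphere_fit <- function(x, ...) {
  tibble::tibble(center_x = x$center[["x"]], center_y = x$center[["y"]],
                 center_z = x$center[["z"]], radius = x$radius,
                 diameter = 2 * x$radius, rms = x$rms, n = x$n)
}

#' Global scale calibration from sphere targets
#'
#' Combines fitted and known sphere diameters into a single dimensionless
#' scale factor (mean over spheres of known/fitted diameter). Applying the
#' factor to the fitted diameters reproduces the known ones exactly in the
#' noiseless case.
#'
#' @param fits A list of [fit_sphere()] results, or a numeric vector of
#'   fitted diameters (cm).
#' @param known_diameters Numeric vector of true target diameters (cm), same
#'   length as `fits`.
#' @return An object of class `scale_calibration` with fields `scale` and a
#'   per-sphere `table`.
#' @export
calibrate_scale <- function(fits, known_diameters) {
  fitted <- if (is.numeric(fits)) fits else
    vapply(fits, function(f) 2 * f$radius, numeric(1))
  if (length(fitted) == 0) abort("at least one sphere fit is required.")
  if (length(fitted) != length(known_diameters)) {
    abort("`fits` and `known_diameters` must have the same length.")
  }
  if (any(fitted <= 0)) abort("fitted diameters must be positive.")
  ratios <- known_diameters / fitted
  structure(list(scale = mean(ratios),
                 table = tibble::tibble(known_diameter = known_diameters,
                                        fitted_diameter = fitted,
                                        ratio = ratios)),
            class = "scale_calibration")
}

#' @export
print.scale_calibration <- function(x, ...) {
  cat(sprintf("Scale calibration: factor %.6f over %d sphere(s)\n",
              x$scale, nrow(x$table)))
  invisible(x)
}

#' @export
tidy.scale_calibration <- function(x, ...) x$table

#' @export
glance.scale_calibration <- function(x, ...) {
  tibble::tibble(scale = x$scale, n_spheres = nrow(x$table))
}

#' Apply a scale calibration to a cloud
#'
#' Coordinates are multiplied by the scale factor about the cloud centroid
#' (diameter-only targets cannot fix a datum, so the centroid is kept).
#'
#' @param cloud A point-cloud data frame.
#' @param calibration A [calibrate_scale()] result or a bare numeric factor.
#' @return The rescaled point cloud.
#' @export
apply_scale <- function(cloud, calibration) {
  s <- if (is.numeric(calibration)) calibration else calibration$scale
  cloud <- as_point_cloud(cloud)
  ctr <- c(mean(cloud$x), mean(cloud$y), mean(cloud$z))
  cloud$x <- ctr[1] + s * (cloud$x - ctr[1])
  cloud$y <- ctr[2] + s * (cloud$y - ctr[2])
  cloud$z <- ctr[3] + s * (cloud$z - ctr[3])
  cloud
}

# ---- DLT -------------------------------------------------------------------

#' Solve the 11-parameter direct linear transformation
#'
#' Registers 2D image coordinates against 3D point-cloud coordinates with
#' the 11-parameter DLT model
#' \deqn{x + (l_1 X + l_2 Y + l_3 Z + l_4)/(l_9 X + l_{10} Y + l_{11} Z + 1) = 0}
#' (and analogously for y with l5..l8). Parameters are solved by linear
#' least squares on the homogeneous system obtained by clearing
#' denominators, after Hartley-style centring/scaling of both coordinate
#' sets for conditioning (undone afterwards).
#'
#' @param correspondences Data frame with columns `x`, `y` (image, pixels)
#'   and `X`, `Y`, `Z` (object, cm); at least 6 rows, object points not all
#'   coplanar.
#' @return An object of class `dlt_model` with the parameter vector
#'   `l` (l1..l11) and the reprojection RMS in pixels.
#' @export
solve_dlt <- function(correspondences) {
  needed <- c("x", "y", "X", "Y", "Z")
  if (!all(needed %in% names(correspondences))) {
    abort("correspondences need columns x, y, X, Y, Z.")
  }
  cs <- tibble::as_tibble(correspondences)
  if (any(!is.finite(as.matrix(cs[, needed])))) {
    abort("correspondences contain non-finite values.")
  }
  n <- nrow(cs)
  if (n < 6) abort("at least 6 correspondences are required.")
  obj <- as.matrix(cs[, c("X", "Y", "Z")])
  img <- as.matrix(cs[, c("x", "y")])

  # coplanarity check on the object points
  oc <- scale(obj, center = TRUE, scale = FALSE)
  sv <- svd(oc)$d
  if (sv[3] < 1e-8 * max(sv[1], 1)) {
    abort("degenerate configuration: object points are (nearly) coplanar.")
  }

  # normalization transforms
  t_obj <- norm_transform(obj)
  t_img <- norm_transform(img)
  on <- t(t_obj %*% t(cbind(obj, 1)))
  im <- t(t_img %*% t(cbind(img, 1)))

  rows <- matrix(0, 2 * n, 12)
  for (i in seq_len(n)) {
    xt <- on[i, ]
    rows[2 * i - 1, ] <- c(xt, 0, 0, 0, 0, -im[i, 1] * xt)
    rows[2 * i, ] <- c(0, 0, 0, 0, xt, -im[i, 2] * xt)
  }
  v <- svd(rows, nu = 0)$v
  p_norm <- matrix(v[, 12], 3, 4, byrow = TRUE)
  p <- solve(t_img) %*% p_norm %*% t_obj
  if (abs(p[3, 4]) < 1e-12 * max(abs(p))) {
    abort("degenerate configuration: DLT normalization term vanishes.")
  }
  p <- p / p[3, 4]
  l <- c(-p[1, ], -p[2, ], p[3, 1:3])
  names(l) <- paste0("l", 1:11)
  model <- structure(list(l = l, rms = NA_real_, n = n), class = "dlt_model")
  proj <- project_dlt(model, cs)
  model$rms <- sqrt(mean((proj$x - cs$x)^2 + (proj$y - cs$y)^2))
  model
}

# similarity transform centring points and scaling mean norm to sqrt(dim)
norm_transform <- function(pts) {
  d <- ncol(pts)
  ctr <- colMeans(pts)
  dev <- sweep(pts, 2, ctr)
  ms <- mean(sqrt(rowSums(dev^2)))
  s <- if (ms > 0) sqrt(d) / ms else 1
  t_mat <- diag(c(rep(s, d), 1))
  t_mat[seq_len(d), d + 1] <- -s * ctr
  t_mat
}

#' @export
print.dlt_model <- function(x, ...) {
  cat(sprintf("DLT model (11 parameters), reprojection RMS %.3e px, n = %d\n",
              x$rms, x$n))
  invisible(x)
}

#' @export
tidy.dlt_model <- function(x, ...) {
  tibble::tibble(term = names(x$l), estimate = unname(x$l))
}

#' @export
glance.dlt_model <- function(x, ...) {
  tibble::tibble(rms_px = x$rms, n_correspondences = x$n)
}

#' Project object points through a DLT model
#'
#' Forward evaluation of the registration model:
#' `x = -(l1 X + l2 Y + l3 Z + l4) / (l9 X + l10 Y + l11 Z + 1)` and
#' analogously for `y` with l5..l8.
#'
#' @param model A [solve_dlt()] result.
#' @param object_points Data frame with columns `X`, `Y`, `Z` (cm).
#' @return A tibble with projected image columns `x`, `y` (pixels).
#' @export
project_dlt <- function(model, object_points) {
  stopifnot(inherits(model, "dlt_model"))
  if (!all(c("X", "Y", "Z") %in% names(object_points))) {
    abort("object points need columns X, Y, Z.")
  }
  l <- model$l
  xm <- as.matrix(object_points[, c("X", "Y", "Z")])
  den <- xm %*% l[9:11] + 1
  if (any(abs(den) < 1e-12)) {
    abort("vanishing DLT denominator at one or more points.")
  }
  tibble::tibble(
    x = as.numeric(-(xm %*% l[1:3] + l[4]) / den),
    y = as.numeric(-(xm %*% l[5:7] + l[8]) / den))
}

#' Read 2D-3D correspondences
#'
#' @param path CSV with header `x,y,X,Y,Z` (image pixels, object cm).
#' @return A tibble.
#' @export
read_correspondences <- function(path) {
  cs <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("x", "y", "X", "Y", "Z") %in% names(cs))) {
    abort("correspondence CSV must have header x,y,X,Y,Z.")
  }
  cs
}

#' Serialize a DLT model to JSON
#'
#' @param model A `dlt_model`.
#' @param path Destination JSON file.
#' @return `path`, invisibly.
#' @export
write_dlt_model <- function(model, path) {
  jsonlite::write_json(c(as.list(model$l), list(rms = model$rms, n = model$n)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
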