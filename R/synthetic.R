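#' Leaf specification
#'
#' Describes one idealized maize leaf. The midrib is a constant-curvature
#' (circular-arc) curve in the vertical plane through the leaf azimuth: its
#' tangent starts at `inclination` degrees above the horizontal and rotates
#' downward linearly with arc length, by `arch` quarter-turns (90 deg) in
#' total from base to tip. The blade is a ruled strip around the midrib whose
#' width tapers linearly from 20% of `width` at the base to `width` at one
#' third of the length and down to zero at the tip. Leaf length (midrib arc
#' length), maximum width, base inclination and growth height are therefore
#' analytically known ground truth.
#'
#' @param growth_height Height on the stem where the leaf attaches (cm).
#' @param azimuth Compass direction of the leaf in the XY plane (degrees).
#' @param length Midrib arc length (cm).
#' @param width Maximum blade width (cm); must be smaller than `length`.
#' @param inclination Midrib base tangent angle above the horizontal
#'   (degrees, in `[0, 90]`).
#' @param arch Droop of the midrib: fraction of a quarter turn the tangent
#'   rotates from base to tip (dimensionless, >= 0).
#' @return A one-row tibble (vectorized inputs give one row per leaf).
#' @export
leaf_spec <- function(growth_height, azimuth, length, width, inclination,
                      arch = 0.2) {
  spec <- tibble::tibble(growth_height = growth_height, azimuth = azimuth,
                         length = length, width = width,
                         inclination = inclination, arch = arch)
  if (any(spec$length <= spec$width) || any(spec$width <= 0)) {
    abort("leaf spec requires length > width > 0.")
  }
  if (any(spec$inclination < 0 | spec$inclination > 90)) {
    abort("leaf inclination must lie in [0, 90] degrees.")
  }
  spec
}

#' Plant specification
#'
#' @param height Plant height: vertical distance from stem base to stem tip
#'   (cm).
#' @param base_x,base_y Stem base position (cm).
#' @param base_z Ground elevation at the stem base (cm).
#' @param stem_radius Stem cylinder radius (cm).
#' @param leaves A tibble of [leaf_spec()] rows (or NULL for a leafless
#'   stem). All leaf growth heights must be below `height`.
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(height, base_x = 0, base_y = 0, base_z = 0,
                       stem_radius = 1, leaves = NULL) {
  if (height <= 0) abort("plant height must be positive.")
  if (!is.null(leaves) && nrow(leaves) > 0 &&
      any(leaves$growth_height >= height)) {
    abort("leaf growth heights must be below the plant height.")
  }
  structure(list(height = height, base_x = base_x, base_y = base_y,
                 base_z = base_z, stem_radius = stem_radius,
                 leaves = leaves),
            class = "plant_spec")
}

# constant-curvature midrib: arc-length parametrization, base at origin.
# returns horizontal run u(s), vertical rise v(s) for s in [0, length]
midrib_curve <- function(s, length, inclination, arch) {
  psi0 <- inclination * pi / 180
  kappa <- arch * (pi / 2) / length
  if (abs(kappa) < 1e-12) {
    list(u = s * cos(psi0), v = s * sin(psi0))
  } else {
    list(u = (sin(psi0) - sin(psi0 - kappa * s)) / kappa,
         v = (cos(psi0 - kappa * s) - cos(psi0)) / kappa)
  }
}

# blade half-width at relative arc position r in [0, 1]
leaf_taper <- function(r, width) {
  peak <- 1 / 3
  w <- ifelse(r <= peak,
              0.2 + 0.8 * r / peak,
              (1 - r) / (1 - peak))
  width * pmax(w, 0)
}

#' Sample a point cloud from a plant specification
#'
#' The stem is sampled as a vertical cylinder of rings from the base to
#' exactly `spec$height` (so the noiseless maximum Z equals base Z + height).
#' Each leaf is sampled uniformly over its ruled strip by rejection from the
#' bounding rectangle of the (arc length, lateral offset) parameter plane.
#'
#' @param spec A [plant_spec()].
#' @param density Target surface sampling density (points per square cm).
#' @param noise_sd Isotropic Gaussian noise added to each coordinate (cm).
#' @param seed Optional integer; fixes the sampled cloud exactly.
#' @return A [point_cloud()] tibble with extra columns `part` ("stem" or
#'   "leaf") and `leaf_id` (NA for stem points).
#' @export
generate_plant <- function(spec, density = 4, noise_sd = 0, seed = NULL) {
  if (density <= 0) abort("point density must be positive.")
  gen <- function() generate_plant_impl(spec, density, noise_sd)
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

generate_plant_impl <- function(spec, density, noise_sd) {
  step <- 1 / sqrt(density)
  # stem rings
  n_h <- max(2L, floor(spec$height / step) + 1L)
  hs <- seq(0, spec$height, length.out = n_h)
  n_ang <- max(3L, round(2 * pi * spec$stem_radius / step))
  parts <- list()
  ang0 <- runif(n_h, 0, 2 * pi)
  ang <- rep(seq(0, 2 * pi, length.out = n_ang + 1)[-(n_ang + 1)],
             times = n_h) + rep(ang0, each = n_ang)
  stem <- tibble::tibble(
    x = spec$base_x + spec$stem_radius * cos(ang),
    y = spec$base_y + spec$stem_radius * sin(ang),
    z = spec$base_z + rep(hs, each = n_ang),
    part = "stem", leaf_id = NA_integer_)
  parts[[1]] <- stem

  leaves <- spec$leaves
  if (!is.null(leaves) && nrow(leaves) > 0) {
    for (i in seq_len(nrow(leaves))) {
      lf <- leaves[i, ]
      if (lf$growth_height + lf$length * sin(lf$inclination * pi / 180) >
          spec$height + 1e-9) {
        warn("leaf may rise above the stem tip; plant-height ground truth may be exceeded.")
      }
      az <- lf$azimuth * pi / 180
      e_r <- c(cos(az), sin(az))
      e_t <- c(-sin(az), cos(az))
      n_try <- max(10L, ceiling(2.2 * density * lf$length * lf$width))
      s <- runif(n_try, 0, lf$length)
      t <- runif(n_try, -lf$width / 2, lf$width / 2)
      keep <- abs(t) <= leaf_taper(s / lf$length, lf$width) / 2
      s <- s[keep]; t <- t[keep]
      mc <- midrib_curve(s, lf$length, lf$inclination, lf$arch)
      u <- spec$stem_radius + mc$u
      parts[[length(parts) + 1]] <- tibble::tibble(
        x = spec$base_x + u * e_r[1] + t * e_t[1],
        y = spec$base_y + u * e_r[2] + t * e_t[2],
        z = spec$base_z + lf$growth_height + mc$v,
        part = "leaf", leaf_id = i)
    }
  }
  cloud <- dplyr::bind_rows(parts)
  if (noise_sd > 0) {
    n <- nrow(cloud)
    cloud$x <- cloud$x + rnorm(n, 0, noise_sd)
    cloud$y <- cloud$y + rnorm(n, 0, noise_sd)
    cloud$z <- cloud$z + rnorm(n, 0, noise_sd)
  }
  as_point_cloud(cloud)
}

#' Scene specification for a synthetic maize canopy
#'
#' Defaults emulate a jointing-stage breeding trial: 60 cm row spacing with
#' 28 cm in-row plant spacing (about 60,000 plants/ha), plant heights drawn
#' from 45-92 cm, a gently sloped soil surface, two calibration spheres of
#' 25 cm and 20 cm diameter resting on the soil, isotropic sensor noise and
#' sparse uniform outliers.
#'
#' @param n_rows,n_cols Plant grid dimensions (rows x plants per row).
#' @param plant_spacing In-row spacing between plants (cm).
#' @param row_spacing Spacing between rows (cm).
#' @param ground_slope Soil slope about the X axis (degrees).
#' @param ground_roughness Standard deviation of soil micro-relief (cm).
#' @param noise_sd Sensor noise standard deviation (cm), isotropic Gaussian.
#' @param n_outliers Count of uniform sparse outlier points.
#' @param sphere_diameters Diameters of the calibration spheres (cm).
#' @param density Surface sampling density (points per square cm).
#' @param border Bare-soil border around the plant grid (cm).
#' @param height_range,n_leaves_range,leaf_length_range,leaf_width_range,leaf_incl_range
#'   Ranges the per-plant traits are drawn from.
#' @param arch Leaf midrib arch coefficient (see [leaf_spec()]).
#' @param stem_radius Stem radius (cm).
#' @param seed Integer seed fixing the whole scene.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(n_rows = 2, n_cols = 3, plant_spacing = 28,
                       row_spacing = 60, ground_slope = 2,
                       ground_roughness = 0.1, noise_sd = 0.3,
                       n_outliers = 200, sphere_diameters = c(25, 20),
                       density = 4, border = 40,
                       height_range = c(45, 92), n_leaves_range = c(3, 5),
                       leaf_length_range = c(20, 40),
                       leaf_width_range = c(3.5, 6),
                       leaf_incl_range = c(20, 60), arch = 0.2,
                       stem_radius = 1, seed = 1) {
  if (plant_spacing <= 0 || row_spacing <= 0) {
    abort("plant and row spacing must be positive.")
  }
  if (noise_sd < 0 || ground_roughness < 0) {
    abort("noise and roughness standard deviations must be non-negative.")
  }
  structure(list(
    n_rows = n_rows, n_cols = n_cols, plant_spacing = plant_spacing,
    row_spacing = row_spacing, ground_slope = ground_slope,
    ground_roughness = ground_roughness, noise_sd = noise_sd,
    n_outliers = n_outliers, sphere_diameters = sphere_diameters,
    density = density, border = border, height_range = height_range,
    n_leaves_range = n_leaves_range, leaf_length_range = leaf_length_range,
    leaf_width_range = leaf_width_range, leaf_incl_range = leaf_incl_range,
    arch = arch, stem_radius = stem_radius, seed = seed),
    class = "scene_spec")
}

#' Draw a random single-plant specification
#'
#' Convenience generator for parameter-recovery studies: plant height is
#' drawn from `height_range`, leaves are spread evenly around the stem
#' (with +/-15 degree jitter) at staggered, well-separated growth heights
#' (evenly spaced in 30-75% of the plant height with small jitter), and
#' leaf inclinations are capped so no leaf tip rises above the stem. The
#' staggering guarantees that leaves form disjoint clusters off the stem,
#' the regime leaf segmentation is designed for.
#'
#' @param seed Integer seed fixing the specification.
#' @param n_leaves Number of leaves.
#' @param height_range,length_range,width_range,incl_range Trait ranges.
#' @param arch Midrib arch coefficient.
#' @param stem_radius Stem radius (cm).
#' @return A [plant_spec()].
#' @export
random_plant_spec <- function(seed, n_leaves = 3, height_range = c(45, 92),
                              length_range = c(20, 35),
                              width_range = c(4, 6),
                              incl_range = c(20, 60), arch = 0.2,
                              stem_radius = 1) {
  withr::with_seed(seed, {
    h <- runif(1, height_range[1], height_range[2])
    slots <- (seq_len(n_leaves) - 0.5 + runif(n_leaves, -0.15, 0.15)) /
      n_leaves
    gh <- h * (0.3 + 0.45 * slots)
    az <- (runif(1, 0, 360) + (seq_len(n_leaves) - 1) * 360 / n_leaves +
             runif(n_leaves, -15, 15)) %% 360
    len <- runif(n_leaves, length_range[1], length_range[2])
    wid <- runif(n_leaves, width_range[1], width_range[2])
    # upper leaves are the more erect ones (as in maize); sorting also keeps
    # a steep lower leaf from climbing into its neighbour's attachment zone
    incl <- sort(runif(n_leaves, incl_range[1], incl_range[2]))
    max_sin <- pmax(0.05, (0.95 * h - gh) / len)
    incl <- pmin(incl, asin(pmin(1, max_sin)) * 180 / pi)
    plant_spec(height = h, stem_radius = stem_radius,
               leaves = leaf_spec(gh, az, len, wid, incl, arch))
  })
}

# uniform sample on a sphere surface
sample_sphere <- function(n, center, radius) {
  u <- runif(n, -1, 1)
  phi <- runif(n, 0, 2 * pi)
  r_xy <- sqrt(pmax(0, 1 - u^2))
  tibble::tibble(x = center[1] + radius * r_xy * cos(phi),
                 y = center[2] + radius * r_xy * sin(phi),
                 z = center[3] + radius * u)
}

#' Generate a ground-truthed synthetic canopy scene
#'
#' Builds the soil surface (sloped plane plus Gaussian micro-relief), places
#' vertically growing plants with randomized traits on it, rests the
#' calibration spheres tangent to the plane, adds isotropic sensor noise to
#' all scene points, and appends uniform outliers. Every point receives a
#' ground-truth role and instance id.
#'
#' @param spec A [scene_spec()].
#' @return A list of class `scene` with elements:
#'   \describe{
#'     \item{cloud}{[point_cloud()] with `label` (plant instance id, 0
#'       otherwise).}
#'     \item{truth}{list with `labels` (tibble point_id/role/instance),
#'       `plants` and `leaves` trait tibbles, `plane` (normal, d) of the
#'       noiseless soil plane, and `spheres` (centres/diameters).}
#'   }
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  slope <- spec$ground_slope * pi / 180
  ground_z <- function(y) tan(slope) * y

  # plant grid
  xs <- (seq_len(spec$n_cols) - 1) * spec$plant_spacing
  ys <- (seq_len(spec$n_rows) - 1) * spec$row_spacing
  grid <- expand.grid(x = xs, y = ys)
  n_plants <- nrow(grid)

  xlim <- range(xs) + c(-spec$border, spec$border)
  ylim <- range(ys) + c(-spec$border, spec$border)

  plants <- list(); leaves <- list(); clouds <- list()
  for (p in seq_len(n_plants)) {
    h <- runif(1, spec$height_range[1], spec$height_range[2])
    n_lv <- sample(seq(spec$n_leaves_range[1], spec$n_leaves_range[2]), 1)
    gh <- sort(runif(n_lv, 0.25 * h, 0.8 * h))
    base_az <- runif(1, 0, 360)
    az <- (base_az + 180 * (seq_len(n_lv) - 1) + rnorm(n_lv, 0, 10)) %% 360
    len <- runif(n_lv, spec$leaf_length_range[1], spec$leaf_length_range[2])
    wid <- runif(n_lv, spec$leaf_width_range[1], spec$leaf_width_range[2])
    incl <- runif(n_lv, spec$leaf_incl_range[1], spec$leaf_incl_range[2])
    # keep leaf tips below the stem tip so height ground truth is exact
    max_sin <- pmax(0.05, (0.97 * h - gh) / len)
    incl <- pmin(incl, asin(pmin(1, max_sin)) * 180 / pi)
    lf <- leaf_spec(gh, az, len, wid, incl, spec$arch)
    ps <- plant_spec(height = h, base_x = grid$x[p], base_y = grid$y[p],
                     base_z = ground_z(grid$y[p]),
                     stem_radius = spec$stem_radius, leaves = lf)
    pc <- generate_plant_impl(ps, spec$density, noise_sd = 0)
    pc$role <- "plant"; pc$instance <- p
    clouds[[length(clouds) + 1]] <- pc
    plants[[p]] <- tibble::tibble(
      plant_id = p, base_x = ps$base_x, base_y = ps$base_y,
      base_z = ps$base_z, height = h, stem_radius = spec$stem_radius,
      n_leaves = n_lv)
    leaves[[p]] <- dplyr::mutate(lf, plant_id = p,
                                 leaf_id = dplyr::row_number(),
                                 .before = 1)
  }

  # soil surface
  g_step <- 1 / sqrt(spec$density)
  gx <- seq(xlim[1], xlim[2], by = g_step)
  gy <- seq(ylim[1], ylim[2], by = g_step)
  gg <- expand.grid(x = gx, y = gy)
  gz <- ground_z(gg$y)
  if (spec$ground_roughness > 0) {
    gz <- gz + rnorm(nrow(gg), 0, spec$ground_roughness)
  }
  clouds[[length(clouds) + 1]] <- tibble::tibble(
    x = gg$x, y = gg$y, z = gz, part = "ground", leaf_id = NA_integer_,
    role = "ground", instance = 0L)

  # calibration spheres tangent to the noiseless plane, on the border strip
  plane_normal <- c(0, -sin(slope), cos(slope))
  spheres <- list()
  for (i in seq_along(spec$sphere_diameters)) {
    r <- spec$sphere_diameters[i] / 2
    # corners of the bare-soil apron, clear of the canopy
    sph_xy <- list(c(xlim[1] + r + 6, ylim[1] + r + 6),
                   c(xlim[2] - r - 6, ylim[1] + r + 6))
    contact <- c(sph_xy[[i]], ground_z(sph_xy[[i]][2]))
    center <- contact + r * plane_normal
    n_pts <- max(50L, ceiling(spec$density * 4 * pi * r^2))
    sp <- sample_sphere(n_pts, center, r)
    sp$part <- "sphere"; sp$leaf_id <- NA_integer_
    sp$role <- "sphere"; sp$instance <- i
    clouds[[length(clouds) + 1]] <- sp
    spheres[[i]] <- tibble::tibble(sphere_id = i, x = center[1],
                                   y = center[2], z = center[3],
                                   diameter = spec$sphere_diameters[i])
  }

  cloud <- dplyr::bind_rows(clouds)
  if (spec$noise_sd > 0) {
    n <- nrow(cloud)
    cloud$x <- cloud$x + rnorm(n, 0, spec$noise_sd)
    cloud$y <- cloud$y + rnorm(n, 0, spec$noise_sd)
    cloud$z <- cloud$z + rnorm(n, 0, spec$noise_sd)
  }

  # sparse outliers over an inflated scene box
  if (spec$n_outliers > 0) {
    zmax <- max(cloud$z)
    out <- tibble::tibble(
      x = runif(spec$n_outliers, xlim[1], xlim[2]),
      y = runif(spec$n_outliers, ylim[1], ylim[2]),
      z = runif(spec$n_outliers, min(cloud$z), zmax + 30),
      part = "outlier", leaf_id = NA_integer_,
      role = "outlier", instance = 0L)
    cloud <- dplyr::bind_rows(cloud, out)
  }

  truth <- list(
    labels = tibble::tibble(point_id = seq_len(nrow(cloud)),
                            role = cloud$role,
                            instance = cloud$instance,
                            leaf_id = cloud$leaf_id),
    plants = dplyr::bind_rows(plants),
    leaves = dplyr::bind_rows(leaves),
    plane = list(normal = plane_normal, d = 0),
    spheres = dplyr::bind_rows(spheres))

  cloud$label <- ifelse(cloud$role == "plant", cloud$instance, 0L)
  cloud <- dplyr::select(cloud, "x", "y", "z", "label")
  structure(list(cloud = as_point_cloud(cloud), truth = truth,
                 spec = spec), class = "scene")
}

#' Write a synthetic scene to a directory
#'
#' Writes the cloud (`cloud.ply`), per-point ground-truth labels
#' (`labels.csv`), per-plant and per-leaf trait tables (`plants.csv`,
#' `leaves.csv`) and the scene parameters (`scene_spec.yaml`).
#'
#' @param scene A scene from [generate_scene()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_point_cloud(scene$cloud, file.path(dir, "cloud.ply"))
  readr::write_csv(scene$truth$labels, file.path(dir, "labels.csv"))
  readr::write_csv(scene$truth$plants, file.path(dir, "plants.csv"))
  readr::write_csv(scene$truth$leaves, file.path(dir, "leaves.csv"))
  yaml::write_yaml(unclass(scene$spec), file.path(dir, "scene_spec.yaml"))
  invisible(dir)
}

#' Restore a scene specification from YAML
#'
#' @param path Path to a YAML file written by [write_scene()] or by hand.
#' @return A [scene_spec()].
#' @export
read_scene_spec <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(scene_spec))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown scene_spec field(s): ",
                 paste(unknown, collapse = ", ")))
  }
  do.call(scene_spec, vals)
}
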