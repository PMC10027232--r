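#' Plant height of a segmented instance
#'
#' Plant height is the vertical distance from the highest point of the plant
#' down to the lowest, `max(Z) - min(Z)`, on a leveled cloud. When the lowest
#' points of the plant have been consumed by ground removal, pass
#' `ground_level` (usually 0 after leveling) to measure from the soil plane
#' instead of from the lowest retained point.
#'
#' @param cloud A leveled point-cloud data frame.
#' @param instance Optional instance id; when given, only points with
#'   `cloud$instance == instance` are used.
#' @param ground_level Optional reference height replacing `min(Z)`.
#' @return Plant height in cm.
#' @export
plant_height <- function(cloud, instance = NULL, ground_level = NULL) {
  cloud <- as_point_cloud(cloud)
  if (!is.null(instance) && !"instance" %in% names(cloud)) {
    abort("cloud has no `instance` column; run segment_plants() first.")
  }
  z <- if (is.null(instance)) cloud$z else cloud$z[cloud$instance == instance]
  if (length(z) == 0) abort("empty instance: cannot measure plant height.")
  if (length(z) == 1) {
    warn("single-point instance: plant height is degenerate (0).")
    if (is.null(ground_level)) return(0)
  }
  zmin <- if (is.null(ground_level)) min(z) else ground_level
  max(z) - zmin
}

#' Split a segmented plant into stem and leaf segments
#'
#' The stem axis is estimated as the vertical line through the XY median of
#' the densest vertical column (the 2 cm XY cell with the largest Z extent).
#' Points within `stem_radius` of the axis are stem; the remaining points
#' are clustered by voxel connectivity into leaves. Each leaf receives a
#' midrib polyline built by slicing the points along their first principal
#' direction and averaging each slice; the polyline is oriented from the
#' stem outward and its first vertex is the attachment point.
#'
#' @param cloud A point-cloud data frame holding one leveled plant.
#' @param stem_radius XY radius around the stem axis treated as stem (cm).
#' @param cell_size Connection distance for leaf clustering (cm).
#' @param min_points Minimum points for a cluster to count as a leaf.
#' @return A list of `leaf_segment` objects (possibly empty), each with
#'   `indices` (row indices into `cloud`), `midrib` (ordered tibble x/y/z),
#'   and `attachment` (3-vector). The estimated stem axis XY is attached as
#'   attribute `stem_xy`.
#' @export
extract_leaves <- function(cloud, stem_radius = 2.5, cell_size = 2,
                           min_points = 20) {
  cloud <- as_point_cloud(cloud)
  if (nrow(cloud) < 3) return(structure(list(), stem_xy = c(NA, NA)))
  stem_xy <- locate_stem(cloud)
  r_xy <- sqrt((cloud$x - stem_xy[1])^2 + (cloud$y - stem_xy[2])^2)
  off <- which(r_xy > stem_radius)
  if (length(off) == 0) return(structure(list(), stem_xy = stem_xy))
  comp <- voxel_components(pc_matrix(cloud[off, ]), cell_size)
  leaves <- list()
  for (cc in seq_len(max(comp))) {
    idx <- off[comp == cc]
    if (length(idx) < min_points) next
    seg <- build_midrib(cloud[idx, ], stem_xy, clip_radius = stem_radius,
                        attach_radius = attr(stem_xy, "radius"))
    seg$indices <- idx
    # order leaves bottom-up by attachment height for stable ids
    leaves[[length(leaves) + 1]] <- seg
  }
  if (length(leaves) > 1) {
    ord <- order(vapply(leaves, function(s) s$attachment[3], numeric(1)))
    leaves <- leaves[ord]
  }
  structure(leaves, stem_xy = stem_xy)
}

# XY median of the densest vertical column on a 2 cm XY grid, refined with
# the lower-stem points (below the lowest leaves, the cloud is pure stem,
# and the median of a sampled cylinder surface is its axis). Returns the
# axis XY and, as attribute `radius`, the estimated stem surface radius.
locate_stem <- function(cloud) {
  cell <- 2
  ix <- floor((cloud$x - min(cloud$x)) / cell)
  iy <- floor((cloud$y - min(cloud$y)) / cell)
  key <- paste(ix, iy)
  ext <- tapply(cloud$z, key, function(z) max(z) - min(z))
  winner <- names(ext)[which.max(ext)]
  sel <- key == winner
  xy <- c(median(cloud$x[sel]), median(cloud$y[sel]))
  lower <- cloud$z <= min(cloud$z) + 0.25 * (max(cloud$z) - min(cloud$z))
  near <- lower & sqrt((cloud$x - xy[1])^2 + (cloud$y - xy[2])^2) < 2.5
  radius <- 0
  if (sum(near) >= 10) {
    xy <- c(median(cloud$x[near]), median(cloud$y[near]))
    r <- sqrt((cloud$x[near] - xy[1])^2 + (cloud$y[near] - xy[2])^2)
    radius <- unname(stats::quantile(r, 0.95))
  }
  structure(xy, radius = radius)
}

# centred moving average with window shrinking near the ends
running_mean <- function(v, w) {
  n <- length(v)
  h <- (w - 1) %/% 2
  vapply(seq_len(n), function(i) {
    k <- min(h, i - 1, n - i)
    mean(v[(i - k):(i + k)])
  }, numeric(1))
}

# straight-line fit with outlier trimming: slice centroids occasionally
# jitter hard (partial slices, few points), and a single bad vertex must
# not steer an extrapolation
fit_line_robust <- function(x, y) {
  cf <- stats::lm.fit(cbind(1, x), y)$coefficients
  for (it in 1:3) {
    res <- y - (cf[1] + cf[2] * x)
    s <- stats::mad(res)
    if (!is.finite(s) || s < 1e-12) break
    keep <- abs(res) <= 2.5 * s
    if (sum(keep) < 3 || all(keep)) break
    cf <- stats::lm.fit(cbind(1, x[keep]), y[keep])$coefficients
  }
  cf
}

# midrib polyline by slicing along the first principal direction
build_midrib <- function(pts, stem_xy, clip_radius = 0, attach_radius = 0) {
  if (is.null(attach_radius)) attach_radius <- 0
  stem_xy <- as.numeric(stem_xy)[1:2]
  m <- pc_matrix(pts)
  ctr <- colMeans(m)
  dev <- sweep(m, 2, ctr)
  pc1 <- svd(dev, nu = 0, nv = 1)$v[, 1]
  proj <- as.numeric(dev %*% pc1)
  chord <- diff(range(proj))
  n_slices <- max(20L, ceiling(chord))  # 20 slices or one per cm
  br <- seq(min(proj), max(proj), length.out = n_slices + 1)
  slice <- pmin(findInterval(proj, br, rightmost.closed = TRUE), n_slices)
  occupied <- sort(unique(slice))
  verts <- t(vapply(occupied, function(s) colMeans(m[slice == s, , drop = FALSE]),
                    numeric(3)))
  # orient outward from the stem axis
  d_first <- sum((verts[1, 1:2] - stem_xy)^2)
  d_last <- sum((verts[nrow(verts), 1:2] - stem_xy)^2)
  if (d_last < d_first) {
    verts <- verts[rev(seq_len(nrow(verts))), , drop = FALSE]
    slice <- (n_slices + 1L) - slice
    occupied <- sort(unique(slice))
  }
  slice_of_point <- match(slice, occupied)
  # slices straddling the stem-exclusion cylinder are partial (only the
  # outer part of the blade survives), so their centroids are displaced;
  # drop the leading vertices inside that zone before any measurement
  r_vert <- sqrt((verts[, 1] - stem_xy[1])^2 + (verts[, 2] - stem_xy[2])^2)
  first_ok <- which(r_vert > clip_radius + 1)[1]
  if (!is.na(first_ok) && first_ok > 1 && nrow(verts) - first_ok >= 2) {
    drop <- seq_len(first_ok - 1)
    verts <- verts[-drop, , drop = FALSE]
    slice_of_point <- slice_of_point - (first_ok - 1L)
    slice_of_point[slice_of_point < 1L] <- NA_integer_
  }
  # slice centroids jitter, and an unsmoothed polyline zig-zags, inflating
  # arc length and flattening segment elevations. Smooth in cylindrical
  # coordinates about the stem axis: the azimuthal coordinate carries no
  # trait signal and only varies slowly along a real midrib, so it gets a
  # wide window; the radial and vertical coordinates get a light one.
  if (nrow(verts) >= 3) {
    rel1 <- verts[, 1] - stem_xy[1]
    rel2 <- verts[, 2] - stem_xy[2]
    r_cyl <- sqrt(rel1^2 + rel2^2)
    theta <- atan2(rel2, rel1)
    theta <- theta[1] + c(0, cumsum(((diff(theta) + pi) %% (2 * pi)) - pi))
    r_cyl <- running_mean(r_cyl, 3)
    zs <- running_mean(verts[, 3], 3)
    theta <- running_mean(theta, 7)
    verts <- cbind(stem_xy[1] + r_cyl * cos(theta),
                   stem_xy[2] + r_cyl * sin(theta), zs)
  }
  # extrapolate back to the stem surface along the drooping midrib: fit
  # the segment elevation angle linearly in arc length over the basal
  # half, then integrate the fitted angle inward until the surface is
  # reached. This runs before the tip step so the polyline's arc origin is
  # the true attachment.
  if (nrow(verts) >= 2) {
    segs <- diff(verts)
    lens <- sqrt(rowSums(segs^2))
    # elevation against radial progress from the stem axis: transverse
    # wobble of the centroids cancels out of the radial coordinate
    dr <- diff(sqrt((verts[, 1] - stem_xy[1])^2 +
                      (verts[, 2] - stem_xy[2])^2))
    phi <- atan2(segs[, 3], pmax(dr, 1e-9))
    arc <- c(0, cumsum(lens))
    mid <- (arc[-length(arc)] + arc[-1]) / 2
    use <- which(mid <= pmax(0.6 * arc[length(arc)], mid[1]))
    if (length(use) >= 4) {
      cf <- fit_line_robust(mid[use], phi[use])
    } else if (length(use) >= 2) {
      cf <- stats::lm.fit(cbind(1, mid[use]), phi[use])$coefficients
    } else {
      cf <- c(phi[1], 0)
    }
    r1 <- sqrt(sum((verts[1, 1:2] - stem_xy)^2))
    base_gap <- r1 - attach_radius  # the leaf emerges at the stem surface
    if (base_gap > 1e-9) {
      hdir <- (verts[1, 1:2] - stem_xy) / r1
      # march inward in small arc steps, tilting with the fitted angle
      ds <- 0.05
      s <- 0
      reach <- 0
      drop_z <- 0
      while (reach < base_gap && s < base_gap * 4) {
        s <- s + ds
        a <- min(max(cf[1] + cf[2] * (-(s - ds / 2)), -pi / 2), pi / 2)
        reach <- reach + ds * cos(a)
        drop_z <- drop_z + ds * sin(a)
      }
      attach <- c(stem_xy + attach_radius * hdir, verts[1, 3] - drop_z)
      verts <- rbind(attach, verts)
      slice_of_point <- slice_of_point + 1L
    }
  }
  # the sampled blade ends short of the true tip: the taper makes the
  # point density vanish there, so the outermost samples sit inside the
  # midrib endpoint. With surface density rho and a blade width shrinking
  # linearly at rate b, the arc-length density of samples near the
  # endpoint L is rho * b * (L - s); the endpoint is estimated as the
  # posterior mean of L under that inhomogeneous-Poisson likelihood
  # evaluated on the points in the last stretch of the blade.
  tip_diag <- NULL
  if (nrow(verts) >= 5) {
    nv <- nrow(verts)
    segd <- diff(verts)
    lens <- sqrt(rowSums(segd^2))
    arc <- c(0, cumsum(lens))
    # transverse extent of each slice measured as the azimuthal offset of
    # its points about the smoothed midrib: unlike a free principal
    # direction, the azimuthal coordinate cannot soak up vertical jitter
    rel_p1 <- m[, 1] - stem_xy[1]
    rel_p2 <- m[, 2] - stem_xy[2]
    r_pt <- sqrt(rel_p1^2 + rel_p2^2)
    th_pt <- atan2(rel_p2, rel_p1)
    th_v <- atan2(verts[, 2] - stem_xy[2], verts[, 1] - stem_xy[1])
    r_v <- sqrt((verts[, 1] - stem_xy[1])^2 + (verts[, 2] - stem_xy[2])^2)
    ext <- vapply(seq_len(nv), function(i) {
      sel <- which(!is.na(slice_of_point) & slice_of_point == i)
      ns <- length(sel)
      if (ns < 3) return(NA_real_)
      t_off <- r_pt[sel] * sin(th_pt[sel] - th_v[i])
      diff(range(t_off)) * (ns + 1) / (ns - 1)
    }, numeric(1))
    nslice <- vapply(seq_len(nv), function(i)
      sum(!is.na(slice_of_point) & slice_of_point == i), integer(1))
    fit_ok <- which(!is.na(ext) & nslice >= 8 &
                      arc >= 0.45 * arc[nv] & arc <= 0.95 * arc[nv])
    if (length(fit_ok) >= 3 && lens[nv - 1] > 1e-9) {
      cf <- fit_line_robust(arc[fit_ok], ext[fit_ok])
      dirv <- (verts[nv, ] - verts[nv - 1, ]) / lens[nv - 1]
      # arc position of the farthest sample, converted from its radial
      # overhang past the last vertex via the end elevation angle
      dz_end <- diff(verts[, 3])
      dr_end <- diff(r_v)
      k_end <- max(1L, nv - 3L):(nv - 1L)
      cos_end <- max(0.2, cos(atan2(mean(dz_end[k_end]),
                                    max(mean(dr_end[k_end]), 1e-9))))
      # arc positions of all points near the end, via the same radial map
      s_pt <- arc[nv] + (r_pt - r_v[nv]) / cos_end
      s1 <- max(s_pt)
      s_max <- max(arc[nv], s1)
      b <- -cf[2]
      good <- which(!is.na(ext))
      area <- sum(ext[good]) * mean(diff(arc))
      rho <- nrow(m) / max(area, 1e-6)
      tip <- s_max
      if (b > 1e-4) {
        c_hat <- rho * b
        win <- 5
        tail_s <- s_pt[s_pt >= s1 - win]
        grid_l <- seq(s1 + 1e-3, s1 + 5, length.out = 200)
        ll <- vapply(grid_l, function(l)
          sum(log(l - tail_s)) - c_hat * (l - (s1 - win))^2 / 2, numeric(1))
        w <- exp(ll - max(ll))
        tip <- max(s_max, sum(grid_l * w) / sum(w))
      }
      tip_diag <- c(arc_last = unname(arc[nv]), s_max = unname(s_max),
                    tip = unname(tip), b = unname(b), rho = unname(rho))
      extra <- min(max(tip - arc[nv], 0), 4)
      if (extra > 0) verts <- rbind(verts, verts[nv, ] + extra * dirv)
    }
  }
  midrib <- tibble::tibble(x = verts[, 1], y = verts[, 2], z = verts[, 3])
  structure(list(midrib = midrib, attachment = unname(verts[1, ]),
                 slice_of_point = slice_of_point, points = pts,
                 tip_diag = tip_diag),
            class = "leaf_segment")
}

#' @export
print.leaf_segment <- function(x, ...) {
  cat(sprintf(
    "Leaf segment: %d points, %d midrib vertices, attachment z = %.2f cm\n",
    length(x$indices), nrow(x$midrib), x$attachment[3]))
  invisible(x)
}

#' Leaf length (midrib arc length)
#'
#' Arc length of the midrib polyline from attachment to tip. The polyline
#' built by [extract_leaves()] already spans the full leaf: its first vertex
#' sits on the stem surface and its last vertex at the estimated tip (the
#' posterior-mean endpoint of the vanishing-taper sampling model).
#'
#' @param leaf A `leaf_segment`.
#' @return Length in cm.
#' @export
leaf_length <- function(leaf) {
  v <- as.matrix(leaf$midrib)
  if (nrow(v) < 2) abort("degenerate midrib: need at least 2 vertices.")
  sum(sqrt(rowSums(diff(v)^2)))
}

#' Leaf width (maximum transverse extent)
#'
#' For each midrib slice, the extent of the slice's points perpendicular to
#' the local midrib tangent is measured; the maximum over slices is the leaf
#' width.
#'
#' @param leaf A `leaf_segment`.
#' @param cloud Unused when the segment carries its points (kept for
#'   call-site symmetry with [leaf_length()]).
#' @return Width in cm.
#' @export
leaf_width <- function(leaf, cloud = NULL) {
  pts <- leaf$points
  if (is.null(pts) || nrow(pts) < 3) abort("degenerate leaf: need >= 3 points.")
  m <- pc_matrix(pts)
  v <- as.matrix(leaf$midrib)
  nv <- nrow(v)
  widths <- vapply(seq_len(nv), function(i) {
    sel <- which(!is.na(leaf$slice_of_point) & leaf$slice_of_point == i)
    ns <- length(sel)
    if (ns < 3) return(0)
    tangent <- v[min(i + 1, nv), ] - v[max(i - 1, 1), ]
    tl <- sqrt(sum(tangent^2))
    if (tl < 1e-12) return(0)
    tangent <- tangent / tl
    dev <- sweep(m[sel, , drop = FALSE], 2, v[i, ])
    perp <- dev - outer(as.numeric(dev %*% tangent), tangent)
    pc <- svd(perp, nu = 0, nv = 1)$v[, 1]
    # sample range underestimates the true transverse support; rescale by
    # the uniform-distribution range correction (n + 1) / (n - 1)
    diff(range(perp %*% pc)) * (ns + 1) / (ns - 1)
  }, numeric(1))
  max(widths)
}

#' Leaf inclination above the horizontal
#'
#' The stem-leaf angle is the angle between the stem axis and the midrib
#' tangent at the attachment point; the inclination is its complement,
#' `90 - stem-leaf angle`, clamped to `[0, 90]` degrees — i.e. how steeply
#' the leaf leaves the stem, measured from the horizontal plane. Because a
#' maize midrib droops continuously, the tangent at the attachment is found
#' by regressing the elevation angle of each polyline segment on its arc
#' position over the basal 60% of the midrib and evaluating the fit at arc
#' length zero; this removes the downward bias a plain first-segment
#' tangent would have on arched leaves.
#'
#' @param leaf A `leaf_segment`.
#' @param stem_axis Unit stem direction (default vertical, `c(0, 0, 1)`).
#' @return Inclination in degrees.
#' @export
leaf_inclination <- function(leaf, stem_axis = c(0, 0, 1)) {
  v <- as.matrix(leaf$midrib)
  if (nrow(v) < 2) abort("degenerate midrib: need at least 2 vertices.")
  segs <- diff(v)
  lens <- sqrt(rowSums(segs^2))
  if (all(lens < 1e-12)) abort("zero-length base tangent.")
  axis <- stem_axis / sqrt(sum(stem_axis^2))
  # elevation of each segment relative to the plane normal to the stem
  # axis, with the in-plane progress measured radially outward from the
  # attachment: transverse wobble of the polyline cancels out of the
  # radial coordinate instead of flattening the elevation
  along <- as.numeric(segs %*% axis)
  rel <- sweep(v, 2, v[1, ])
  rel_along <- as.numeric(rel %*% axis)
  rad <- sqrt(pmax(rowSums(rel^2) - rel_along^2, 0))
  phi <- atan2(along, pmax(diff(rad), 1e-9)) * 180 / pi
  arc <- c(0, cumsum(lens))
  mid <- (arc[-length(arc)] + arc[-1]) / 2
  use <- which(mid <= pmax(0.6 * arc[length(arc)], mid[1]))
  if (length(use) < 2) {
    base_phi <- phi[1]
  } else if (length(use) < 4) {
    base_phi <- stats::lm.fit(cbind(1, mid[use]), phi[use])$coefficients[1]
  } else {
    base_phi <- fit_line_robust(mid[use], phi[use])[1]
  }
  min(max(abs(base_phi), 0), 90)
}

#' Leaf growth height
#'
#' Height of the leaf attachment point above the ground plane (the cloud
#' must be leveled so that the soil is Z = 0).
#'
#' @param leaf A `leaf_segment`.
#' @return Height in cm. Attachments below 0 indicate poor leveling and
#'   trigger a warning, but the value is still reported.
#' @export
leaf_growth_height <- function(leaf) {
  if (is.null(leaf$attachment)) abort("leaf has no attachment point.")
  gh <- leaf$attachment[3]
  if (gh < 0) warn("leaf attachment below the ground plane; check leveling.")
  gh
}

#' Extract the full trait table of a segmented scene
#'
#' Runs [plant_height()] and the leaf chain ([extract_leaves()],
#' [leaf_length()], [leaf_width()], [leaf_inclination()],
#' [leaf_growth_height()]) on every plant instance of a leveled,
#' ground-removed, segmented cloud.
#'
#' @param cloud A cloud with an `instance` column (see [segment_plants()]).
#' @param ground_level Reference height for plant height (default 0: the
#'   leveled soil plane).
#' @param stem_radius,leaf_cell,leaf_min_points Passed to [extract_leaves()].
#' @return A tibble with columns plant_id, height_cm, leaf_id, length_cm,
#'   width_cm, inclination_deg, growth_height_cm (one row per leaf; plants
#'   with no detected leaves get a single row of NA leaf values).
#' @export
extract_traits <- function(cloud, ground_level = 0, stem_radius = 2.5,
                           leaf_cell = 2, leaf_min_points = 20) {
  cloud <- as_point_cloud(cloud)
  if (!"instance" %in% names(cloud)) {
    abort("cloud has no `instance` column; run segment_plants() first.")
  }
  ids <- sort(unique(cloud$instance[cloud$instance > 0]))
  purrr::map_dfr(ids, function(id) {
    pts <- cloud[cloud$instance == id, ]
    h <- plant_height(pts, ground_level = ground_level)
    leaves <- extract_leaves(pts, stem_radius = stem_radius,
                             cell_size = leaf_cell,
                             min_points = leaf_min_points)
    if (length(leaves) == 0) {
      return(tibble::tibble(plant_id = id, height_cm = h,
                            leaf_id = NA_integer_, length_cm = NA_real_,
                            width_cm = NA_real_, inclination_deg = NA_real_,
                            growth_height_cm = NA_real_))
    }
    purrr::map_dfr(seq_along(leaves), function(i) {
      lf <- leaves[[i]]
      tibble::tibble(plant_id = id, height_cm = h, leaf_id = i,
                     length_cm = leaf_length(lf),
                     width_cm = leaf_width(lf),
                     inclination_deg = leaf_inclination(lf),
                     growth_height_cm = leaf_growth_height(lf))
    })
  })
}
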