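#' Assign points to breeding plots
#'
#' Labels each point with the id of the plot-map cell whose half-open XY
#' rectangle `[xmin, xmax) x [ymin, ymax)` contains it; a point exactly on a
#' shared boundary therefore belongs to the higher cell. Points outside all
#' cells receive plot id 0.
#'
#' @param cloud A point-cloud data frame.
#' @param plots A plot map (see [read_plot_map()]).
#' @return The cloud with a `plot_id` column added.
#' @export
assign_plots <- function(cloud, plots) {
  cloud <- as_point_cloud(cloud)
  plots <- validate_plot_map(plots)
  plot_id <- rep(0L, nrow(cloud))
  for (i in seq_len(nrow(plots))) {
    inside <- cloud$x >= plots$xmin[i] & cloud$x < plots$xmax[i] &
      cloud$y >= plots$ymin[i] & cloud$y < plots$ymax[i]
    plot_id[inside] <- as.integer(plots$plot_id[i])
  }
  cloud$plot_id <- plot_id
  cloud
}

# Connected components of the voxel occupancy graph: points are binned into
# cubic cells of side `cell`; occupied cells touching in the 26-neighbourhood
# are connected. Returns an integer component id per point.
voxel_components <- function(p, cell) {
  if (cell <= 0) abort("cell size must be positive.")
  n <- nrow(p)
  if (n == 0) return(integer())
  mins <- c(min(p[, 1]), min(p[, 2]), min(p[, 3]))
  iv <- floor((p[, 1] - mins[1]) / cell) + 1
  jv <- floor((p[, 2] - mins[2]) / cell) + 1
  kv <- floor((p[, 3] - mins[3]) / cell) + 1
  nj <- max(jv) + 2
  nk <- max(kv) + 2
  key <- (iv * nj + jv) * nk + kv
  ukey <- sort(unique(key))
  vox_of_point <- match(key, ukey)
  nv <- length(ukey)

  # half neighbourhood (13 offsets) avoids duplicate edges
  offs <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  offs <- offs[offs$di > 0 | (offs$di == 0 & offs$dj > 0) |
                 (offs$di == 0 & offs$dj == 0 & offs$dk > 0), ]
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    nb <- ukey + (offs$di[r] * nj + offs$dj[r]) * nk + offs$dk[r]
    hit <- match(nb, ukey)
    ok <- !is.na(hit)
    if (any(ok)) {
      edges <- rbind(edges, cbind(which(ok), hit[ok]))
    }
  }
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  memb <- igraph::components(g)$membership
  as.integer(memb[vox_of_point])
}

#' Segment individual plants by voxel-connectivity clustering
#'
#' Single-linkage Euclidean clustering on a voxel occupancy graph: points are
#' binned into cells of side `cell_size` and occupied cells touching in the
#' 26-neighbourhood form one cluster. Clusters with fewer than `min_points`
#' points are discarded (instance 0). This is a deterministic geometric
#' substitute for a learned plant segmenter; the interface accepts any
#' labelling that partitions the retained points, so a trained model can be
#' dropped in.
#'
#' @param cloud A ground-removed, leveled point-cloud data frame.
#' @param cell_size Connection distance of the clustering in cm (default 5).
#' @param min_points Minimum cluster size kept as a plant (default 50).
#' @param plant_spacing Optional nominal in-row spacing (cm); clusters whose
#'   XY span exceeds 1.8 x this value trigger a touching-canopy warning.
#' @return The cloud with an `instance` column (0 = discarded); the instance
#'   summary table (instance_id, n_points, base_x, base_y) is attached and
#'   available via [plant_instances()]. Stem base = XY median of the
#'   cluster's lowest decile of Z.
#' @export
segment_plants <- function(cloud, cell_size = 5, min_points = 50,
                           plant_spacing = NULL) {
  cloud <- as_point_cloud(cloud)
  if (nrow(cloud) == 0) {
    cloud$instance <- integer()
    attr(cloud, "instances") <- tibble::tibble(
      instance_id = integer(), n_points = integer(),
      base_x = numeric(), base_y = numeric())
    return(cloud)
  }
  comp <- voxel_components(pc_matrix(cloud), cell_size)
  sizes <- tabulate(comp)
  keep_comp <- which(sizes >= min_points)

  summaries <- purrr::map_dfr(keep_comp, function(cc) {
    idx <- which(comp == cc)
    zq <- quantile(cloud$z[idx], 0.1, names = FALSE)
    low <- idx[cloud$z[idx] <= zq]
    tibble::tibble(component = cc, n_points = length(idx),
                   base_x = median(cloud$x[low]),
                   base_y = median(cloud$y[low]),
                   span_xy = max(max(cloud$x[idx]) - min(cloud$x[idx]),
                                 max(cloud$y[idx]) - min(cloud$y[idx])))
  })
  if (nrow(summaries) > 0) {
    summaries <- dplyr::arrange(summaries, .data$base_x, .data$base_y)
    summaries$instance_id <- seq_len(nrow(summaries))
    if (!is.null(plant_spacing) &&
        any(summaries$span_xy > 1.8 * plant_spacing)) {
      warn(paste0("cluster XY span exceeds 1.8 x plant spacing; ",
                  "touching canopies may have merged into one instance."))
    }
  }
  inst <- rep(0L, nrow(cloud))
  for (r in seq_len(nrow(summaries))) {
    inst[comp == summaries$component[r]] <- summaries$instance_id[r]
  }
  cloud$instance <- inst
  attr(cloud, "instances") <- dplyr::select(
    summaries, "instance_id", "n_points", "base_x", "base_y")
  cloud
}

#' Instance summary attached by [segment_plants()]
#'
#' @param cloud A cloud returned by [segment_plants()].
#' @return A tibble with one row per retained plant instance.
#' @export
plant_instances <- function(cloud) {
  inst <- attr(cloud, "instances")
  if (is.null(inst)) abort("no instance table attached; run segment_plants().")
  inst
}
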