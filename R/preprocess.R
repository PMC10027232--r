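#' Retrieve the filter report of a preprocessing step
#'
#' [statistical_outlier_removal()] and [voxel_downsample()] return the
#' filtered cloud with a report attached as an attribute; this accessor
#' retrieves it.
#'
#' @param cloud A cloud returned by a preprocessing function.
#' @return A one-row tibble with `points_before`, `points_after` and
#'   `ratio_pct` (100 x after/before).
#' @export
filter_report <- function(cloud) {
  rep <- attr(cloud, "filter_report")
  if (is.null(rep)) abort("no filter report attached to this cloud.")
  rep
}

make_filter_report <- function(before, after) {
  tibble::tibble(points_before = before, points_after = after,
                 ratio_pct = if (before > 0) 100 * after / before else NA_real_)
}

#' Statistical outlier removal
#'
#' For every point, the mean distance to its `k` nearest neighbours is
#' computed; points whose mean distance exceeds the global mean plus
#' `std_ratio` standard deviations are removed. Labels and any other
#' per-point columns are carried through unchanged.
#'
#' @param cloud A point-cloud data frame with more than `k` points.
#' @param k Neighbour count (default 20).
#' @param std_ratio Standard-deviation multiplier for the distance threshold
#'   (default 2).
#' @return The filtered cloud, with a [filter_report()] attribute.
#' @export
statistical_outlier_removal <- function(cloud, k = 20, std_ratio = 2) {
  cloud <- as_point_cloud(cloud)
  if (k < 1) abort("`k` must be at least 1.")
  n <- nrow(cloud)
  if (k >= n) abort("`k` must be smaller than the number of points.")
  md <- cpp_knn_mean_dist(pc_matrix(cloud), as.integer(k))
  thr <- mean(md) + std_ratio * sd(md)
  keep <- md <= thr
  out <- cloud[keep, , drop = FALSE]
  attr(out, "filter_report") <- make_filter_report(n, nrow(out))
  out
}

#' Voxel-grid down-sampling
#'
#' Overlays a cubic grid of side `edge_length` anchored at the minimum corner
#' of the cloud's bounding box; every occupied voxel contributes exactly one
#' output point, the centroid ("gravity centre") of its members. Voxel
#' membership uses half-open boxes (floor division), so a point exactly on an
#' upper face belongs to the higher-index voxel. When a `label` column is
#' present the output label is the majority label of the members (ties go to
#' the smallest id).
#'
#' @param cloud A point-cloud data frame.
#' @param edge_length Voxel side length in cm (> 0).
#' @return The down-sampled cloud with a [filter_report()] attribute.
#' @export
voxel_downsample <- function(cloud, edge_length) {
  if (edge_length <= 0) abort("voxel edge length must be positive.")
  cloud <- as_point_cloud(cloud)
  n <- nrow(cloud)
  if (n == 0) {
    out <- cloud
    attr(out, "filter_report") <- make_filter_report(0L, 0L)
    return(out)
  }
  mins <- c(min(cloud$x), min(cloud$y), min(cloud$z))
  ix <- floor((cloud$x - mins[1]) / edge_length)
  iy <- floor((cloud$y - mins[2]) / edge_length)
  iz <- floor((cloud$z - mins[3]) / edge_length)
  key <- (ix * (max(iy) + 2) + iy) * (max(iz) + 2) + iz
  gid <- match(key, sort(unique(key)))
  counts <- tabulate(gid)
  num_cols <- c("x", "y", "z", intersect("intensity", names(cloud)))
  sums <- rowsum(as.matrix(tibble::as_tibble(cloud)[num_cols]), gid)
  cent <- tibble::as_tibble(sums / counts)
  if ("label" %in% names(cloud)) {
    lab <- tibble::tibble(gid = gid, label = cloud[["label"]]) |>
      dplyr::count(.data$gid, .data$label) |>
      dplyr::arrange(.data$gid, dplyr::desc(.data$n), .data$label)
    cent$label <- lab$label[!duplicated(lab$gid)]
  }
  out <- as_point_cloud(cent)
  attr(out, "filter_report") <- make_filter_report(n, nrow(out))
  out
}

#' Percentage of points retained by a filtering step
#'
#' @param report A [filter_report()] tibble (or a cloud carrying one).
#' @return `100 * points_after / points_before`.
#' @examples
#' compression_summary(tibble::tibble(points_before = 100, points_after = 36))
#' @export
compression_summary <- function(report) {
  if (is.data.frame(report) && !"points_before" %in% names(report)) {
    report <- filter_report(report)
  }
  if (!is.data.frame(report)) report <- filter_report(report)
  if (report$points_before == 0) {
    abort("cannot summarize compression of an empty input cloud.")
  }
  100 * report$points_after / report$points_before
}
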