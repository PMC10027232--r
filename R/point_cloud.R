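#' Point cloud tibbles
#'
#' A point cloud is an ordinary tibble with numeric columns `x`, `y`, `z`
#' (centimetres) and, optionally, `intensity` (per-point scalar) and `label`
#' (integer; 0 = unassigned/ground, > 0 = plant instance id). Every
#' `phenocloud` operation accepts any data frame with these columns and
#' returns a tibble, so point clouds compose with dplyr verbs and the pipe.
#'
#' @param x,y,z Numeric coordinate vectors of equal length, in centimetres.
#' @param intensity Optional numeric vector, one value per point.
#' @param label Optional integer vector, one value per point.
#' @return A tibble of class `point_cloud`.
#' @examples
#' pc <- point_cloud(x = c(0, 1), y = c(0, 0), z = c(0, 2))
#' n_points(pc)
#' @export
point_cloud <- function(x = numeric(), y = numeric(), z = numeric(),
                        intensity = NULL, label = NULL) {
  cloud <- tibble::tibble(x = as.numeric(x), y = as.numeric(y),
                          z = as.numeric(z))
  if (!is.null(intensity)) cloud$intensity <- as.numeric(intensity)
  if (!is.null(label)) cloud$label <- as.integer(label)
  as_point_cloud(cloud)
}

#' Coerce and validate a point cloud
#'
#' @param cloud A data frame with numeric columns `x`, `y`, `z` and optional
#'   `intensity` and `label` columns.
#' @return A validated tibble of class `point_cloud`.
#' @export
as_point_cloud <- function(cloud) {
  if (!is.data.frame(cloud)) {
    abort("`cloud` must be a data frame with columns x, y, z.")
  }
  missing_cols <- setdiff(c("x", "y", "z"), names(cloud))
  if (length(missing_cols) > 0) {
    abort(paste0("point cloud is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  cloud <- tibble::as_tibble(cloud)
  for (col in c("x", "y", "z")) {
    if (!is.numeric(cloud[[col]])) {
      abort(paste0("point cloud column `", col, "` must be numeric."))
    }
    if (anyNA(cloud[[col]]) || any(!is.finite(cloud[[col]]))) {
      abort(paste0("point cloud column `", col,
                   "` contains non-finite values."))
    }
  }
  if ("label" %in% names(cloud)) {
    if (length(cloud[["label"]]) != nrow(cloud)) {
      abort("`label` must have exactly one entry per point.")
    }
    cloud$label <- as.integer(cloud[["label"]])
  }
  class(cloud) <- unique(c("point_cloud", class(cloud)))
  cloud
}

#' Number of points in a cloud
#'
#' @param cloud A point-cloud data frame.
#' @return Integer point count.
#' @export
n_points <- function(cloud) nrow(cloud)

# internal: n x 3 coordinate matrix
pc_matrix <- function(cloud) {
  cbind(x = cloud$x, y = cloud$y, z = cloud$z)
}

#' @export
print.point_cloud <- function(x, ...) {
  cat("# A point cloud:", nrow(x), "points\n")
  NextMethod()
}

#' Plot a point cloud as 2D projections
#'
#' Draws top (x-y) and side (x-z) orthographic projections, coloured by
#' `label` when present.
#'
#' @param object A point-cloud data frame.
#' @param projection One of "xz" (side view, default) or "xy" (top view).
#' @param max_points Clouds larger than this are randomly thinned for display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.point_cloud <- function(object, projection = c("xz", "xy"),
                                 max_points = 50000, ...) {
  projection <- match.arg(projection)
  df <- tibble::as_tibble(object)
  if (nrow(df) > max_points) {
    df <- df[sample.int(nrow(df), max_points), ]
  }
  vert <- if (projection == "xz") "z" else "y"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data[[vert]]))
  if ("label" %in% names(df)) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(colour = factor(.data$label)), size = 0.3) +
      ggplot2::labs(colour = "label")
  } else {
    p <- p + ggplot2::geom_point(size = 0.3)
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = paste0(vert, " (cm)")) +
    ggplot2::theme_minimal()
}
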