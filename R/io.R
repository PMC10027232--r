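#' Read a point cloud from disk
#'
#' Supports three ASCII formats: whitespace-separated XYZ (3 or 4 columns,
#' the 4th read as an integer label), ASCII PLY (`x y z` vertex properties
#' plus an optional `label` property), and ASCII PCD v0.7. Binary PLY/PCD
#' variants are rejected with a clear message. Coordinates are taken to be
#' centimetres.
#'
#' @param path Path to the file.
#' @param format One of "auto" (detect from the file extension), "xyz",
#'   "ply" or "pcd".
#' @return A [point_cloud()] tibble.
#' @seealso [write_point_cloud()]
#' @export
read_point_cloud <- function(path, format = c("auto", "xyz", "ply", "pcd")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("point cloud file not found: ", path))
  }
  if (format == "auto") format <- detect_cloud_format(path)
  switch(format,
         xyz = read_xyz(path),
         ply = read_ply(path),
         pcd = read_pcd(path))
}

detect_cloud_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("xyz", "txt", "ply", "pcd")) {
    abort(paste0("cannot infer point cloud format from extension '.", ext,
                 "'; pass `format` explicitly."))
  }
  if (ext == "txt") "xyz" else ext
}

#' Write a point cloud to disk
#'
#' Output is re-readable by [read_point_cloud()] with coordinates preserved
#' to 6 decimal places (well below 1e-4 cm). When the cloud carries a
#' `label` column it is stored as an extra per-point integer column/property.
#'
#' @param cloud A point-cloud data frame.
#' @param path Destination path.
#' @param format One of "auto", "xyz", "ply", "pcd".
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path,
                              format = c("auto", "xyz", "ply", "pcd")) {
  format <- match.arg(format)
  cloud <- as_point_cloud(cloud)
  if (format == "auto") format <- detect_cloud_format(path)
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) abort(paste0("destination directory does not exist: ",
                            dirname(path)))
  switch(format,
         xyz = write_xyz(cloud, path),
         ply = write_ply(cloud, path),
         pcd = write_pcd(cloud, path))
  invisible(path)
}

fmt_coord <- function(v) sprintf("%.6f", v)

# ---- XYZ ------------------------------------------------------------------

read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) return(point_cloud())
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  ncols <- lengths(toks)
  if (any(ncols < 3 | ncols > 4)) {
    bad <- keep[which(ncols < 3 | ncols > 4)[1]]
    abort(paste0("malformed record on line ", bad,
                 ": expected 3 or 4 whitespace-separated values."))
  }
  vals <- suppressWarnings(lapply(toks, as.numeric))
  bad_tok <- vapply(vals, anyNA, logical(1))
  if (any(bad_tok)) {
    bad <- keep[which(bad_tok)[1]]
    abort(paste0("non-numeric token on line ", bad, " of ", basename(path)))
  }
  if (!all(ncols == ncols[1])) {
    abort("mixed 3- and 4-column records; label column must be consistent.")
  }
  m <- do.call(rbind, vals)
  if (ncols[1] == 4) {
    point_cloud(m[, 1], m[, 2], m[, 3], label = m[, 4])
  } else {
    point_cloud(m[, 1], m[, 2], m[, 3])
  }
}

write_xyz <- function(cloud, path) {
  if (nrow(cloud) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  rows <- paste(fmt_coord(cloud$x), fmt_coord(cloud$y), fmt_coord(cloud$z))
  if ("label" %in% names(cloud)) rows <- paste(rows, cloud[["label"]])
  writeLines(rows, path)
  invisible(path)
}

# ---- PLY ------------------------------------------------------------------

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || trimws(lines[1]) != "ply") {
    abort(paste0(basename(path), " is not a PLY file (missing 'ply' magic)."))
  }
  end <- match("end_header", trimws(lines))
  if (is.na(end)) abort("PLY header has no end_header line.")
  header <- trimws(lines[seq_len(end)])
  fmt <- grep("^format ", header, value = TRUE)
  if (length(fmt) != 1 || !grepl("^format ascii", fmt)) {
    abort("only ASCII PLY is supported; binary PLY rejected.")
  }
  vline <- grep("^element vertex ", header, value = TRUE)
  if (length(vline) != 1) abort("PLY header must declare one vertex element.")
  n <- as.integer(sub("^element vertex\\s+", "", vline))
  props <- sub("^property\\s+\\S+\\s+", "", grep("^property ", header,
                                                 value = TRUE))
  if (!identical(props[1:3], c("x", "y", "z"))) {
    abort("PLY vertex properties must start with x, y, z.")
  }
  has_label <- "label" %in% props
  data_lines <- lines[seq(end + 1, length.out = n)]
  if (n == 0) return(point_cloud())
  toks <- strsplit(trimws(data_lines), "\\s+")
  vals <- suppressWarnings(lapply(toks, as.numeric))
  bad <- vapply(vals, function(v) anyNA(v) || length(v) < length(props),
                logical(1))
  if (any(bad)) {
    abort(paste0("malformed PLY vertex record on line ",
                 end + which(bad)[1], " of ", basename(path)))
  }
  m <- do.call(rbind, vals)
  if (has_label) {
    point_cloud(m[, 1], m[, 2], m[, 3], label = m[, match("label", props)])
  } else {
    point_cloud(m[, 1], m[, 2], m[, 3])
  }
}

write_ply <- function(cloud, path) {
  has_label <- "label" %in% names(cloud)
  header <- c(
    "ply",
    "format ascii 1.0",
    paste("element vertex", nrow(cloud)),
    "property double x",
    "property double y",
    "property double z",
    if (has_label) "property int label",
    "end_header")
  rows <- if (nrow(cloud) == 0) character() else {
    r <- paste(fmt_coord(cloud$x), fmt_coord(cloud$y), fmt_coord(cloud$z))
    if (has_label) r <- paste(r, cloud[["label"]])
    r
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

# ---- PCD ------------------------------------------------------------------

read_pcd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^DATA\\s", lines)
  if (length(hdr_idx) == 0) abort("PCD file has no DATA line.")
  hdr_idx <- hdr_idx[1]
  mode <- trimws(sub("^DATA\\s+", "", lines[hdr_idx]))
  if (mode != "ascii") {
    abort("only 'DATA ascii' PCD files are supported; binary PCD rejected.")
  }
  fields_line <- grep("^FIELDS\\s", lines[seq_len(hdr_idx)], value = TRUE)
  if (length(fields_line) != 1) abort("PCD header must have one FIELDS line.")
  fields <- strsplit(trimws(sub("^FIELDS\\s+", "", fields_line)), "\\s+")[[1]]
  if (!identical(fields[1:3], c("x", "y", "z"))) {
    abort("PCD fields must start with x y z.")
  }
  has_label <- "label" %in% fields
  pts_line <- grep("^POINTS\\s", lines[seq_len(hdr_idx)], value = TRUE)
  n <- as.integer(sub("^POINTS\\s+", "", pts_line[1]))
  if (n == 0) return(point_cloud())
  data_lines <- lines[seq(hdr_idx + 1, length.out = n)]
  toks <- strsplit(trimws(data_lines), "\\s+")
  vals <- suppressWarnings(lapply(toks, as.numeric))
  bad <- vapply(vals, function(v) anyNA(v) || length(v) < length(fields),
                logical(1))
  if (any(bad)) {
    abort(paste0("malformed PCD record on line ", hdr_idx + which(bad)[1],
                 " of ", basename(path)))
  }
  m <- do.call(rbind, vals)
  if (has_label) {
    point_cloud(m[, 1], m[, 2], m[, 3], label = m[, match("label", fields)])
  } else {
    point_cloud(m[, 1], m[, 2], m[, 3])
  }
}

write_pcd <- function(cloud, path) {
  has_label <- "label" %in% names(cloud)
  fields <- c("x", "y", "z", if (has_label) "label")
  header <- c(
    "# .PCD v0.7 - Point Cloud Data file format",
    "VERSION 0.7",
    paste("FIELDS", paste(fields, collapse = " ")),
    paste("SIZE", paste(c(8, 8, 8, if (has_label) 4), collapse = " ")),
    paste("TYPE", paste(c("F", "F", "F", if (has_label) "I"),
                        collapse = " ")),
    paste("COUNT", paste(rep(1, length(fields)), collapse = " ")),
    paste("WIDTH", nrow(cloud)),
    "HEIGHT 1",
    "VIEWPOINT 0 0 0 1 0 0 0",
    paste("POINTS", nrow(cloud)),
    "DATA ascii")
  rows <- if (nrow(cloud) == 0) character() else {
    r <- paste(fmt_coord(cloud$x), fmt_coord(cloud$y), fmt_coord(cloud$z))
    if (has_label) r <- paste(r, cloud[["label"]])
    r
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

# ---- plot map -------------------------------------------------------------

#' Read a breeding-plot map
#'
#' A plot map is a CSV with header `plot_id,variety,xmin,xmax,ymin,ymax`
#' describing non-overlapping rectangular plot cells in centimetres. Cells
#' use half-open bounds `[xmin, xmax) x [ymin, ymax)` when points are
#' assigned (see [assign_plots()]).
#'
#' @param path Path to the CSV file.
#' @return A tibble with one row per plot cell.
#' @export
read_plot_map <- function(path) {
  pm <- readr::read_csv(path, show_col_types = FALSE)
  validate_plot_map(pm)
}

#' Validate a plot-map data frame
#'
#' @param plots Data frame with columns plot_id, variety, xmin, xmax, ymin,
#'   ymax.
#' @return The validated tibble.
#' @export
validate_plot_map <- function(plots) {
  needed <- c("plot_id", "variety", "xmin", "xmax", "ymin", "ymax")
  missing_cols <- setdiff(needed, names(plots))
  if (length(missing_cols) > 0) {
    abort(paste0("plot map is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(plots$plot_id)) abort("plot ids must be unique.")
  if (any(plots$xmax <= plots$xmin) || any(plots$ymax <= plots$ymin)) {
    abort("each plot cell must have xmax > xmin and ymax > ymin.")
  }
  n <- nrow(plots)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (plots$xmin[i] < plots$xmax[j] && plots$xmin[j] < plots$xmax[i] &&
            plots$ymin[i] < plots$ymax[j] && plots$ymin[j] < plots$ymax[i]) {
          abort(paste0("plot cells overlap: ", plots$plot_id[i], " and ",
                       plots$plot_id[j]))
        }
      }
    }
  }
  tibble::as_tibble(plots)
}
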