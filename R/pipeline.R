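#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end chain (ingest/simulate ->
#' preprocess -> ground -> segment -> traits -> evaluate) with the package
#' defaults. Exactly one of `input` (a point-cloud file) or `scene` (a
#' [scene_spec()] for a synthetic canopy) must be supplied to
#' [run_pipeline()].
#'
#' @param input Optional path to a point-cloud file (xyz/ply/pcd).
#' @param scene Optional [scene_spec()] describing a synthetic scene.
#' @param seed Global random seed (drives RANSAC; and the scene when the
#'   scene spec carries no seed).
#' @param sor_k,sor_std_ratio Statistical outlier removal parameters.
#' @param voxel_edge Voxel down-sampling edge length (cm).
#' @param ransac_threshold,ransac_iterations RANSAC plane parameters.
#' @param ground_margin Soil band removed above the fitted plane (cm).
#' @param cluster_cell,cluster_min_points Plant clustering parameters.
#' @param plant_spacing Nominal in-row plant spacing (cm); used for the
#'   touching-canopy warning and for matching plants to ground truth.
#' @param stem_radius,leaf_cell,leaf_min_points Leaf extraction parameters.
#' @param verbose Print one log line per stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, scene = NULL, seed = 1,
                            sor_k = 20, sor_std_ratio = 2,
                            voxel_edge = 0.5, ransac_threshold = 1,
                            ransac_iterations = 1000, ground_margin = 1,
                            cluster_cell = 5, cluster_min_points = 50,
                            plant_spacing = 28, stem_radius = 2.5,
                            leaf_cell = 2, leaf_min_points = 20,
                            verbose = TRUE) {
  structure(list(
    input = input, scene = scene, seed = seed, sor_k = sor_k,
    sor_std_ratio = sor_std_ratio, voxel_edge = voxel_edge,
    ransac_threshold = ransac_threshold,
    ransac_iterations = ransac_iterations, ground_margin = ground_margin,
    cluster_cell = cluster_cell, cluster_min_points = cluster_min_points,
    plant_spacing = plant_spacing, stem_radius = stem_radius,
    leaf_cell = leaf_cell, leaf_min_points = leaf_min_points,
    verbose = verbose), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; a `scene:` mapping is converted with
#' [scene_spec()]. Configurations round-trip through
#' [write_pipeline_config()].
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown pipeline_config field(s): ",
                 paste(unknown, collapse = ", ")))
  }
  if (!is.null(vals$scene)) vals$scene <- do.call(scene_spec, vals$scene)
  do.call(pipeline_config, vals)
}

#' Write a pipeline configuration to YAML
#'
#' @param config A `pipeline_config`.
#' @param path Destination YAML file.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  vals <- unclass(config)
  if (!is.null(vals$scene)) vals$scene <- unclass(vals$scene)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Run the full phenotyping pipeline
#'
#' Executes, in the acquisition order: ingest (or synthesize) the cloud,
#' statistical outlier removal, voxel down-sampling, RANSAC soil-plane fit,
#' leveling, ground removal, plant segmentation, and trait extraction.
#' Writes to `out_dir`: the preprocessed and segmented clouds
#' (`preprocessed.ply`, `segmented.ply`), the instance table
#' (`instances.csv`), the trait table (`traits.csv`), ground truth (for
#' synthetic scenes), a stage log (`log.txt`) and a `manifest.json`
#' recording version, seed and all parameters. Re-running with the same
#' configuration reproduces identical trait CSVs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output run directory (created if needed).
#' @return Invisibly, a list with `traits`, `instances`, `plane`, the
#'   leveled segmented `cloud`, and (for synthetic scenes) `truth`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    if (isTRUE(config$verbose)) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  truth <- NULL
  cloud <- stage("ingest", {
    if (!is.null(config$scene)) {
      sc <- config$scene
      if (is.null(sc$seed)) sc$seed <- config$seed
      scene <- generate_scene(sc)
      truth <- scene$truth
      write_scene(scene, file.path(out_dir, "scene"))
      say("stage=ingest source=synthetic points=%d plants=%d",
          nrow(scene$cloud), nrow(truth$plants))
      scene$cloud
    } else if (!is.null(config$input)) {
      if (!file.exists(config$input)) {
        abort(paste0("input cloud not found: ", config$input))
      }
      pc <- read_point_cloud(config$input)
      say("stage=ingest source=%s points=%d", config$input, nrow(pc))
      pc
    } else {
      abort("config needs either `input` or `scene`.")
    }
  })

  filtered <- stage("statistical_filter", {
    out <- statistical_outlier_removal(cloud, k = config$sor_k,
                                       std_ratio = config$sor_std_ratio)
    rep <- filter_report(out)
    say("stage=statistical_filter in=%d out=%d", rep$points_before,
        rep$points_after)
    out
  })

  down <- stage("voxel_downsample", {
    out <- voxel_downsample(filtered, config$voxel_edge)
    rep <- filter_report(out)
    say("stage=voxel_downsample edge=%.2f in=%d out=%d retained=%.1f%%",
        config$voxel_edge, rep$points_before, rep$points_after,
        compression_summary(rep))
    out
  })

  plane <- stage("ransac_plane", {
    pl <- ransac_plane(down, distance_threshold = config$ransac_threshold,
                       iterations = config$ransac_iterations,
                       seed = config$seed)
    say("stage=ransac_plane inliers=%d/%d rms=%.3f", pl$n_inliers, pl$n,
        pl$rms)
    pl
  })

  leveled <- stage("level_scene", level_scene(down, plane))
  above <- stage("remove_ground", {
    out <- remove_ground(leveled, plane = NULL, margin = config$ground_margin)
    say("stage=remove_ground in=%d out=%d margin=%.2f", nrow(leveled),
        nrow(out), config$ground_margin)
    out
  })

  segmented <- stage("segment_plants", {
    out <- segment_plants(above, cell_size = config$cluster_cell,
                          min_points = config$cluster_min_points,
                          plant_spacing = config$plant_spacing)
    say("stage=segment_plants instances=%d in=%d",
        nrow(plant_instances(out)), nrow(out))
    out
  })

  traits <- stage("extract_traits", {
    tr <- extract_traits(segmented, ground_level = 0,
                         stem_radius = config$stem_radius,
                         leaf_cell = config$leaf_cell,
                         leaf_min_points = config$leaf_min_points)
    say("stage=extract_traits plants=%d leaves=%d",
        length(unique(tr$plant_id)), sum(!is.na(tr$leaf_id)))
    tr
  })

  write_point_cloud(down, file.path(out_dir, "preprocessed.ply"))
  seg_out <- segmented
  seg_out$label <- seg_out$instance
  write_point_cloud(
    as_point_cloud(seg_out[, c("x", "y", "z", "label")]),
    file.path(out_dir, "segmented.ply"))
  readr::write_csv(plant_instances(segmented),
                   file.path(out_dir, "instances.csv"))
  readr::write_csv(traits, file.path(out_dir, "traits.csv"))
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  manifest <- list(
    package = "phenocloud",
    version = as.character(utils::packageVersion("phenocloud")),
    seed = config$seed,
    parameters = lapply(
      unclass(config)[setdiff(names(unclass(config)), c("scene", "input"))],
      function(v) v),
    synthetic = !is.null(config$scene))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(traits = traits, instances = plant_instances(segmented),
                 plane = plane, cloud = segmented, truth = truth))
}

#' Compare a pipeline run against synthetic ground truth
#'
#' Matches extracted plant instances to true plants by nearest stem base
#' (within half the plant spacing); unmatched plants on either side are
#' excluded and counted. For matched plants, manual-vs-system style
#' statistics (R-squared, RMSE, relative errors) are computed for plant
#' height, and for the per-leaf traits with leaves paired by nearest growth
#' height.
#'
#' @param run_dir A directory written by [run_pipeline()] (needs
#'   `instances.csv` and `traits.csv`), or a list as returned by it.
#' @param truth The `truth` element of a [generate_scene()] result.
#' @param plant_spacing Nominal plant spacing (cm) controlling the matching
#'   radius (default 28).
#' @return A list with `reports` (named list of [eval_report()] per trait),
#'   `matches` (tibble instance_id/plant_id/distance) and
#'   `n_unmatched_truth`, `n_unmatched_extracted`.
#' @export
validate_against_truth <- function(run_dir, truth, plant_spacing = 28) {
  if (is.character(run_dir)) {
    inst_path <- file.path(run_dir, "instances.csv")
    tr_path <- file.path(run_dir, "traits.csv")
    if (!file.exists(inst_path) || !file.exists(tr_path)) {
      abort(paste0("run directory is empty or incomplete: ", run_dir))
    }
    instances <- readr::read_csv(inst_path, show_col_types = FALSE)
    traits <- readr::read_csv(tr_path, show_col_types = FALSE)
  } else {
    instances <- run_dir$instances
    traits <- run_dir$traits
  }
  if (nrow(instances) == 0) abort("no extracted plant instances to validate.")

  # greedy nearest-base matching within half the plant spacing
  radius <- plant_spacing / 2
  cand <- tidyr::expand_grid(i = seq_len(nrow(instances)),
                             j = seq_len(nrow(truth$plants)))
  cand$dist <- sqrt(
    (instances$base_x[cand$i] - truth$plants$base_x[cand$j])^2 +
      (instances$base_y[cand$i] - truth$plants$base_y[cand$j])^2)
  cand <- dplyr::arrange(dplyr::filter(cand, .data$dist <= radius),
                         .data$dist)
  used_i <- logical(nrow(instances)); used_j <- logical(nrow(truth$plants))
  matches <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (used_i[i] || used_j[j]) next
    used_i[i] <- TRUE; used_j[j] <- TRUE
    matches[[length(matches) + 1]] <- tibble::tibble(
      instance_id = instances$instance_id[i],
      plant_id = truth$plants$plant_id[j], distance = cand$dist[r])
  }
  matches <- dplyr::bind_rows(matches)
  if (nrow(matches) == 0) abort("no extracted plant matched the truth.")

  plant_rows <- dplyr::distinct(traits, .data$plant_id,
                                .keep_all = TRUE)
  height_pairs <- dplyr::inner_join(
    matches,
    dplyr::select(plant_rows, instance_id = "plant_id", system = "height_cm"),
    by = "instance_id")
  height_pairs <- dplyr::inner_join(
    height_pairs,
    dplyr::select(truth$plants, "plant_id", manual = "height"),
    by = "plant_id")
  reports <- list(height = eval_report(height_pairs))

  # leaf traits: pair leaves by nearest growth height within 10 cm
  leaf_map <- c(length_cm = "length", width_cm = "width",
                inclination_deg = "inclination",
                growth_height_cm = "growth_height")
  leaf_pairs <- list()
  for (r in seq_len(nrow(matches))) {
    ext <- traits[traits$plant_id == matches$instance_id[r] &
                    !is.na(traits$leaf_id), ]
    tru <- truth$leaves[truth$leaves$plant_id == matches$plant_id[r], ]
    if (nrow(ext) == 0 || nrow(tru) == 0) next
    for (e in seq_len(nrow(ext))) {
      dgh <- abs(tru$growth_height - ext$growth_height_cm[e])
      j <- which.min(dgh)
      if (dgh[j] > 10) next
      leaf_pairs[[length(leaf_pairs) + 1]] <- tibble::tibble(
        trait = names(leaf_map),
        manual = as.numeric(tru[j, leaf_map]),
        system = as.numeric(ext[e, names(leaf_map)]))
      tru <- tru[-j, , drop = FALSE]
      if (nrow(tru) == 0) break
    }
  }
  if (length(leaf_pairs) > 0) {
    lp <- dplyr::bind_rows(leaf_pairs)
    for (tr_name in unique(lp$trait)) {
      reports[[tr_name]] <- eval_report(lp[lp$trait == tr_name, ])
    }
  }
  list(reports = reports, matches = matches,
       n_unmatched_truth = sum(!used_j),
       n_unmatched_extracted = sum(!used_i))
}
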