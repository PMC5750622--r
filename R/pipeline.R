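#' Experiment configuration
#'
#' Describes a full run: the boxes (each a synthetic simulation or an image
#' manifest), the observation days, the processing and analysis parameters,
#' and the output location.
#'
#' @param boxes list of box descriptions. Each box is a list with
#'   \code{box_id}, \code{density} ("D3"/"D4"/"D5"), \code{treatment}
#'   ("C"/"H"/"L"/"PC"), \code{replicate}, and either \code{sim} (a list of
#'   \code{\link{sim_params}} arguments; \code{growth_days} and \code{seed}
#'   are filled from the config) or \code{image_dir} (a directory of
#'   \code{<box>_<side>_<DAP>.png} images). An optional \code{center}
#'   overrides hypocotyl detection and an optional \code{crop}
#'   (\code{c(row_min, row_max, col_min, col_max)}) crops raw images.
#' @param daps observation days, strictly increasing (default
#'   12, 14, 19, 21, 26 DAP).
#' @param processing a \code{\link{canny_params}}.
#' @param geometry list: \code{gel_depth_mm} (default 33),
#'   \code{voxel_size_mm} for synthetic rasterization (default 0.5).
#' @param analysis list: \code{collapse_method} ("outer"/"additive"),
#'   \code{n_sectors} (default 16), \code{exclusion_radius_px} (default 1).
#' @param render list for synthetic boxes: \code{psf_sigma},
#'   \code{noise_sd}, \code{n_artifacts}.
#' @param output_dir where summaries, matrices and figures are written.
#' @param seed master seed; every random stream in the run derives from it.
#' @param keep_images write rendered/processed PNGs (default TRUE).
#' @return an object of class \code{experiment_config}.
#' @export
experiment_config <- function(boxes, daps = c(12, 14, 19, 21, 26),
                              processing = canny_params(),
                              geometry = list(),
                              analysis = list(),
                              render = list(),
                              output_dir = tempfile("rootrose_run_"),
                              seed = 1L, keep_images = TRUE) {
  geometry <- utils::modifyList(list(gel_depth_mm = 33.0,
                                     voxel_size_mm = 0.5), geometry)
  analysis <- utils::modifyList(list(collapse_method = "outer",
                                     n_sectors = 16L,
                                     exclusion_radius_px = 1), analysis)
  render <- utils::modifyList(list(psf_sigma = 0.5, noise_sd = 0.02,
                                   n_artifacts = 0L), render)
  ids <- vapply(boxes, function(b) as.character(b$box_id), character(1))
  if (anyDuplicated(ids)) stop_field("boxes", "box ids must be unique")
  if (is.unsorted(daps, strictly = TRUE))
    stop_field("daps", "must be strictly increasing")
  for (b in boxes) {
    if (is.null(b$sim) && is.null(b$image_dir))
      stop_field("boxes", sprintf(
        "box '%s' needs either `sim` params or an `image_dir`", b$box_id))
  }
  structure(list(boxes = boxes, daps = as.numeric(daps),
                 processing = processing, geometry = geometry,
                 analysis = analysis, render = render,
                 output_dir = output_dir, seed = as.integer(seed),
                 keep_images = isTRUE(keep_images)),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the arguments of
#'   \code{\link{experiment_config}} (\code{processing} given as a list of
#'   \code{\link{canny_params}} arguments).
#' @return an \code{experiment_config}.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  experiment_config(
    boxes = y$boxes,
    daps = if (is.null(y$daps)) c(12, 14, 19, 21, 26) else y$daps,
    processing = do.call(canny_params,
                         if (is.null(y$processing)) list() else y$processing),
    geometry = if (is.null(y$geometry)) list() else y$geometry,
    analysis = if (is.null(y$analysis)) list() else y$analysis,
    render = if (is.null(y$render)) list() else y$render,
    output_dir = if (is.null(y$output_dir)) tempfile("rootrose_run_")
                 else y$output_dir,
    seed = if (is.null(y$seed)) 1L else y$seed,
    keep_images = if (is.null(y$keep_images)) TRUE else y$keep_images)
}

# sim_params for one synthetic box under the run's master seed.
box_sim_params <- function(config, box, box_index) {
  args <- if (is.null(box$sim) || isTRUE(box$sim)) list() else box$sim
  if (is.null(args$growth_days)) args$growth_days <- config$daps
  if (is.null(args$seed)) args$seed <- sub_seed(config$seed, 100L, box_index)
  if (is.null(args$box_depth_mm)) args$box_depth_mm <- config$geometry$gel_depth_mm
  do.call(sim_params, args)
}

#' Crop an intensity image
#'
#' @param image an \code{\link{intensity_image}}.
#' @param rect \code{c(row_min, row_max, col_min, col_max)}, 1-based
#'   inclusive.
#' @return the cropped \code{intensity_image}.
#' @export
crop_image <- function(image, rect) {
  px <- image$pixels
  if (is.matrix(px)) px <- px[rect[1]:rect[2], rect[3]:rect[4], drop = FALSE]
  else px <- px[rect[1]:rect[2], rect[3]:rect[4], , drop = FALSE]
  intensity_image(px, image$metadata)
}

# One JSON log line per processing event.
log_event <- function(con, ...) {
  if (is.null(con)) return(invisible())
  writeLines(jsonlite::toJSON(list(...), auto_unbox = TRUE, digits = NA,
                              null = "null"), con)
}

# Render the four synthetic views of one (box, dap); returns list of
# intensity_images keyed by side plus the voxel grid and system.
synth_views <- function(config, params, dap, box_index, dap_index) {
  sys <- simulate_root_system(params, dap)
  vox <- rasterize(sys, config$geometry$voxel_size_mm)
  sides <- c("A", "B", "C", "D")
  imgs <- lapply(seq_along(sides), function(i) {
    sk <- project_view(vox, sides[i])
    render_fluorescence(sk,
                        psf_sigma = config$render$psf_sigma,
                        noise_sd = config$render$noise_sd,
                        n_artifacts = config$render$n_artifacts,
                        seed = sub_seed(config$seed, 200L, box_index,
                                        dap_index, i))
  })
  names(imgs) <- sides
  list(system = sys, voxels = vox, images = imgs)
}

# Process four single-channel images into summary statistics + artifacts.
analyse_views <- function(imgs, config, center_override = NULL,
                          out_prefix = NULL, logcon = NULL) {
  depth_mm <- config$geometry$gel_depth_mm
  skels <- lapply(names(imgs), function(sd) {
    raw <- canny_skeleton(imgs[[sd]], config$processing, side = sd,
                          depth_calibration_mm = depth_mm)
    cl <- clean_skeleton(raw, config$processing, image = imgs[[sd]])
    log_event(logcon, event = "skeleton", side = sd,
              raw_px = sum(raw$mask), kept_px = sum(cl$mask),
              removed_px = max(0, sum(raw$mask) - sum(cl$mask)))
    cl
  })
  names(skels) <- names(imgs)
  xy <- combine_opposing_views(skels$A, skels$C)
  zy <- combine_opposing_views(skels$B, skels$D)
  profile <- vertical_profile(xy, zy)
  center <- locate_center(xy, zy, override = center_override)
  log_event(logcon, event = "center", x0 = center[1], z0 = center[2],
            overridden = !is.null(center_override))
  xz <- collapse_to_xz(xy, zy, method = config$analysis$collapse_method,
                       center = center)
  ang <- polar_transform(xz, config$analysis$exclusion_radius_px)
  vs <- vertical_stats(profile)
  cs <- circular_stats(ang)
  wr <- windrose(ang, config$analysis$n_sectors)
  if (!is.null(out_prefix)) {
    write_profile_tsv(profile, paste0(out_prefix, "_profile.tsv"))
    write_matrix_tsv(xy, paste0(out_prefix, "_xy.tsv"))
    write_matrix_tsv(zy, paste0(out_prefix, "_zy.tsv"))
    write_matrix_tsv(xz, paste0(out_prefix, "_xz.tsv"))
    write_angles_tsv(ang, paste0(out_prefix, "_angles.tsv"))
    plot_windrose(wr, paste0(out_prefix, "_windrose.png"))
    plot_xz_heatmap(xz, paste0(out_prefix, "_heatmap.png"))
    if (config$keep_images)
      for (sd in names(skels))
        write_skeleton_png(skels[[sd]], paste0(out_prefix, "_skel_", sd, ".png"))
  }
  list(skeletons = skels, profile = profile, xz = xz, angles = ang,
       vertical = vs, circular = cs, windrose = wr)
}

na_record <- function(box, dap) {
  data.frame(box_id = as.character(box$box_id), density = box$density,
             treatment = box$treatment, replicate = box$replicate,
             dap = dap, location_of_max_mm = NA_real_, skewness = NA_real_,
             kurtosis = NA_real_, rayleigh_rbar = NA_real_,
             rayleigh_p = NA_real_, watson_u2 = NA_real_,
             watson_p = NA_character_, mean_direction_rad = NA_real_,
             total_root_pixels = NA_real_, stringsAsFactors = FALSE)
}

#' Run the full experiment pipeline
#'
#' For every (box, day): obtain the four face images (simulated and rendered,
#' or read from the box's image directory), digitize them to cleaned root
#' skeletons, combine opposing views into the XY and ZY matrices, derive the
#' depth profile and overhead XZ matrix, and compute the vertical and
#' circular statistics. Writes per-stage TSV matrices, windrose and heatmap
#' figures, a JSON-lines processing log, and the summary CSV
#' (\code{summary.csv}; one row per box and day, angles in radians, '.'
#' decimal). A failing (box, day) yields a row of NA statistics and the run
#' continues; the number of failures is attached as attribute
#' \code{n_failed}.
#'
#' @param config an \code{\link{experiment_config}}.
#' @return the summary \code{data.frame}, invisibly; attributes
#'   \code{n_failed} and \code{output_dir}.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(config$output_dir, "run_log.jsonl"), "w")
  on.exit(close(logcon))
  records <- list()
  n_failed <- 0L
  for (bi in seq_along(config$boxes)) {
    box <- config$boxes[[bi]]
    box_dir <- file.path(config$output_dir, as.character(box$box_id))
    dir.create(box_dir, recursive = TRUE, showWarnings = FALSE)
    params <- if (!is.null(box$sim)) box_sim_params(config, box, bi) else NULL
    for (di in seq_along(config$daps)) {
      dap <- config$daps[di]
      rec <- tryCatch({
        center_override <- box$center
        if (!is.null(params)) {
          sv <- synth_views(config, params, dap, bi, di)
          imgs <- sv$images
          if (is.null(center_override))  # hypocotyl position is known
            center_override <- params$origin_xz /
              config$geometry$voxel_size_mm + 0.5
          if (config$keep_images)
            for (sd in names(imgs))
              png::writePNG(imgs[[sd]]$pixels,
                            file.path(box_dir, sprintf("%s_%s_%d.png",
                                                       box$box_id, sd, dap)))
        } else {
          imgs <- lapply(c("A", "B", "C", "D"), function(sd) {
            p <- file.path(box$image_dir,
                           sprintf("%s_%s_%d.png", box$box_id, sd, dap))
            im <- read_image(p)
            im <- extract_green_signal(im)
            if (!is.null(box$crop)) im <- crop_image(im, box$crop)
            im
          })
          names(imgs) <- c("A", "B", "C", "D")
        }
        res <- analyse_views(imgs, config,
                             center_override = center_override,
                             out_prefix = file.path(box_dir,
                                                    sprintf("%s_%d",
                                                            box$box_id, dap)),
                             logcon = logcon)
        vs <- res$vertical; cs <- res$circular
        log_event(logcon, event = "record", box = as.character(box$box_id),
                  dap = dap, total_px = vs$total_weight)
        data.frame(box_id = as.character(box$box_id), density = box$density,
                   treatment = box$treatment, replicate = box$replicate,
                   dap = dap,
                   location_of_max_mm = vs$location_of_max_mm,
                   skewness = vs$skewness, kurtosis = vs$kurtosis,
                   rayleigh_rbar = cs$rayleigh_rbar,
                   rayleigh_p = cs$rayleigh_p,
                   watson_u2 = cs$watson_u2, watson_p = cs$watson_p,
                   mean_direction_rad = cs$mean_direction_rad,
                   total_root_pixels = vs$total_weight,
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        log_event(logcon, event = "failure", box = as.character(box$box_id),
                  dap = dap, message = conditionMessage(e))
        n_failed <<- n_failed + 1L
        na_record(box, dap)
      })
      records[[length(records) + 1L]] <- rec
    }
  }
  summary <- do.call(rbind, records)
  utils::write.csv(summary, file.path(config$output_dir, "summary.csv"),
                   row.names = FALSE)
  attr(summary, "n_failed") <- n_failed
  attr(summary, "output_dir") <- config$output_dir
  invisible(summary)
}

#' Generate a synthetic image fixture on disk
#'
#' Writes the directory tree \code{\link{run_experiment}} expects for its
#' image-manifest mode: one PNG per (box, day, side) named
#' \code{<box>_<side>_<DAP>.png} under \code{<output_dir>/<box>/}, plus
#' per-(box, day) ground-truth depth-profile and angle TSVs derived from the
#' underlying voxel grids. A full study-scale fixture (16 boxes x 5 days x
#' 4 sides) therefore emits 320 images.
#'
#' @param config an \code{\link{experiment_config}} whose boxes all carry
#'   \code{sim} parameters.
#' @return character vector of the written image paths, invisibly; the
#'   ground-truth files sit alongside them.
#' @export
generate_fixture <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  paths <- character(0)
  for (bi in seq_along(config$boxes)) {
    box <- config$boxes[[bi]]
    if (is.null(box$sim))
      stop_field("boxes", sprintf("box '%s' has no synthetic params",
                                  box$box_id))
    params <- box_sim_params(config, box, bi)
    box_dir <- file.path(config$output_dir, as.character(box$box_id))
    dir.create(box_dir, recursive = TRUE, showWarnings = FALSE)
    for (di in seq_along(config$daps)) {
      dap <- config$daps[di]
      sv <- synth_views(config, params, dap, bi, di)
      for (sd in names(sv$images)) {
        p <- file.path(box_dir, sprintf("%s_%s_%d.png", box$box_id, sd, dap))
        png::writePNG(sv$images[[sd]]$pixels, p)
        paths <- c(paths, p)
      }
      write_profile_tsv(ground_truth_vertical_profile(sv$voxels),
                        file.path(box_dir, sprintf("%s_gt_profile_%d.tsv",
                                                   box$box_id, dap)))
      ctr <- params$origin_xz / sv$voxels$voxel_size_mm + 0.5
      write_angles_tsv(ground_truth_angles(sv$voxels, ctr),
                       file.path(box_dir, sprintf("%s_gt_angles_%d.tsv",
                                                  box$box_id, dap)))
    }
  }
  invisible(paths)
}
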