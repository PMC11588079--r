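#' Default pipeline configuration
#'
#' A nested list of every stage parameter at its published default:
#' model parameters, synthetic-generator settings, brightfield and
#' confocal processing kernels, graph clean-up radii, and tracking
#' settings. All randomness derives from the single top-level `seed`
#' through fixed per-stage offsets, so any stage is reproducible in
#' isolation.
#'
#' @return A named list; override entries and pass to the `run_*`
#'   orchestrators, or supply a YAML file with the same structure.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    model = unclass(lunula_params()),
    protocol = list(irradiance = c(10, 0.2), duration = c(15, 30)),
    synthetic = list(
      length_um = 100, width_um = 25, core_fraction = 0.6, pixel_size = 0.5,
      n_nodes = 60, axis_bias = 1.5, tube_radius_um = 1.2,
      slab_depth_um = 8, strain_rate = 0.35, core_diffusivity = 0.5,
      n_frames = 10, frame_interval_s = 12, noise_sd_trace = 0.05,
      absorption = 0.7),
    imaging = list(voxel_size_um = c(x = 0.5, y = 0.5, z = 1),
                   attenuation_um = 20, background_level = 10,
                   noise_sd = 2, amplitude = 100),
    brightfield = list(sigma_px = 21, close_diameter_px = 51),
    confocal = list(min_voxels = 20000, blur_sigma_px = 1,
                    tophat_um = c(2.8, 2.8, 1), closing_um = c(1, 1, 1)),
    graph = list(merge_px = 5, prune_px = 9),
    tracking = list(search_window_um = c(6, 6, 2), memory = 4,
                    adaptive_floor = 0.1, min_steps = 9,
                    sg_window_s = 37.5, sg_poly_order = 2),
    fit = list(free = c("tau_kv", "tau1"), n_boot = 0)
  )
}

#' Load a configuration, merging user values over the defaults
#'
#' @param config `NULL` (defaults), a YAML file path, or a nested list;
#'   entries override [default_config()] recursively.
#' @return The resolved configuration list.
#' @export
load_config <- function(config = NULL) {
  base <- default_config()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  merge_into <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_into(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  merge_into(base, config)
}

resolve_out_dir <- function(out_dir, overwrite) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite)
    stop("output directory ", out_dir,
         " exists and is not empty (use overwrite = TRUE)", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out_dir
}

write_log <- function(lines, out_dir, verbose) {
  writeLines(lines, file.path(out_dir, "run.log"))
  if (verbose) message(paste(lines, collapse = "\n"))
  invisible(lines)
}

#' Generate a complete synthetic dataset
#'
#' Builds the cell geometry and ground-truth reticulum, advects it
#' through the contraction field, renders the confocal volume series and
#' a model-driven brightfield series, and writes everything -- volumes,
#' brightfield TIFF, ground-truth node positions and edges, the
#' area/loss trace, and the fully resolved configuration -- to
#' `out_dir`. Byte-identical outputs for identical configurations.
#'
#' @param config See [load_config()].
#' @param out_dir Output directory.
#' @param overwrite Allow writing into a non-empty directory.
#' @param verbose Emit progress messages.
#' @return Invisibly, a list with the in-memory objects (`geometry`,
#'   `reticulum`, `tracks`, `volumes`, `brightfield`, `trace`).
#' @export
run_synthetic <- function(config = NULL, out_dir, overwrite = FALSE,
                          verbose = FALSE) {
  cfg <- load_config(config)
  out_dir <- resolve_out_dir(out_dir, overwrite)
  sy <- cfg$synthetic
  params <- do.call(model_params, cfg$model)
  protocol <- light_protocol(cfg$protocol$irradiance, cfg$protocol$duration)

  geometry <- make_cell_geometry(sy$length_um, sy$width_um, sy$core_fraction,
                                 sy$pixel_size)
  reticulum <- sample_reticulum(geometry, n_nodes = sy$n_nodes,
                                axis_bias = sy$axis_bias,
                                tube_radius = sy$tube_radius_um,
                                seed = cfg$seed + 101L,
                                slab_depth_um = sy$slab_depth_um)
  field <- motion_field(strain_rate = sy$strain_rate,
                        center = c(geometry$core_centroid_um,
                                   sy$slab_depth_um / 2),
                        core_diffusivity = sy$core_diffusivity,
                        seed = cfg$seed + 202L)
  times <- (seq_len(sy$n_frames) - 1) * sy$frame_interval_s / 60
  tracks <- advect_network(reticulum, field, times, geometry)

  imaging <- imaging_spec(voxel_size_um = unlist(cfg$imaging$voxel_size_um),
                          attenuation_um = cfg$imaging$attenuation_um,
                          frame_interval_s = sy$frame_interval_s,
                          background_level = cfg$imaging$background_level,
                          noise_sd = cfg$imaging$noise_sd,
                          amplitude = cfg$imaging$amplitude,
                          seed = cfg$seed + 303L)
  volumes <- render_confocal_series(tracks, reticulum, imaging)
  trace <- simulate_area_trace(params, protocol,
                               noise_sd = sy$noise_sd_trace,
                               seed = cfg$seed + 404L)
  brightfield <- render_brightfield_series(geometry, trace, imaging,
                                           absorption = sy$absorption)

  write_volume_series(volumes, out_dir, "confocal")
  write_brightfield_tiff(brightfield, file.path(out_dir, "brightfield.tif"))
  utils::write.csv(tracks, file.path(out_dir, "truth_nodes.csv"),
                   row.names = FALSE)
  utils::write.csv(reticulum$edges, file.path(out_dir, "truth_edges.csv"),
                   row.names = FALSE)
  write_trace_csv(trace, file.path(out_dir, "trace.csv"))
  yaml::write_yaml(cfg, file.path(out_dir, "config_resolved.yaml"))
  write_log(c(
    sprintf("synthetic dataset: %d nodes, %d edges, beta1 = %d",
            nrow(reticulum$nodes), nrow(reticulum$edges),
            graph_beta1(reticulum)),
    sprintf("frames: %d confocal volumes (%s voxels), %d brightfield frames",
            sy$n_frames, paste(dim(volumes$frames[[1]]), collapse = "x"),
            length(brightfield$frames)),
    sprintf("seed: %d", cfg$seed)), out_dir, verbose)
  invisible(list(geometry = geometry, reticulum = reticulum, tracks = tracks,
                 volumes = volumes, brightfield = brightfield, trace = trace,
                 config = cfg))
}

#' Run the confocal analysis chain on a volume series
#'
#' Depth-attenuation fit (first frame, reused), correction, segmentation,
#' per-frame mask topology, skeleton-graph extraction and clean-up,
#' network metrics, node tracking, trajectory filtering, and MSD curves.
#' Writes per-frame topology and graph tables, trajectory and MSD CSVs, a
#' stage-count log, and the resolved configuration.
#'
#' @param config See [load_config()].
#' @param input_dir Directory with a volume series written by
#'   [write_volume_series()] (prefix `confocal`).
#' @param out_dir Output directory.
#' @param overwrite Allow writing into a non-empty directory.
#' @param verbose Emit progress messages.
#' @return Invisibly: list with `topology` (data frame), `graphs`,
#'   `trajectories`, `msd`.
#' @export
run_confocal <- function(config = NULL, input_dir, out_dir,
                         overwrite = FALSE, verbose = FALSE) {
  cfg <- load_config(config)
  if (!dir.exists(input_dir) ||
      !file.exists(file.path(input_dir, "confocal_meta.json")))
    stop("input_dir does not contain a confocal volume series", call. = FALSE)
  out_dir <- resolve_out_dir(out_dir, overwrite)
  vs <- read_volume_series(input_dir, "confocal")
  vsz <- vs$voxel_size_um
  log_lines <- character(0)

  att <- fit_depth_attenuation(vs$frames[[1]], vsz)
  log_lines <- c(log_lines, sprintf(
    "attenuation fit: I0 = %.3f, lambda = %.2f um%s", att$I0, att$lambda_um,
    if (att$flat) " (flat profile: identity correction)" else ""))

  topo <- list(); graphs <- list(); clouds <- list()
  for (f in seq_along(vs$frames)) {
    corr <- correct_volume(vs$frames[[f]], att, vsz)
    seg <- segment_volume(corr, vsz, min_voxels = cfg$confocal$min_voxels,
                          blur_sigma_px = cfg$confocal$blur_sigma_px,
                          tophat_um = cfg$confocal$tophat_um,
                          closing_um = cfg$confocal$closing_um)
    tp <- mask_topology(seg$labels > 0)
    g <- skeletonize_to_graph(seg, vsz)
    gs <- simplify_graph(g, merge_px = cfg$graph$merge_px,
                         prune_px = cfg$graph$prune_px,
                         pixel_size_xy = vsz[["x"]])
    graphs[[f]] <- gs
    clouds[[f]] <- node_positions(gs)
    topo[[f]] <- data.frame(frame = f, chi = tp$chi, genus = tp$genus,
                            n_labels = seg$n_labels,
                            voxels = sum(seg$sizes),
                            beta1 = graph_beta1(gs),
                            n_nodes = nrow(gs$nodes),
                            n_edges = nrow(gs$edges))
    log_lines <- c(log_lines, sprintf(
      "frame %d: %d label(s) kept, %d voxels; graph %d -> %d nodes after cleanup",
      f, seg$n_labels, sum(seg$sizes), nrow(g$nodes), nrow(gs$nodes)))
  }
  topo <- do.call(rbind, topo)

  traj <- track_nodes(clouds,
                      search_window_um = cfg$tracking$search_window_um,
                      memory = cfg$tracking$memory,
                      adaptive_floor = cfg$tracking$adaptive_floor,
                      frame_times_s = vs$frame_times_s)
  kept <- filter_trajectories(traj, cfg$tracking$min_steps)
  log_lines <- c(log_lines, sprintf(
    "tracking: %d trajectories, %d kept (>= %d steps), %d rejected",
    length(unique(traj$traj_id)), length(unique(kept$traj_id)),
    cfg$tracking$min_steps,
    length(unique(traj$traj_id)) - length(unique(kept$traj_id))))

  msd <- do.call(rbind, lapply(unique(kept$traj_id), function(id) {
    m <- msd_curve(kept[kept$traj_id == id, ])
    if (nrow(m)) cbind(traj_id = id, m) else NULL
  }))

  utils::write.csv(topo, file.path(out_dir, "topology.csv"),
                   row.names = FALSE)
  for (f in seq_along(graphs))
    write_graph_csv(graphs[[f]], file.path(out_dir, sprintf("graph_t%04d", f)))
  utils::write.csv(traj, file.path(out_dir, "trajectories.csv"),
                   row.names = FALSE)
  if (!is.null(msd))
    utils::write.csv(msd, file.path(out_dir, "msd.csv"), row.names = FALSE)
  yaml::write_yaml(cfg, file.path(out_dir, "config_resolved.yaml"))
  write_log(log_lines, out_dir, verbose)
  invisible(list(topology = topo, graphs = graphs, trajectories = traj,
                 trajectories_kept = kept, msd = msd, attenuation = att))
}

#' Fit the response model to measured or synthetic traces
#'
#' Reads area/loss trace CSVs, fits the requested free parameters per
#' trace ([fit_trace()]), and summarizes the population (mean and SD per
#' parameter) together with the dose-response of maximal contraction
#' versus stimulus irradiance when three or more traces are supplied.
#'
#' @param config See [load_config()]; `config$fit$free` selects the free
#'   parameters and `config$protocol` the driving protocol.
#' @param trace_paths Character vector of trace CSV paths.
#' @param out_dir Output directory.
#' @param overwrite Allow writing into a non-empty directory.
#' @param verbose Emit progress messages.
#' @return Invisibly: list with `fits`, `summary` (data frame), and
#'   `dose` (or `NULL`).
#' @export
run_fit <- function(config = NULL, trace_paths, out_dir, overwrite = FALSE,
                    verbose = FALSE) {
  cfg <- load_config(config)
  if (length(trace_paths) < 1) stop("need at least one trace", call. = FALSE)
  out_dir <- resolve_out_dir(out_dir, overwrite)
  params <- do.call(model_params, cfg$model)
  protocol <- light_protocol(cfg$protocol$irradiance, cfg$protocol$duration)

  traces <- lapply(trace_paths, read_trace_csv)
  fits <- lapply(traces, function(tr)
    fit_trace(tr, protocol, free = cfg$fit$free, init = params,
              n_boot = cfg$fit$n_boot))
  est <- do.call(rbind, lapply(fits, function(f) f$estimates))
  summ <- data.frame(
    param = colnames(est),
    mean = colMeans(est, na.rm = TRUE),
    sd = if (nrow(est) > 1) apply(est, 2, stats::sd, na.rm = TRUE)
         else NA_real_,
    n = colSums(!is.na(est)))
  dose <- NULL
  if (length(traces) >= 3) {
    irr <- vapply(traces, function(tr)
      max(tr$irradiance_mW_cm2, na.rm = TRUE), numeric(1))
    dose <- tryCatch(dose_response(traces, irr), error = function(e) NULL)
  }
  jsonlite::write_json(
    list(fits = lapply(fits, function(f)
      list(estimates = as.list(f$estimates), rss = f$residual_rss,
           degenerate = f$degenerate)),
      summary = summ,
      dose = if (!is.null(dose)) list(irradiances = dose$irradiances,
                                      delta_a_max = dose$delta_a_max,
                                      pearson_rho = dose$pearson_rho)),
    file.path(out_dir, "fit_report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "columns")
  yaml::write_yaml(cfg, file.path(out_dir, "config_resolved.yaml"))
  write_log(c(sprintf("fitted %d trace(s); free: %s", length(fits),
                      paste(cfg$fit$free, collapse = ", ")),
              utils::capture.output(print(summ))), out_dir, verbose)
  invisible(list(fits = fits, summary = summ, dose = dose))
}
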