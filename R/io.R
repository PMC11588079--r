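#' Write a volume series as multi-page TIFFs with a metadata sidecar
#'
#' Each frame becomes one multi-page 16-bit TIFF (`<prefix>_t0001.tif`,
#' one page per z-plane); voxel size, frame times and the intensity scale
#' go to `<prefix>_meta.json`, which [read_volume_series()] uses to
#' restore calibrated intensities.
#'
#' @param vs A `volume_series` (from [render_confocal_series()]).
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return The metadata path, invisibly.
#' @export
write_volume_series <- function(vs, dir, prefix = "vol") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  scale <- max(1e-12, max(vapply(vs$frames, max, numeric(1))))
  paths <- character(length(vs$frames))
  for (f in seq_along(vs$frames)) {
    vol <- vs$frames[[f]] / scale
    pages <- lapply(seq_len(dim(vol)[3]), function(z) t(vol[, , z]))
    paths[f] <- file.path(dir, sprintf("%s_t%04d.tif", prefix, f))
    tiff::writeTIFF(pages, paths[f], bits.per.sample = 16L)
  }
  meta <- list(prefix = prefix, n_frames = length(vs$frames),
               dim_xyz = dim(vs$frames[[1]]),
               voxel_size_um = as.list(vs$voxel_size_um),
               frame_times_s = vs$frame_times_s,
               origin_um = vs$origin_um, intensity_scale = scale)
  mp <- file.path(dir, paste0(prefix, "_meta.json"))
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' @rdname write_volume_series
#' @param dir Directory holding the TIFFs and sidecar.
#' @export
read_volume_series <- function(dir, prefix = "vol") {
  mp <- file.path(dir, paste0(prefix, "_meta.json"))
  if (!file.exists(mp))
    stop("missing metadata sidecar: ", mp, call. = FALSE)
  meta <- jsonlite::read_json(mp, simplifyVector = TRUE)
  frames <- vector("list", meta$n_frames)
  for (f in seq_len(meta$n_frames)) {
    path <- file.path(dir, sprintf("%s_t%04d.tif", prefix, f))
    if (!file.exists(path))
      stop("missing volume file: ", path, " (frame ", f, ")", call. = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    vol <- array(0, dim = c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages)))
    for (z in seq_along(pages)) vol[, , z] <- t(pages[[z]])
    frames[[f]] <- vol * meta$intensity_scale
  }
  vsz <- unlist(meta$voxel_size_um)
  structure(list(frames = frames, voxel_size_um = vsz,
                 frame_times_s = meta$frame_times_s,
                 origin_um = meta$origin_um),
            class = "volume_series")
}

#' Write or read a brightfield series as a multi-page TIFF
#'
#' One page per time point, 16-bit, with an intensity scale and frame
#' times in a JSON sidecar.
#'
#' @param bs A `brightfield_series` (or list of `[x, y]` matrices).
#' @param path Output TIFF path (sidecar gets `.json` appended).
#' @param times_min Frame times when `bs` is a bare list.
#' @export
write_brightfield_tiff <- function(bs, path, times_min = NULL) {
  frames <- if (inherits(bs, "brightfield_series")) bs$frames else bs
  if (inherits(bs, "brightfield_series")) times_min <- bs$times_min
  scale <- max(1e-12, max(vapply(frames, max, numeric(1))))
  tiff::writeTIFF(lapply(frames, function(f) t(f) / scale), path,
                  bits.per.sample = 16L)
  jsonlite::write_json(list(times_min = times_min, intensity_scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_brightfield_tiff
#' @export
read_brightfield_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta_path <- paste0(path, ".json")
  scale <- 1; times <- seq_along(pages) - 1
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    scale <- meta$intensity_scale
    if (!is.null(meta$times_min)) times <- meta$times_min
  }
  structure(list(frames = lapply(pages, function(p) t(p) * scale),
                 times_min = times),
            class = "brightfield_series")
}
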