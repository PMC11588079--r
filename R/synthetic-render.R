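#' Imaging model for rendered synthetic data
#'
#' @param voxel_size_um Named voxel size `c(x=, y=, z=)` (um).
#' @param attenuation_um Depth-attenuation length `lambda` of the
#'   Beer-Lambert factor `exp(-z/lambda)` (um).
#' @param frame_interval_s Time between frames (s).
#' @param background_level Detector background offset (intensity units).
#' @param noise_sd Additive Gaussian detector noise SD.
#' @param amplitude Fluorescence amplitude of tube voxels before
#'   attenuation.
#' @param seed Integer seed for the rendering noise.
#' @return An `imaging_spec` list.
#' @export
imaging_spec <- function(voxel_size_um = c(x = 0.5, y = 0.5, z = 1),
                         attenuation_um = 20, frame_interval_s = 12,
                         background_level = 10, noise_sd = 2,
                         amplitude = 100, seed = 1) {
  if (any(voxel_size_um <= 0)) stop("voxel sizes must be > 0", call. = FALSE)
  if (attenuation_um <= 0) stop("attenuation_um must be > 0", call. = FALSE)
  if (frame_interval_s <= 0) stop("frame_interval_s must be > 0", call. = FALSE)
  vs <- voxel_size_um
  if (is.null(names(vs))) names(vs) <- c("x", "y", "z")
  structure(list(voxel_size_um = vs, attenuation_um = attenuation_um,
                 frame_interval_s = frame_interval_s,
                 background_level = background_level, noise_sd = noise_sd,
                 amplitude = amplitude, seed = seed),
            class = "imaging_spec")
}

#' Render a confocal autofluorescence volume series
#'
#' Rasterizes tubes of radius `tube_radius` around every graph edge at the
#' node positions of each frame, applies Beer-Lambert depth attenuation
#' `exp(-z/lambda)` slice by slice, and adds detector background plus
#' Gaussian noise. Physical voxel coordinates put the slab of the
#' reticulum a margin above z = 0 (the coverslip side).
#'
#' @param tracks `node_tracks` from [advect_network()] (or a single-frame
#'   table built from a graph).
#' @param graph The [skeleton_graph()] providing the edge list.
#' @param imaging An [imaging_spec()].
#' @param tube_radius Strand radius (um); defaults to the radius attached
#'   to `graph`. A radius below one xy voxel triggers a partial-volume
#'   warning.
#' @param extent_um Optional list with `x = c(min, max)`, `y = c(min, max)`
#'   physical extents; defaults to the bounding box of all positions plus
#'   a margin.
#' @return A `volume_series` list: `frames` (list of `[x, y, z]` arrays),
#'   `voxel_size_um`, `frame_times_s`, `origin_um`, and the generating
#'   `imaging` spec.
#' @export
render_confocal_series <- function(tracks, graph, imaging = imaging_spec(),
                                   tube_radius = NULL, extent_um = NULL) {
  if (is.null(tube_radius)) tube_radius <- attr(graph, "tube_radius_um")
  if (is.null(tube_radius)) stop("tube_radius is required", call. = FALSE)
  vs <- imaging$voxel_size_um
  if (tube_radius < max(vs["x"], vs["y"]))
    warning("tube radius below one voxel: expect partial-volume effects",
            call. = FALSE)
  set.seed(imaging$seed)

  marg <- 2 * tube_radius + 2 * max(vs)
  if (is.null(extent_um)) {
    extent_um <- list(x = range(tracks$x_um) + c(-marg, marg),
                      y = range(tracks$y_um) + c(-marg, marg))
  }
  z_ext <- range(tracks$z_um) + c(-marg, marg)
  z_ext[1] <- max(z_ext[1], 0)  # z = 0 is the coverslip side
  nx <- ceiling(diff(extent_um$x) / vs["x"]) + 1L
  ny <- ceiling(diff(extent_um$y) / vs["y"]) + 1L
  nz <- ceiling(diff(z_ext) / vs["z"]) + 1L
  org <- c(extent_um$x[1], extent_um$y[1], z_ext[1])
  xs <- org[1] + (seq_len(nx) - 1) * vs["x"]
  ys <- org[2] + (seq_len(ny) - 1) * vs["y"]
  zs <- org[3] + (seq_len(nz) - 1) * vs["z"]
  att <- exp(-pmax(zs, 0) / imaging$attenuation_um)

  frames <- sort(unique(tracks$frame))
  edges <- graph$edges
  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    pos <- frame_positions(tracks, frames[fi])
    vol <- array(0, dim = c(nx, ny, nz))
    for (e in seq_len(nrow(edges))) {
      a <- pos[as.character(edges$from[e]), ]
      b <- pos[as.character(edges$to[e]), ]
      lo <- pmin(a, b) - tube_radius; hi <- pmax(a, b) + tube_radius
      ix <- which(xs >= lo[1] & xs <= hi[1])
      iy <- which(ys >= lo[2] & ys <= hi[2])
      iz <- which(zs >= lo[3] & zs <= hi[3])
      if (!length(ix) || !length(iy) || !length(iz)) next
      gx <- xs[ix]; gy <- ys[iy]; gz <- zs[iz]
      P <- cbind(rep(gx, times = length(iy) * length(iz)),
                 rep(rep(gy, each = length(ix)), times = length(iz)),
                 rep(gz, each = length(ix) * length(iy)))
      ab <- b - a; L2 <- sum(ab^2)
      tpar <- if (L2 == 0) rep(0, nrow(P)) else
        pmin(pmax(((P[, 1] - a[1]) * ab[1] + (P[, 2] - a[2]) * ab[2] +
                     (P[, 3] - a[3]) * ab[3]) / L2, 0), 1)
      dx <- P[, 1] - (a[1] + tpar * ab[1])
      dy <- P[, 2] - (a[2] + tpar * ab[2])
      dz <- P[, 3] - (a[3] + tpar * ab[3])
      hitv <- dx * dx + dy * dy + dz * dz <= tube_radius^2
      if (any(hitv)) {
        sub <- array(vol[ix, iy, iz], dim = c(length(ix), length(iy), length(iz)))
        sub[hitv] <- imaging$amplitude
        vol[ix, iy, iz] <- sub
      }
    }
    vol <- sweep(vol, 3, att, "*")
    vol <- vol + imaging$background_level +
      array(stats::rnorm(length(vol), 0, imaging$noise_sd), dim = dim(vol))
    out[[fi]] <- pmax(vol, 0)
  }
  structure(list(frames = out, voxel_size_um = vs,
                 frame_times_s = (frames - 1) * imaging$frame_interval_s,
                 origin_um = org, imaging = imaging,
                 tube_radius_um = tube_radius),
            class = "volume_series")
}

#' Render a brightfield transmission series from an area trace
#'
#' Emulates the transmitted-light data: a uniform illuminated background
#' in which the chloroplast absorbs a fixed fraction of the light. The
#' absorbing region starts as the whole cell body and shrinks
#' concentrically toward the cytoplasmic core so that its pixel count
#' tracks the driving `A(t)/A0` trace exactly; pixels are ordered by
#' distance from the core centroid, and the core itself is never vacated.
#'
#' @param geometry A [make_cell_geometry()].
#' @param area_trace An `area_loss_trace` (or any data frame with
#'   `time_min` and `relative_area`).
#' @param imaging An [imaging_spec()] (only `background_level`, `noise_sd`
#'   and `seed` are used).
#' @param absorption Fraction of background light absorbed by chloroplast
#'   pixels (1 = fully opaque).
#' @return A `brightfield_series` list: `frames` (list of `[x, y]`
#'   matrices), `times_min`, `geometry`, `absorption`, plus the per-frame
#'   ground-truth `chloro_px` pixel counts.
#' @export
render_brightfield_series <- function(geometry, area_trace,
                                      imaging = imaging_spec(),
                                      absorption = 0.7) {
  set.seed(imaging$seed)
  a_rel <- pmax(pmin(area_trace$relative_area, 1), 0)
  outer_idx <- which(geometry$outer)
  n_outer <- length(outer_idx)
  coords <- mask_coords_um(geometry, geometry$outer)
  d <- sqrt((coords[, 1] - geometry$core_centroid_um[1])^2 +
              (coords[, 2] - geometry$core_centroid_um[2])^2)
  is_core <- geometry$core[outer_idx]
  # removal order: core pixels are kept forever, others leave outermost-first
  ord <- outer_idx[order(is_core, -d, decreasing = TRUE)]
  n_core <- sum(is_core)

  frames <- vector("list", length(a_rel))
  chloro_px <- integer(length(a_rel))
  for (f in seq_along(a_rel)) {
    n_keep <- max(n_core, min(n_outer, round(a_rel[f] * n_outer)), 1L)
    img <- matrix(imaging$background_level, nrow(geometry$outer),
                  ncol(geometry$outer))
    img[ord[seq_len(n_keep)]] <- imaging$background_level * (1 - absorption)
    img <- img + matrix(stats::rnorm(length(img), 0, imaging$noise_sd),
                        nrow(img))
    frames[[f]] <- pmax(img, 0)
    chloro_px[f] <- n_keep
  }
  structure(list(frames = frames, times_min = area_trace$time_min,
                 geometry = geometry, absorption = absorption,
                 imaging = imaging, chloro_px = chloro_px),
            class = "brightfield_series")
}
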