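#' Synthetic crescent cell geometry
#'
#' Builds a raster model of the crescent-shaped *P. lunula* cell as the
#' set difference of two equal-radius discs (a lune): a cell of tip-to-tip
#' length `length_um` and maximal thickness `width_um`, with its major
#' axis along x. A convex cytoplasmic core region (an ellipse intersected
#' with the cell outline, scaled by bisection) occupies a requested
#' fraction of the cell area; the area outside the core is what the
#' chloroplast can vacate, so the default `core_fraction = 0.6` leaves a
#' maximal projected-area contraction of 40%.
#'
#' Masks are logical matrices indexed `[x, y]` (EBImage convention); the
#' mapping to physical coordinates is `x_um = origin_um[1] + (i-1) *
#' pixel_size` and likewise for y.
#'
#' @param length_um Tip-to-tip cell length (um).
#' @param width_um Maximal cell thickness (um); must be < `length_um`.
#' @param core_fraction Requested `|core| / |outer|` in (0, 1); realized
#'   within 3% or an error is raised.
#' @param pixel_size Raster resolution (um/px).
#' @return A `cell_geometry` list: `outer`, `core` (logical matrices),
#'   `pixel_size`, `origin_um`, `major_axis`, `core_area_fraction`
#'   (realized), `centroid_um`, `core_centroid_um`, `area_um2` (raster)
#'   and `area_analytic_um2` (closed-form lune area).
#' @export
make_cell_geometry <- function(length_um = 100, width_um = 25,
                               core_fraction = 0.6, pixel_size = 0.5) {
  if (!(length_um > width_um && width_um > 0))
    stop("need length_um > width_um > 0", call. = FALSE)
  if (core_fraction <= 0 || core_fraction >= 1)
    stop("core_fraction must lie in (0, 1)", call. = FALSE)
  R <- sqrt((length_um / 2)^2 + width_um^2 / 4)
  yc <- width_um  # center offset of the cutting disc (equal radii)

  m <- 3 * pixel_size
  xs <- seq(-(length_um / 2 + m), length_um / 2 + m, by = pixel_size)
  ys <- seq(-(R + m), yc / 2 + m, by = pixel_size)
  X <- matrix(xs, nrow = length(xs), ncol = length(ys))
  Y <- matrix(ys, nrow = length(xs), ncol = length(ys), byrow = TRUE)
  outer_mask <- (X^2 + Y^2 <= R^2) & (X^2 + (Y - yc)^2 > R^2)
  n_outer <- sum(outer_mask)
  if (n_outer < 100)
    stop("raster too coarse for the requested geometry", call. = FALSE)

  # convex core: ellipse about the mid-thickness point, grown by bisection
  # until the requested area fraction is met
  cy <- (-R + (yc - R)) / 2  # mid-thickness at x = 0 (cell bottom is -R)
  core_at <- function(s) {
    a <- s * 0.48 * length_um
    b <- s * 0.5 * width_um
    ((X / a)^2 + ((Y - cy) / b)^2 <= 1) & outer_mask
  }
  lo <- 0.01; hi <- 2
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (sum(core_at(mid)) / n_outer < core_fraction) lo <- mid else hi <- mid
  }
  core_mask <- core_at(hi)
  realized <- sum(core_mask) / n_outer
  if (realized < core_fraction - 0.03) {
    # an inscribed ellipse cannot fill a concave crescent much beyond
    # ~80%; for larger cores peel the outline instead (fraction -> 1)
    erode_by <- function(k) {
      if (k == 0L) return(outer_mask)
      as.matrix(EBImage::erode(EBImage::Image(outer_mask * 1),
                               EBImage::makeBrush(2L * k + 1L, "disc"))) > 0.5
    }
    target_n <- round(core_fraction * n_outer)
    k <- 0L
    while (sum(erode_by(k + 1L)) >= target_n) k <- k + 1L
    inner <- erode_by(k + 1L)
    band <- which(erode_by(k) & !inner)
    need <- target_n - sum(inner)
    core_mask <- inner
    if (need > 0L && length(band) > 0L)
      core_mask[band[seq_len(min(need, length(band)))]] <- TRUE
    realized <- sum(core_mask) / n_outer
  }
  if (abs(realized - core_fraction) > 0.03)
    stop(sprintf(
      "raster too coarse to honor core_fraction: requested %.3f, realized %.3f",
      core_fraction, realized), call. = FALSE)

  lens <- 2 * R^2 * acos(yc / (2 * R)) - yc / 2 * sqrt(4 * R^2 - yc^2)
  structure(list(
    outer = outer_mask, core = core_mask, pixel_size = pixel_size,
    origin_um = c(xs[1], ys[1]), major_axis = c(1, 0),
    core_area_fraction = realized,
    centroid_um = c(mean(X[outer_mask]), mean(Y[outer_mask])),
    core_centroid_um = c(mean(X[core_mask]), mean(Y[core_mask])),
    area_um2 = n_outer * pixel_size^2,
    area_analytic_um2 = pi * R^2 - lens,
    disc_radius_um = R, disc_offset_um = yc
  ), class = "cell_geometry")
}

#' Physical coordinates of mask pixels
#'
#' @param geometry A [make_cell_geometry()] object.
#' @param mask Logical matrix on the geometry raster.
#' @return Two-column matrix of (x_um, y_um) pixel-center coordinates.
#' @keywords internal
mask_coords_um <- function(geometry, mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(geometry$origin_um[1] + (idx[, 1] - 1) * geometry$pixel_size,
        geometry$origin_um[2] + (idx[, 2] - 1) * geometry$pixel_size)
}

um_to_px <- function(geometry, xy_um) {
  cbind(round((xy_um[, 1] - geometry$origin_um[1]) / geometry$pixel_size) + 1L,
        round((xy_um[, 2] - geometry$origin_um[2]) / geometry$pixel_size) + 1L)
}

#' Test whether points fall inside a geometry mask
#'
#' @param geometry A [make_cell_geometry()] object.
#' @param xy_um Two-column matrix of (x_um, y_um) points.
#' @param mask Which mask to test against (`"outer"` or `"core"`).
#' @return Logical vector; points off the raster are `FALSE`.
#' @export
points_in_mask <- function(geometry, xy_um, mask = c("outer", "core")) {
  mask <- match.arg(mask)
  mm <- geometry[[mask]]
  px <- um_to_px(geometry, xy_um)
  ok <- px[, 1] >= 1 & px[, 1] <= nrow(mm) & px[, 2] >= 1 & px[, 2] <= ncol(mm)
  inside <- logical(nrow(px))
  inside[ok] <- mm[cbind(px[ok, 1], px[ok, 2])]
  inside
}
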