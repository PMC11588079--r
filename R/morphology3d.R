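# 3D image primitives: shifted-array min/max morphology, 26-connectivity
# labeling, and cubical-complex Euler characteristics. These operate on
# plain R arrays indexed [x, y, z]; 2D matrices are treated as single-slice
# volumes where it makes sense.

# integer offsets of an axis-aligned ellipsoid structuring element with
# half-extents (rx, ry, rz) in voxels
ellipsoid_offsets <- function(rx, ry, rz) {
  hx <- max(0L, floor(rx)); hy <- max(0L, floor(ry)); hz <- max(0L, floor(rz))
  off <- expand.grid(dx = -hx:hx, dy = -hy:hy, dz = -hz:hz)
  keep <- (off$dx / max(rx, 0.5))^2 + (off$dy / max(ry, 0.5))^2 +
    (off$dz / max(rz, 0.5))^2 <= 1 + 1e-9
  as.matrix(off[keep, , drop = FALSE])
}

# shift a 3D array by integer (dx, dy, dz), padding with `fill`
shift_array <- function(a, dx, dy, dz, fill) {
  d <- dim(a)
  out <- array(fill, dim = d)
  sx <- max(1L, 1L + dx):min(d[1], d[1] + dx)
  sy <- max(1L, 1L + dy):min(d[2], d[2] + dy)
  sz <- max(1L, 1L + dz):min(d[3], d[3] + dz)
  if (length(sx) < 1 || length(sy) < 1 || length(sz) < 1) return(out)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz, drop = FALSE]
  out
}

erode3d <- function(a, offsets) {
  out <- a
  for (i in seq_len(nrow(offsets))) {
    o <- offsets[i, ]
    if (all(o == 0)) next
    out <- pmin(out, shift_array(a, o[1], o[2], o[3], fill = Inf))
  }
  out
}

dilate3d <- function(a, offsets) {
  out <- a
  for (i in seq_len(nrow(offsets))) {
    o <- offsets[i, ]
    if (all(o == 0)) next
    out <- pmax(out, shift_array(a, o[1], o[2], o[3], fill = -Inf))
  }
  out
}

#' White top-hat filter in 3D
#'
#' Image minus its grayscale opening with an axis-aligned ellipsoid
#' structuring element: isolates bright structures smaller than the
#' element.
#'
#' @param vol Numeric array `[x, y, z]`.
#' @param half_extents_vox Ellipsoid half-extents in voxels (x, y, z).
#' @return Array of the same dimension, >= 0.
#' @export
tophat3d <- function(vol, half_extents_vox) {
  off <- ellipsoid_offsets(half_extents_vox[1], half_extents_vox[2],
                           half_extents_vox[3])
  vol - dilate3d(erode3d(vol, off), off)
}

#' Binary closing in 3D
#'
#' Dilation followed by erosion with an ellipsoid structuring element.
#'
#' @param mask Logical array `[x, y, z]`.
#' @param half_extents_vox Ellipsoid half-extents in voxels (x, y, z).
#' @return Logical array.
#' @export
closing3d <- function(mask, half_extents_vox) {
  off <- ellipsoid_offsets(half_extents_vox[1], half_extents_vox[2],
                           half_extents_vox[3])
  a <- array(as.numeric(mask), dim = dim(mask))
  erode3d(dilate3d(a, off), off) > 0.5
}

# the 13 "positive" neighbor offsets of the 26-neighborhood
offsets26_half <- local({
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o <- o[!(o[, 1] == 0 & o[, 2] == 0 & o[, 3] == 0), ]
  o[o[, 3] > 0 | (o[, 3] == 0 & (o[, 2] > 0 | (o[, 2] == 0 & o[, 1] > 0))), ]
})

#' Connected-component labeling of a 3D mask (26-connectivity)
#'
#' @param mask Logical array `[x, y, z]` (a matrix is treated as one
#'   slice).
#' @return Integer array of labels (0 = background), with attribute
#'   `sizes` (voxel count per label, labels sorted by decreasing size and
#'   renumbered contiguously).
#' @export
label3d <- function(mask) {
  d2 <- is.matrix(mask)
  if (d2) mask <- array(mask, dim = c(dim(mask), 1L))
  d <- dim(mask)
  idx <- array(0L, dim = d)
  fg <- which(mask)
  if (length(fg) == 0L) {
    out <- array(0L, dim = d)
    attr(out, "sizes") <- integer(0)
    return(if (d2) out[, , 1] else out)
  }
  idx[fg] <- seq_along(fg)
  ef <- integer(0); et <- integer(0)
  for (i in seq_len(nrow(offsets26_half))) {
    o <- offsets26_half[i, ]
    sh <- shift_array(idx, o[1], o[2], o[3], fill = 0L)
    hit <- which(idx > 0L & sh > 0L)
    if (length(hit)) { ef <- c(ef, idx[hit]); et <- c(et, sh[hit]) }
  }
  g <- igraph::graph_from_edgelist(cbind(ef, et), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_along(fg)]
  sizes <- tabulate(comp)
  ord <- order(sizes, decreasing = TRUE)
  relab <- integer(length(sizes)); relab[ord] <- seq_along(ord)
  lab <- array(0L, dim = d)
  lab[fg] <- relab[comp]
  attr(lab, "sizes") <- sizes[ord]
  if (d2) { s <- attr(lab, "sizes"); lab <- lab[, , 1]; attr(lab, "sizes") <- s }
  lab
}

#' Euler characteristic of a voxel set
#'
#' Computes `chi` of the union of closed unit voxels (pixels in 2D, cubes
#' in 3D) as the alternating sum of cells of the induced cubical complex:
#' vertices - edges + faces (- cubes). This convention connects diagonal
#' foreground voxels (26-adjacency; complement 6-adjacency).
#'
#' @param mask Logical matrix (2D) or array (3D).
#' @return Integer Euler characteristic; 0 for an empty mask.
#' @export
euler_characteristic <- function(mask) {
  if (is.matrix(mask)) mask <- array(mask, dim = c(dim(mask), 1L))
  d <- dim(mask)
  a <- array(FALSE, dim = d + 2L)
  a[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  n3 <- sum(a)
  if (n3 == 0L) return(0L)
  or_shift <- function(arr, offs) {
    out <- arr
    for (i in seq_len(nrow(offs)))
      out <- out | shift_array(arr, offs[i, 1], offs[i, 2], offs[i, 3],
                               fill = FALSE)
    out
  }
  if (d[3] == 1L) {
    # 2D: chi = vertices - edges + pixels
    e_x <- sum(or_shift(a, rbind(c(0, 1, 0))))  # x-parallel, shared in y
    e_y <- sum(or_shift(a, rbind(c(1, 0, 0))))
    n0 <- sum(or_shift(a, rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))))
    return(as.integer(n0 - (e_x + e_y) + n3))
  }
  # 3D: chi = vertices - edges + faces - cubes
  f_x <- sum(or_shift(a, rbind(c(1, 0, 0))))  # faces orthogonal to x
  f_y <- sum(or_shift(a, rbind(c(0, 1, 0))))
  f_z <- sum(or_shift(a, rbind(c(0, 0, 1))))
  e_x <- sum(or_shift(a, rbind(c(0, 1, 0), c(0, 0, 1), c(0, 1, 1))))
  e_y <- sum(or_shift(a, rbind(c(1, 0, 0), c(0, 0, 1), c(1, 0, 1))))
  e_z <- sum(or_shift(a, rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))))
  v_off <- as.matrix(expand.grid(0:1, 0:1, 0:1))[-1, ]
  n0 <- sum(or_shift(a, v_off))
  as.integer(n0 - (e_x + e_y + e_z) + (f_x + f_y + f_z) - n3)
}
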