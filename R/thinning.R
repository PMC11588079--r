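# Topology-preserving 3D thinning by sequential simple-point removal.
# A border voxel is "simple" iff deleting it changes neither the number of
# 26-connected foreground components in its 26-neighborhood nor the number
# of 6-connected background components of its 18-neighborhood that touch
# it face-wise (Bertrand's characterization). Curve endpoints (<= 1
# foreground neighbor) are preserved, yielding a 1-voxel-wide curve
# skeleton; voxels are peeled shallowest-first (by iterative-erosion
# depth) to keep the skeleton medial.

# 3x3x3 neighborhood bookkeeping, built once at load time
.nbhd <- local({
  cells <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  center <- which(rowSums(abs(cells)) == 0)
  n26 <- setdiff(seq_len(27), center)
  n18 <- which(rowSums(abs(cells)) <= 2 & rowSums(abs(cells)) > 0)
  face <- which(rowSums(abs(cells)) == 1)
  adj_of <- function(members, conn) {
    lapply(seq_along(members), function(i) {
      di <- cells[members[i], ]
      hits <- vapply(seq_along(members), function(j) {
        dj <- cells[members[j], ]
        d <- abs(di - dj)
        if (i == j) return(FALSE)
        if (conn == 26) max(d) == 1 else sum(d) == 1
      }, logical(1))
      which(hits)
    })
  }
  list(cells = cells, center = center, n26 = n26, n18 = n18,
       face_in_n18 = match(face, n18),
       adj26 = adj_of(n26, 26), adj6_18 = adj_of(n18, 6))
})

# number of connected components of `present` (logical over member cells)
# under a precomputed adjacency list; optionally only components touching
# `seeds`
.count_components <- function(present, adj, seeds = NULL) {
  todo <- which(present)
  if (length(todo) == 0L) return(0L)
  comp <- integer(length(present))
  nc <- 0L
  for (s in todo) {
    if (comp[s] != 0L) next
    nc <- nc + 1L
    stack <- s
    while (length(stack) > 0) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- nc
      nb <- adj[[v]]
      stack <- c(stack, nb[present[nb] & comp[nb] == 0L])
    }
  }
  if (is.null(seeds)) return(nc)
  length(unique(comp[seeds][present[seeds] & comp[seeds] > 0L]))
}

is_simple_point <- function(nb27) {
  fg26 <- nb27[.nbhd$n26]
  if (.count_components(fg26, .nbhd$adj26) != 1L) return(FALSE)
  bg18 <- !nb27[.nbhd$n18]
  .count_components(bg18, .nbhd$adj6_18, seeds = .nbhd$face_in_n18) == 1L
}

#' Curve skeleton of a 3D binary mask
#'
#' Medial-axis-style thinning: border voxels are deleted one at a time,
#' shallowest first, whenever deletion preserves local topology (simple
#' points) and the voxel is not a curve endpoint. The result has the same
#' number of components, tunnels and cavities as the input.
#'
#' @param mask Logical array `[x, y, z]` (a matrix is treated as a single
#'   slice).
#' @return Logical array of the same dimension containing the skeleton.
#' @export
skeletonize3d <- function(mask) {
  d2 <- is.matrix(mask)
  if (d2) mask <- array(mask, dim = c(dim(mask), 1L))
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask

  # peel depth by iterative 6-erosion (ordering heuristic only)
  depth <- array(0L, dim = dim(pad))
  cur <- pad
  k <- 0L
  while (any(cur)) {
    k <- k + 1L
    depth[cur] <- k
    er <- cur
    for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1)))
      er <- er & shift_array(cur, o[1], o[2], o[3], fill = FALSE)
    if (all(er == cur)) { depth[cur] <- k; break }
    cur <- er
  }

  repeat {
    bg6 <- array(FALSE, dim = dim(pad))
    for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1)))
      bg6 <- bg6 | !shift_array(pad, o[1], o[2], o[3], fill = FALSE)
    cand <- which(pad & bg6)
    if (length(cand) == 0L) break
    cand <- cand[order(depth[cand])]
    dims <- dim(pad)
    removed <- FALSE
    for (v in cand) {
      if (!pad[v]) next
      iz <- (v - 1L) %/% (dims[1] * dims[2])
      rem <- (v - 1L) %% (dims[1] * dims[2])
      iy <- rem %/% dims[1]
      ix <- rem %% dims[1]
      nb <- pad[ix:(ix + 2L), iy:(iy + 2L), iz:(iz + 2L)]
      if (sum(nb) - 1L <= 1L) next  # endpoint
      if (is_simple_point(as.vector(nb))) { pad[v] <- FALSE; removed <- TRUE }
    }
    if (!removed) break
  }
  out <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
  out <- array(out, dim = d)
  if (d2) out[, , 1] else out
}
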