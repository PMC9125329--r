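#' Convert a labeled voxel phantom into a tetrahedral mesh
#'
#' Each occupied voxel is split into 6 tetrahedra (Kuhn subdivision) around
#' the same cube diagonal in every voxel, so faces of adjacent voxels are
#' triangulated compatibly and lattice nodes are shared. The decomposition is
#' volume-exact: the summed tetrahedron volume equals the occupied voxel
#' volume, and every tetrahedron inherits its parent voxel's material label
#' (1 adipose, 2 lesion). Node order is determined by the lattice key, not by
#' traversal order, so meshing is fully deterministic.
#'
#' @param phantom A `breast_phantom` with at least one occupied voxel.
#' @return A `tet_mesh`: `nodes` (n x 3 mm), `tets` (m x 4 node indices,
#'   positively oriented), `labels` (length m), `voxel_of` (parent voxel
#'   linear index per tet), `voxel_mm`, and slots for boundary sets filled by
#'   [classify_boundaries()].
#' @export
voxels_to_tets <- function(phantom) {
  stopifnot(inherits(phantom, "breast_phantom"))
  d <- dim(phantom$labels)
  occ <- which(phantom$labels > 0L)
  if (length(occ) == 0L) {
    stop2("mi_empty_mesh_error", "phantom has no occupied voxel")
  }
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  # 0-based voxel indices
  i0 <- (occ - 1L) %% nx
  j0 <- ((occ - 1L) %/% nx) %% ny
  k0 <- (occ - 1L) %/% (nx * ny)
  NX <- nx + 1L; NY <- ny + 1L
  corner_key <- function(di, dj, dk) {
    (i0 + di) + NX * ((j0 + dj) + NY * (k0 + dk))
  }
  # corners c0..c7 = (0,0,0),(1,0,0),(0,1,0),(1,1,0),(0,0,1),(1,0,1),(0,1,1),(1,1,1)
  corners <- cbind(
    corner_key(0L, 0L, 0L), corner_key(1L, 0L, 0L),
    corner_key(0L, 1L, 0L), corner_key(1L, 1L, 0L),
    corner_key(0L, 0L, 1L), corner_key(1L, 0L, 1L),
    corner_key(0L, 1L, 1L), corner_key(1L, 1L, 1L))
  keys <- sort(unique(as.vector(corners)))
  idx <- matrix(match(corners, keys), nrow = length(occ))
  h <- phantom$voxel_mm
  nodes <- cbind(
    phantom$origin[1] + (keys %% NX) * h,
    phantom$origin[2] + ((keys %/% NX) %% NY) * h,
    phantom$origin[3] + (keys %/% (NX * NY)) * h)
  # Kuhn subdivision around the c0-c7 diagonal; vertex orders chosen so all
  # signed volumes are positive (+h^3/6 each)
  kuhn <- matrix(c(
    1, 2, 4, 8,
    1, 4, 3, 8,
    1, 3, 7, 8,
    1, 7, 5, 8,
    1, 5, 6, 8,
    1, 6, 2, 8), ncol = 4, byrow = TRUE)
  tets <- do.call(rbind, lapply(seq_len(6), function(t) idx[, kuhn[t, ]]))
  ord <- rep(seq_along(occ), times = 6)
  labels <- as.integer(phantom$labels[occ])[ord]
  voxel_of <- occ[ord]
  mesh <- structure(list(
    nodes = nodes, tets = tets, labels = labels, voxel_of = voxel_of,
    voxel_mm = h, chest_nodes = integer(0), surface_nodes = integer(0),
    surface_faces = NULL), class = "tet_mesh")
  vol <- tet_volumes(mesh)
  if (any(vol <= 0)) {
    # orientation fix-up: swap two vertices of any inverted tets
    bad <- which(vol <= 0)
    mesh$tets[bad, c(3, 4)] <- mesh$tets[bad, c(4, 3)]
  }
  mesh
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d nodes, %d tets (%d lesion), voxel %g mm\n",
              nrow(x$nodes), nrow(x$tets), sum(x$labels == 2L), x$voxel_mm))
  invisible(x)
}

#' Signed volumes of all tetrahedra (mm^3)
#' @param mesh A `tet_mesh`.
#' @export
tet_volumes <- function(mesh) {
  n <- mesh$nodes
  t <- mesh$tets
  a <- n[t[, 2], , drop = FALSE] - n[t[, 1], , drop = FALSE]
  b <- n[t[, 3], , drop = FALSE] - n[t[, 1], , drop = FALSE]
  cc <- n[t[, 4], , drop = FALSE] - n[t[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
     a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
     a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Classify chest-wall and free-surface nodes of a mesh
#'
#' Chest nodes are nodes lying on the chest plane z = 0 (within half a
#' voxel); these are constrained in z during compression. Surface nodes lie
#' on triangular faces owned by exactly one tetrahedron (the free boundary of
#' the staircase solid); these are the candidate contact nodes.
#'
#' @param mesh A `tet_mesh`.
#' @param cup Unused placeholder kept for interface symmetry; boundary sets
#'   are intrinsic to the mesh.
#' @return The mesh with `chest_nodes`, `surface_nodes` and `surface_faces`
#'   (b x 3 node-index matrix) filled in.
#' @export
classify_boundaries <- function(mesh, cup = NULL) {
  stopifnot(inherits(mesh, "tet_mesh"))
  t <- mesh$tets
  faces <- rbind(t[, c(1, 2, 3)], t[, c(1, 2, 4)], t[, c(1, 3, 4)],
                 t[, c(2, 3, 4)])
  fs <- t(apply(faces, 1, sort.int))
  M <- as.double(nrow(mesh$nodes) + 1L)
  key <- fs[, 1] + M * fs[, 2] + M * M * fs[, 3]
  tab <- table(key)  # face keys appear once (boundary) or twice (interior)
  single <- as.numeric(names(tab)[tab == 1L])
  mesh$surface_faces <- faces[match(single, key), , drop = FALSE]
  mesh$surface_nodes <- sort(unique(as.vector(mesh$surface_faces)))
  mesh$chest_nodes <- which(abs(mesh$nodes[, 3]) < mesh$voxel_mm / 2)
  mesh
}

#' Mesh quality and bookkeeping report
#'
#' @param mesh A `tet_mesh`.
#' @return List with element counts per label, min/max/total volume,
#'   max aspect ratio (longest edge over inradius-equivalent), and the
#'   indices of any non-positively-oriented tets.
#' @export
mesh_quality <- function(mesh) {
  vol <- tet_volumes(mesh)
  n <- mesh$nodes
  t <- mesh$tets
  pairs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  emax <- rep(0, nrow(t))
  for (p in pairs) {
    e <- sqrt(rowSums((n[t[, p[1]], , drop = FALSE] -
                         n[t[, p[2]], , drop = FALSE])^2))
    emax <- pmax(emax, e)
  }
  list(
    n_tets = nrow(t),
    n_nodes = nrow(n),
    count_by_label = table(mesh$labels),
    volume_by_label = tapply(vol, mesh$labels, sum),
    min_volume = min(vol),
    max_volume = max(vol),
    total_volume = sum(vol),
    max_aspect = max(emax / (6 * abs(vol))^(1 / 3)),
    negative_tets = which(vol <= 0)
  )
}
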