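#' Simulated pressure-sensor map on the compression plate
#'
#' Bins the plate-contact nodal reaction forces of a converged compression
#' solution into a grid of square sensor tiles (1 x 1 cm by default, the
#' element size of the clinical thin-film sensor): each nodal force is
#' spread over its physical contact footprint (a square one node spacing
#' wide) and integrated per tile, so the map conserves the plate force
#' exactly while the integer number of lattice nodes overlapping a tile
#' cannot alias the reading. A tile is flagged `covered` when the whole tile
#' lies inside the contact patch (every cell of a 1 mm rasterization of the
#' tile falls inside a contact-surface triangle); only covered tiles enter
#' background means.
#'
#' The tile grid is anchored at the phantom bounding-box corner
#' (x = -extent_x/2, z = 0) so tiles are reproducible across runs. A
#' position exactly on a tile edge belongs to the lower-index tile.
#'
#' In addition to the tile grid, the map carries a 1 mm raster of the
#' contact pressure field, built by spreading each nodal reaction over a
#' square kernel one node spacing wide (conservative splatting, robust to
#' the force concentrations that voxel staircase terrace edges produce);
#' the lesion-projection stress is integrated on this raster.
#'
#' @param sol A `displacement_solution`.
#' @param mesh The `tet_mesh` that produced it (boundaries classified).
#' @param tile_mm Sensor tile edge (default 10 mm).
#' @param raster_mm Coverage/pressure raster pitch (default 1 mm).
#' @param contact_gap_tol Faces whose deformed nodes all lie within this gap
#'   (mm) of the plate count as contact-patch footprint; this closes the
#'   seams the staircase voxel surface leaves between contact terraces.
#'   Default `NULL` uses half the voxel pitch.
#' @param configuration Lateral (x, z) positions used for binning,
#'   rasterization and tributary areas: `"reference"` (default) or
#'   `"deformed"`. Under the strictly linear kinematics of the solver the
#'   reference-configuration map is the consistent nominal-stress read-out;
#'   the deformed map is appropriate for updated-Lagrangian runs.
#' @return A `sensor_map`: `tiles` and `covered` matrices (x index by z
#'   index), `origin`, `tile_mm`, `raster`, `raster_mm`, `plate_force`.
#' @export
pressure_map <- function(sol, mesh, tile_mm = 10, raster_mm = 1,
                         contact_gap_tol = NULL,
                         configuration = c("reference", "deformed")) {
  if (is.null(contact_gap_tol)) contact_gap_tol <- mesh$voxel_mm / 2
  stopifnot(inherits(sol, "displacement_solution"), inherits(mesh, "tet_mesh"))
  configuration <- match.arg(configuration)
  act <- sol$active_plate
  if (length(act) == 0) {
    stop2("mi_empty_map_error", "no active plate contacts in solution")
  }
  if (is.null(mesh$surface_faces)) mesh <- classify_boundaries(mesh)
  def <- if (configuration == "deformed") sol$nodes_deformed else mesh$nodes
  # the contact gap test always uses real (deformed) heights
  ydef <- sol$nodes_deformed[, 2]
  fx <- def[act, 1]
  fz <- def[act, 3]
  force <- sol$plate_reactions  # mN, compressive positive

  origin <- c(if (!is.null(mesh$origin)) mesh$origin[1] else min(mesh$nodes[, 1]),
              if (!is.null(mesh$origin)) mesh$origin[3] else min(mesh$nodes[, 3]))
  s <- max(mesh$voxel_mm, raster_mm)   # splat kernel edge (node footprint)
  # extend the anchored tile lattice by whole tiles so deformed positions
  # (plus kernel) never clip; tile edges stay on the anchored grid
  origin <- origin - tile_mm * c(
    max(0, ceiling((origin[1] - (min(fx) - s)) / tile_mm)),
    max(0, ceiling((origin[2] - (min(fz) - s)) / tile_mm)))
  ti <- tile_index(fx, origin[1], tile_mm)
  tj <- tile_index(fz, origin[2], tile_mm)
  ntx <- max(ti) + 1L  # one spare tile so the splat kernel never clips
  ntz <- max(tj) + 1L

  # contact triangles: surface faces whose three nodes all lie on (or within
  # the gap tolerance of) the plate; nodes inside the tolerance band that
  # carry no reaction interpolate as zero pressure
  near <- ydef >= sol$plate_y - contact_gap_tol
  sf <- mesh$surface_faces
  tri <- sf[near[sf[, 1]] & near[sf[, 2]] & near[sf[, 3]], , drop = FALSE]

  nrx <- ntx * tile_mm / raster_mm
  nrz <- ntz * tile_mm / raster_mm
  hit <- matrix(FALSE, nrx, nrz)         # geometric contact footprint
  if (nrow(tri) > 0) {
    p1 <- cbind(def[tri[, 1], 1], def[tri[, 1], 3])
    p2 <- cbind(def[tri[, 2], 1], def[tri[, 2], 3])
    p3 <- cbind(def[tri[, 3], 1], def[tri[, 3], 3])
    area2 <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
      (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
    cx <- origin[1] + (seq_len(nrx) - 0.5) * raster_mm
    cz <- origin[2] + (seq_len(nrz) - 0.5) * raster_mm
    for (k in seq_len(nrow(tri))) {
      xr <- range(p1[k, 1], p2[k, 1], p3[k, 1])
      zr <- range(p1[k, 2], p2[k, 2], p3[k, 2])
      is <- which(cx >= xr[1] - raster_mm & cx <= xr[2] + raster_mm)
      js <- which(cz >= zr[1] - raster_mm & cz <= zr[2] + raster_mm)
      if (!length(is) || !length(js) || abs(area2[k]) < 1e-12) next
      gx <- rep(cx[is], times = length(js))
      gz <- rep(cz[js], each = length(is))
      w1 <- ((p2[k, 1] - gx) * (p3[k, 2] - gz) -
               (p3[k, 1] - gx) * (p2[k, 2] - gz)) / area2[k]
      w2 <- ((p3[k, 1] - gx) * (p1[k, 2] - gz) -
               (p1[k, 1] - gx) * (p3[k, 2] - gz)) / area2[k]
      w3 <- 1 - w1 - w2
      ok <- w1 >= -1e-9 & w2 >= -1e-9 & w3 >= -1e-9
      if (!any(ok)) next
      idx <- cbind(rep(is, times = length(js))[ok],
                   rep(js, each = length(is))[ok])
      hit[idx] <- TRUE
    }
  }

  # pressure raster: each nodal force is spread uniformly over a square
  # kernel one node spacing wide around the node position (conservative
  # splatting: the kernel is the node's physical contact footprint, so a
  # single staircase terrace-edge node cannot spike the field, and the
  # integer number of lattice nodes per tile cannot alias the tile reading)
  fmat <- matrix(0, nrx, nrz)
  i_lo <- pmax(1L, as.integer(ceiling((fx - s / 2 - origin[1]) / raster_mm + 0.5)))
  i_hi <- pmin(nrx, as.integer(floor((fx + s / 2 - origin[1]) / raster_mm + 0.5)))
  j_lo <- pmax(1L, as.integer(ceiling((fz - s / 2 - origin[2]) / raster_mm + 0.5)))
  j_hi <- pmin(nrz, as.integer(floor((fz + s / 2 - origin[2]) / raster_mm + 0.5)))
  for (n in seq_along(act)) {
    is <- i_lo[n]:i_hi[n]
    js <- j_lo[n]:j_hi[n]
    fmat[is, js] <- fmat[is, js] +
      force[n] / (length(is) * length(js) * raster_mm^2)
  }
  raster <- fmat
  raster[!hit] <- NA_real_

  # tile pressures: integrate the splat field over each tile
  cp <- tile_mm / raster_mm
  tiles <- matrix(0, ntx, ntz)
  for (i in seq_len(ntx)) {
    for (j in seq_len(ntz)) {
      tiles[i, j] <- sum(fmat[(i - 1) * cp + seq_len(cp),
                              (j - 1) * cp + seq_len(cp)]) *
        raster_mm^2 / tile_mm^2
    }
  }

  # covered tiles: every raster cell of the tile lies in the contact patch
  cells_per <- tile_mm / raster_mm
  covered <- matrix(FALSE, ntx, ntz)
  for (i in seq_len(ntx)) {
    for (j in seq_len(ntz)) {
      sub <- hit[(i - 1) * cells_per + seq_len(cells_per),
                 (j - 1) * cells_per + seq_len(cells_per)]
      covered[i, j] <- all(sub)
    }
  }

  structure(list(tiles = tiles, covered = covered, origin = origin,
                 tile_mm = tile_mm, raster = raster, raster_mm = raster_mm,
                 plate_force = sol$plate_force),
            class = "sensor_map")
}

#' @export
print.sensor_map <- function(x, ...) {
  cat(sprintf(
    "<sensor_map> %d x %d tiles of %g mm, %d covered, mean covered pressure %.3f kPa\n",
    nrow(x$tiles), ncol(x$tiles), x$tile_mm, sum(x$covered),
    sensor_mean(x)))
  invisible(x)
}

#' Sensor tile index of a position
#'
#' Maps a coordinate to its 1-based tile index on a grid anchored at
#' `origin`. A position exactly on a tile edge belongs to the lower-index
#' tile (deterministic tie-break).
#'
#' @param v Positions (mm).
#' @param origin Grid anchor (mm).
#' @param h Tile edge (mm).
#' @return Integer tile indices (clamped at 1 for `v <= origin`).
#' @export
tile_index <- function(v, origin, h) {
  i <- as.integer(ceiling((v - origin) / h - 1e-12))
  pmax(i, 1L)
}

#' Mean pressure over fully covered sensor tiles
#'
#' The background statistic of the clinical protocol: the average pressure
#' over all sensor tiles that fully cover the breast contact patch.
#'
#' @param map A `sensor_map`.
#' @return kPa.
#' @export
sensor_mean <- function(map) {
  stopifnot(inherits(map, "sensor_map"))
  if (!any(map$covered)) {
    stop2("mi_empty_map_error", "no fully covered sensor tile")
  }
  mean(map$tiles[map$covered])
}

#' Relative mean pressure over lesion area (RMPA)
#'
#' The ratio of the mean pressure of the 3 x 3 tile neighborhood centered on
#' the tile containing the lesion center to the mean pressure over all fully
#' covered tiles. Neighborhood tiles that are not fully covered are excluded
#' from the neighborhood mean (zero-filling would bias the statistic down
#' near the breast edge). The lesion center is taken in the deformed
#' configuration, since the clinical map is acquired on the compressed
#' breast.
#'
#' @param map A `sensor_map`.
#' @param lesion_center Deformed lesion center; xyz or xz (mm).
#' @return An `rmpa_result`: `rmpa`, `lesion_tile`, `neighborhood_mean`,
#'   `background_mean`.
#' @export
rmpa <- function(map, lesion_center) {
  stopifnot(inherits(map, "sensor_map"))
  lc <- as.numeric(lesion_center)
  if (length(lc) == 3) lc <- lc[c(1, 3)]
  i <- tile_index(lc[1], map$origin[1], map$tile_mm)
  j <- tile_index(lc[2], map$origin[2], map$tile_mm)
  if (i > nrow(map$tiles) || j > ncol(map$tiles)) {
    stop2("mi_placement_error", "lesion tile outside the sensor grid")
  }
  if (!any(map$covered)) {
    stop2("mi_empty_map_error", "background empty: no covered tile")
  }
  if (!map$covered[i, j]) {
    warning("lesion tile is not fully covered; RMPA computed over the ",
            "covered subset of its neighborhood", call. = FALSE)
  }
  is <- intersect(i + (-1:1), seq_len(nrow(map$tiles)))
  js <- intersect(j + (-1:1), seq_len(ncol(map$tiles)))
  nb_cov <- map$covered[is, js, drop = FALSE]
  if (!any(nb_cov)) {
    stop2("mi_empty_map_error", "no covered tile in the lesion neighborhood")
  }
  nb_mean <- mean(map$tiles[is, js, drop = FALSE][nb_cov])
  bg_mean <- mean(map$tiles[map$covered])
  structure(list(rmpa = nb_mean / bg_mean, lesion_tile = c(i, j),
                 neighborhood_mean = nb_mean, background_mean = bg_mean),
            class = "rmpa_result")
}

#' @export
print.rmpa_result <- function(x, ...) {
  cat(sprintf("<rmpa_result> RMPA = %.3f (tile %d,%d: %.3f kPa over background %.3f kPa)\n",
              x$rmpa, x$lesion_tile[1], x$lesion_tile[2],
              x$neighborhood_mean, x$background_mean))
  invisible(x)
}

#' Mean surface pressure over the lesion projection
#'
#' Average contact pressure over the disc obtained by projecting the lesion
#' sphere along the compression axis onto the plate, evaluated on the 1 mm
#' pressure raster at the lesion's deformed (x, z) center with the lesion's
#' nominal radius. Cells of the disc outside the contact patch are excluded;
#' if any are missing a partial-coverage warning reports the covered
#' fraction.
#'
#' @param map A `sensor_map`.
#' @param lesion_center Deformed lesion center; xyz or xz (mm).
#' @param diameter Lesion diameter (mm), default 15.
#' @return kPa (attribute `covered_fraction` gives the disc coverage).
#' @export
lesion_surface_stress <- function(map, lesion_center, diameter = 15) {
  stopifnot(inherits(map, "sensor_map"))
  lc <- as.numeric(lesion_center)
  if (length(lc) == 3) lc <- lc[c(1, 3)]
  r <- diameter / 2
  nrx <- nrow(map$raster); nrz <- ncol(map$raster)
  cx <- map$origin[1] + (seq_len(nrx) - 0.5) * map$raster_mm
  cz <- map$origin[2] + (seq_len(nrz) - 0.5) * map$raster_mm
  in_disc <- outer(cx - lc[1], cz - lc[2],
                   function(a, b) a^2 + b^2 <= r^2)
  vals <- map$raster[in_disc]
  frac <- mean(!is.na(vals))
  if (!length(vals) || all(is.na(vals))) {
    stop2("mi_empty_map_error",
          "lesion projection disc entirely outside the contact patch")
  }
  if (frac < 1) {
    warning(sprintf(
      "lesion projection disc only %.0f%% inside the contact patch",
      100 * frac), call. = FALSE)
  }
  out <- mean(vals, na.rm = TRUE)
  attr(out, "covered_fraction") <- frac
  out
}

#' Displacement interpolated at a material point
#'
#' Inverse-distance interpolation of the nodal displacement field at a
#' reference-configuration point (used to track the lesion center into the
#' deformed configuration).
#'
#' @param sol A `displacement_solution`.
#' @param mesh The `tet_mesh`.
#' @param point Reference xyz (mm).
#' @param k Number of nearest nodes (default 8).
#' @return Displacement xyz (mm).
#' @export
displacement_at <- function(sol, mesh, point, k = 8) {
  d2 <- colSums((t(mesh$nodes) - as.numeric(point))^2)
  nn <- order(d2)[seq_len(min(k, length(d2)))]
  w <- 1 / pmax(d2[nn], 1e-12)
  colSums(sol$u[nn, , drop = FALSE] * w) / sum(w)
}
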