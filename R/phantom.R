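#' Cup specification for the procedural breast outline
#'
#' The breast outline is a half-ellipsoid truncated by a planar chest wall,
#' standing in for a compressed-breast-sized volume roughly matching bra cup
#' sizes A and B. The bounding box is `extent_x` (inferior-superior) by
#' `extent_y` (medial-lateral, the compression axis) by `extent_z`
#' (chest-nipple). Presets: cup A is 170 x 75 x 37 mm (about 250 mL), cup B is
#' 170 x 100 x 50 mm (about 450 mL).
#'
#' Coordinate convention used throughout the package:
#' x in \[-extent_x/2, extent_x/2\], y in \[0, extent_y\] (compression axis,
#' support plate at y = 0, compression plate starting at y = extent_y),
#' z in \[0, extent_z\] with the planar chest wall at z = 0.
#'
#' @param name `"A"` or `"B"` (case insensitive; `"cupA"`/`"cupB"` accepted).
#' @return A `cup_spec` object with fields `name`, `extent_x`, `extent_y`,
#'   `extent_z` (mm) and the default lesion placement margin `min_margin` (mm).
#' @examples
#' cup_spec("A")
#' @export
cup_spec <- function(name = c("A", "B")) {
  nm <- toupper(sub("^cup", "", as.character(name[1]), ignore.case = TRUE))
  if (!nm %in% c("A", "B")) {
    stop("unknown cup preset: ", name, " (expected 'A' or 'B')", call. = FALSE)
  }
  spec <- if (nm == "A") {
    list(name = "cupA", extent_x = 170, extent_y = 75, extent_z = 37,
         min_margin = 7.5)
  } else {
    list(name = "cupB", extent_x = 170, extent_y = 100, extent_z = 50,
         min_margin = 10)
  }
  structure(spec, class = "cup_spec")
}

#' @export
print.cup_spec <- function(x, ...) {
  cat(sprintf("<cup_spec %s> %g x %g x %g mm, analytic volume %.1f mL\n",
              x$name, x$extent_x, x$extent_y, x$extent_z,
              cup_analytic_volume(x) / 1000))
  invisible(x)
}

#' Analytic volume of the half-ellipsoid outline
#'
#' The outline solid is half of an ellipsoid with semi-axes
#' (extent_x/2, extent_y/2, extent_z), cut by the chest plane z = 0, so its
#' volume is (2/3) pi a b c.
#'
#' @param cup A [cup_spec()].
#' @return Volume in mm^3.
#' @export
cup_analytic_volume <- function(cup) {
  (2 / 3) * pi * (cup$extent_x / 2) * (cup$extent_y / 2) * cup$extent_z
}

ellipsoid_semiaxes <- function(cup) {
  c(cup$extent_x / 2, cup$extent_y / 2, cup$extent_z)
}

#' Distance from an interior point to the breast (skin) surface
#'
#' Euclidean distance from a point to the curved half-ellipsoid surface
#' (the skin). The chest wall plane z = 0 is an attachment plane, not free
#' skin, and is not counted. Used by the lesion placement margin rule.
#'
#' Implementation: nearest point on the full ellipsoid via the standard
#' single-parameter root find (the nearest surface point of an interior point
#' with z > 0 itself has z > 0, so the half-ellipsoid truncation never
#' interferes for valid lesion centers).
#'
#' @param cup A [cup_spec()].
#' @param point Numeric xyz (mm), in outline coordinates.
#' @return Signed distance (mm): positive inside, negative outside.
#' @export
surface_distance <- function(cup, point) {
  ax <- ellipsoid_semiaxes(cup)
  ctr <- c(0, cup$extent_y / 2, 0)
  p <- as.numeric(point) - ctr
  f <- sum((p / ax)^2)
  if (all(abs(p) < 1e-12)) return(min(ax))
  # root of g(t) = sum_i (a_i p_i / (a_i^2 + t))^2 - 1; interior roots have
  # t in (-min(a)^2, 0], exterior t > 0
  g <- function(t) sum((ax * p / (ax^2 + t))^2) - 1
  lo <- -min(ax)^2
  hi <- max(ax) * sqrt(sum(p^2)) + max(ax)^2  # g(hi) < 0 guaranteed
  # bracket: g -> +Inf as t -> lo+, g(hi) < 0
  r <- stats::uniroot(g, lower = lo + 1e-9 * min(ax)^2, upper = hi,
                      tol = 1e-12)$root
  s <- ax^2 * p / (ax^2 + r)            # nearest point on the ellipsoid
  d <- sqrt(sum((s - p)^2))
  if (f <= 1) d else -d
}

#' Generate the voxelized breast outline
#'
#' Marks every voxel whose center satisfies the half-ellipsoid inequality
#' (semi-axes extent_x/2, extent_y/2, extent_z, flat chest plane at z = 0)
#' as adipose (label 1); outside voxels are 0.
#'
#' @param cup A [cup_spec()].
#' @param voxel_mm Voxel edge length in mm; must be positive and no coarser
#'   than a quarter of the smallest extent.
#' @return A `breast_phantom`: list with `labels` (3-D integer array),
#'   `voxel_mm`, `origin` (mm position of the grid corner), `cup`.
#' @examples
#' ph <- build_outline(cup_spec("A"), voxel_mm = 4)
#' phantom_volume(ph) / 1000  # ~ 247 mL
#' @export
build_outline <- function(cup, voxel_mm = 2) {
  stopifnot(inherits(cup, "cup_spec"))
  if (!is.numeric(voxel_mm) || length(voxel_mm) != 1 || voxel_mm <= 0) {
    stop2("mi_resolution_error", "voxel_mm must be a positive scalar")
  }
  if (voxel_mm > min(cup$extent_x, cup$extent_y, cup$extent_z) / 4) {
    stop2("mi_resolution_error", sprintf(
      "voxel_mm = %g too coarse for %s (max %g)", voxel_mm, cup$name,
      min(cup$extent_x, cup$extent_y, cup$extent_z) / 4))
  }
  h <- voxel_mm
  nx <- ceiling(cup$extent_x / h)
  ny <- ceiling(cup$extent_y / h)
  nz <- ceiling(cup$extent_z / h)
  origin <- c(-cup$extent_x / 2, 0, 0)
  xc <- origin[1] + (seq_len(nx) - 0.5) * h
  yc <- origin[2] + (seq_len(ny) - 0.5) * h
  zc <- origin[3] + (seq_len(nz) - 0.5) * h
  ax <- ellipsoid_semiaxes(cup)
  fx <- (xc / ax[1])^2
  fy <- ((yc - cup$extent_y / 2) / ax[2])^2
  fz <- (zc / ax[3])^2
  f <- array(fx, dim = c(nx, ny, nz)) +
    array(rep(fy, each = nx), dim = c(nx, ny, nz)) +
    array(rep(fz, each = nx * ny), dim = c(nx, ny, nz))
  labels <- array(0L, dim = c(nx, ny, nz))
  labels[f <= 1] <- 1L
  if (sum(labels) == 0L) {
    stop2("mi_resolution_error", "outline degenerate: no voxel center inside")
  }
  structure(list(labels = labels, voxel_mm = h, origin = origin, cup = cup),
            class = "breast_phantom")
}

#' @export
print.breast_phantom <- function(x, ...) {
  cat(sprintf(
    "<breast_phantom %s> %s voxels @ %g mm, %d adipose, %d lesion (%.1f mL)\n",
    x$cup$name, paste(dim(x$labels), collapse = "x"), x$voxel_mm,
    sum(x$labels == 1L), sum(x$labels == 2L), phantom_volume(x) / 1000))
  invisible(x)
}

#' Occupied (breast) volume of a phantom in mm^3
#' @param phantom A `breast_phantom`.
#' @export
phantom_volume <- function(phantom) {
  sum(phantom$labels > 0L) * phantom$voxel_mm^3
}

#' Voxel center coordinates of a phantom grid
#' @param phantom A `breast_phantom`.
#' @return List of numeric vectors `x`, `y`, `z` (mm).
#' @export
voxel_centers <- function(phantom) {
  d <- dim(phantom$labels)
  h <- phantom$voxel_mm
  list(x = phantom$origin[1] + (seq_len(d[1]) - 0.5) * h,
       y = phantom$origin[2] + (seq_len(d[2]) - 0.5) * h,
       z = phantom$origin[3] + (seq_len(d[3]) - 0.5) * h)
}

#' Lesion specification
#'
#' A spherical stiff inclusion. `stiffness_ratio` k is the lesion elastic
#' modulus divided by the adipose modulus; the study sweeps use k in
#' {15, 30, 50}. `min_margin` is the minimum allowed distance from the lesion
#' surface to the breast (skin) surface: 7.5 mm for cup A, 10 mm for cup B by
#' default.
#'
#' @param center Numeric xyz (mm).
#' @param diameter Sphere diameter (mm), default 15.
#' @param stiffness_ratio Lesion-to-adipose stiffness ratio, default 15.
#' @param min_margin Margin (mm); `NULL` to take the cup default at insertion.
#' @export
lesion_spec <- function(center, diameter = 15, stiffness_ratio = 15,
                        min_margin = NULL) {
  stopifnot(length(center) == 3, is.numeric(center))
  if (diameter < 0) stop("lesion diameter must be >= 0", call. = FALSE)
  structure(list(center = as.numeric(center), diameter = diameter,
                 stiffness_ratio = stiffness_ratio, min_margin = min_margin),
            class = "lesion_spec")
}

#' Insert a spherical lesion into a phantom
#'
#' Relabels voxels whose centers fall inside the lesion sphere as lesion
#' (label 2). The lesion must keep at least `min_margin` mm between its
#' surface and the breast skin surface; a violation raises a placement error
#' naming the offending distance. A zero-diameter lesion leaves the phantom
#' unchanged.
#'
#' @param phantom A `breast_phantom`.
#' @param lesion A [lesion_spec()].
#' @return The phantom with lesion voxels relabeled.
#' @export
insert_lesion <- function(phantom, lesion) {
  stopifnot(inherits(phantom, "breast_phantom"), inherits(lesion, "lesion_spec"))
  if (lesion$diameter == 0) return(phantom)
  cup <- phantom$cup
  margin <- lesion$min_margin %||% cup$min_margin
  r <- lesion$diameter / 2
  d_surf <- surface_distance(cup, lesion$center)
  if (d_surf < 0) {
    stop2("mi_placement_error", sprintf(
      "lesion center (%s) lies %.2f mm outside the breast outline",
      paste(signif(lesion$center, 4), collapse = ", "), -d_surf))
  }
  if (d_surf - r < margin) {
    stop2("mi_placement_error", sprintf(
      "lesion surface only %.2f mm from the breast surface (minimum %.1f mm)",
      d_surf - r, margin))
  }
  cc <- voxel_centers(phantom)
  d <- dim(phantom$labels)
  dx2 <- (cc$x - lesion$center[1])^2
  dy2 <- (cc$y - lesion$center[2])^2
  dz2 <- (cc$z - lesion$center[3])^2
  inside <- array(dx2, dim = d) +
    array(rep(dy2, each = d[1]), dim = d) +
    array(rep(dz2, each = d[1] * d[2]), dim = d) <= r^2
  sel <- inside & phantom$labels == 1L
  phantom$labels[sel] <- 2L
  phantom
}

#' Default lesion-location registries for the parameter sweeps
#'
#' Returns the fixed registry of lesion centers used by the default sweeps:
#' 7 centers for cup A and 52 for cup B, so that crossing with the three
#' stiffness ratios gives 21 and 156 cases. All centers satisfy the margin
#' rule (7.5 mm for cup A, 10 mm for cup B, lesion surface to skin surface).
#'
#' Cup A: all centers at z = 15 mm from the chest wall, two depth bands
#' spaced 20 mm apart along the compression axis (y = 50 mm "shallow", four
#' centers at x = -30, -10, 10, 30; y = 30 mm "deep", three centers at
#' x = -20, 0, 20), with 20 mm x-increments inside each band.
#'
#' Cup B: four bands with 5 mm x-increments: a near-plate band (y = 70,
#' z = 20; 13 centers, x = -30..30), a mid-breast band 50 mm from the
#' compression plate (y = 50, z = 20; 21 centers, x = -50..50), the same
#' near-plate line moved 5 mm closer to the chest wall (y = 70, z = 15;
#' 13 centers), and a short mid-breast/mid-thickness line (y = 50, z = 25;
#' 5 centers, x = -10..10).
#'
#' @param cup A [cup_spec()] or `"A"`/`"B"`.
#' @return A tibble with columns `loc_id`, `band`, `x`, `y`, `z` (mm).
#' @export
default_locations <- function(cup) {
  if (!inherits(cup, "cup_spec")) cup <- cup_spec(cup)
  if (cup$name == "cupA") {
    df <- rbind(
      data.frame(band = "shallow", x = c(-30, -10, 10, 30), y = 50, z = 15),
      data.frame(band = "deep", x = c(-20, 0, 20), y = 30, z = 15)
    )
  } else {
    df <- rbind(
      data.frame(band = "near_plate", x = seq(-30, 30, by = 5), y = 70, z = 20),
      data.frame(band = "mid_breast", x = seq(-50, 50, by = 5), y = 50, z = 20),
      data.frame(band = "near_chest", x = seq(-30, 30, by = 5), y = 70, z = 15),
      data.frame(band = "mid_thickness", x = seq(-10, 10, by = 5), y = 50, z = 25)
    )
  }
  df$loc_id <- sprintf("%s_%s_x%+04d_y%03d_z%02d", sub("cup", "", cup$name),
                       df$band, as.integer(df$x), as.integer(df$y),
                       as.integer(df$z))
  tibble::as_tibble(df[, c("loc_id", "band", "x", "y", "z")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}
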