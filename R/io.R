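#' Load and validate a sweep configuration from YAML
#'
#' Reads a YAML file with any of the keys `cup`, `voxel_mm`, `k`,
#' `locations`, `n_increments`, `kinematics`, `compression_fraction`,
#' `lesion_diameter`, `preset`, `out_dir`, fills defaults for the rest and
#' rejects unknown keys. Exploratory stiffness ratios outside the standard
#' {15, 30, 50} set are accepted with a warning.
#'
#' @param path YAML file path.
#' @return A validated [sweep_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop2("mi_config_error", paste0("config file not found: ", path))
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("cup", "voxel_mm", "k", "locations", "n_increments",
             "kinematics", "compression_fraction", "lesion_diameter",
             "preset", "out_dir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop2("mi_config_error", paste0(
      "unknown config key(s): ", paste(unknown, collapse = ", "),
      " (allowed: ", paste(known, collapse = ", "), ")"))
  }
  if (!is.null(raw$voxel_mm) &&
      (!is.numeric(raw$voxel_mm) || raw$voxel_mm <= 0)) {
    stop2("mi_config_error", "voxel_mm must be a positive number")
  }
  if (!is.null(raw$compression_fraction) &&
      (raw$compression_fraction <= 0 || raw$compression_fraction >= 1)) {
    stop2("mi_config_error", "compression_fraction must be in (0, 1)")
  }
  if (!is.null(raw$k)) {
    extra <- setdiff(raw$k, c(15, 30, 50))
    if (length(extra)) {
      warning("non-standard stiffness ratio(s): ",
              paste(extra, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(raw$locations) && !identical(raw$locations, "default")) {
    raw$locations <- as.data.frame(do.call(rbind, lapply(
      raw$locations, function(loc) {
        # YAML 1.1 parses a bare `y` key as boolean TRUE; map it back
        names(loc)[names(loc) == "TRUE"] <- "y"
        as.data.frame(loc)
      })))
  }
  args <- raw
  args$cup <- raw$cup %||% "A"
  do.call(sweep_config, args)
}

#' Write a mesh and solution as an ASCII VTU file
#'
#' VTK XML unstructured-grid format with nodal displacement vectors and
#' per-cell compression-direction stress and material label, loadable in
#' standard VTK readers.
#'
#' @param mesh A `tet_mesh`.
#' @param path Output file.
#' @param sol Optional `displacement_solution` for point/cell data.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, sol = NULL) {
  np <- nrow(mesh$nodes)
  nc <- nrow(mesh$tets)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  num <- function(v, fmt = "%.8g") paste(sprintf(fmt, v), collapse = " ")
  w("<?xml version=\"1.0\"?>")
  w("<VTKFile type=\"UnstructuredGrid\" version=\"0.1\" byte_order=\"LittleEndian\">")
  w("  <UnstructuredGrid>")
  w("    <Piece NumberOfPoints=\"%d\" NumberOfCells=\"%d\">", np, nc)
  w("      <Points>")
  w("        <DataArray type=\"Float64\" NumberOfComponents=\"3\" format=\"ascii\">")
  writeLines(apply(mesh$nodes, 1, num), con)
  w("        </DataArray>")
  w("      </Points>")
  w("      <Cells>")
  w("        <DataArray type=\"Int32\" Name=\"connectivity\" format=\"ascii\">")
  writeLines(apply(mesh$tets - 1L, 1, paste, collapse = " "), con)
  w("        </DataArray>")
  w("        <DataArray type=\"Int32\" Name=\"offsets\" format=\"ascii\">")
  writeLines(num(seq_len(nc) * 4L, "%d"), con)
  w("        </DataArray>")
  w("        <DataArray type=\"UInt8\" Name=\"types\" format=\"ascii\">")
  writeLines(num(rep(10L, nc), "%d"), con)
  w("        </DataArray>")
  w("      </Cells>")
  if (!is.null(sol)) {
    w("      <PointData Vectors=\"displacement\">")
    w("        <DataArray type=\"Float64\" Name=\"displacement\" NumberOfComponents=\"3\" format=\"ascii\">")
    writeLines(apply(sol$u, 1, num), con)
    w("        </DataArray>")
    w("      </PointData>")
  }
  w("      <CellData Scalars=\"material\">")
  w("        <DataArray type=\"Int32\" Name=\"material\" format=\"ascii\">")
  writeLines(num(mesh$labels, "%d"), con)
  w("        </DataArray>")
  if (!is.null(sol)) {
    w("        <DataArray type=\"Float64\" Name=\"stress_yy\" format=\"ascii\">")
    writeLines(num(sol$sigma[, "yy"]), con)
    w("        </DataArray>")
  }
  w("      </CellData>")
  w("    </Piece>")
  w("  </UnstructuredGrid>")
  w("</VTKFile>")
  invisible(path)
}

#' Write a sensor map as CSV (one row per tile)
#'
#' Columns: tile indices `i`, `j`, tile-center coordinates `x_mm`, `z_mm`,
#' `pressure_kpa`, `covered`. [read_sensor_csv()] restores the map exactly.
#'
#' @param map A `sensor_map`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sensor_csv <- function(map, path) {
  ij <- expand.grid(i = seq_len(nrow(map$tiles)), j = seq_len(ncol(map$tiles)))
  df <- data.frame(
    i = ij$i, j = ij$j,
    x_mm = map$origin[1] + (ij$i - 0.5) * map$tile_mm,
    z_mm = map$origin[2] + (ij$j - 0.5) * map$tile_mm,
    pressure_kpa = as.vector(map$tiles),
    covered = as.vector(map$covered))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a sensor-map CSV written by [write_sensor_csv()]
#'
#' @param path CSV file.
#' @return A `sensor_map` (tile data only; the 1 mm raster is not
#'   round-tripped).
#' @export
read_sensor_csv <- function(path) {
  df <- utils::read.csv(path)
  ni <- max(df$i); nj <- max(df$j)
  tiles <- matrix(0, ni, nj)
  covered <- matrix(FALSE, ni, nj)
  tiles[cbind(df$i, df$j)] <- df$pressure_kpa
  covered[cbind(df$i, df$j)] <- df$covered
  tile_mm <- if (ni > 1) diff(sort(unique(df$x_mm)))[1] else 10
  origin <- c(min(df$x_mm) - tile_mm / 2, min(df$z_mm) - tile_mm / 2)
  structure(list(tiles = tiles, covered = covered, origin = origin,
                 tile_mm = tile_mm, raster = NULL, raster_mm = NA_real_,
                 plate_force = sum(tiles) * tile_mm^2 / 1000),
            class = "sensor_map")
}

#' Export a complete compression case to a directory
#'
#' Writes the VTU solution, the sensor-map CSV, a metrics JSON, an optional
#' PNG heat map of the tile pressures (if the `png` package is available)
#' and a manifest with software version and per-file checksums sufficient to
#' verify a bit-identical re-run.
#'
#' @param sol A `displacement_solution`.
#' @param mesh Its `tet_mesh`.
#' @param map Its `sensor_map`.
#' @param metrics Named list of per-case metrics to store as JSON.
#' @param dir Output directory (created if needed).
#' @return Invisible character vector of the written paths.
#' @export
export_case <- function(sol, mesh, map, metrics, dir) {
  ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    stop2("mi_io_error", paste0("cannot create output directory: ", dir))
  }
  paths <- c(vtu = file.path(dir, "solution.vtu"),
             sensor = file.path(dir, "sensor.csv"),
             metrics = file.path(dir, "metrics.json"))
  write_vtu(mesh, paths[["vtu"]], sol)
  write_sensor_csv(map, paths[["sensor"]])
  jsonlite::write_json(metrics, paths[["metrics"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (requireNamespace("png", quietly = TRUE)) {
    p <- file.path(dir, "sensor.png")
    m <- t(map$tiles[, rev(seq_len(ncol(map$tiles))), drop = FALSE])
    rng <- range(m)
    img <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
    png::writePNG(img, p)
    paths <- c(paths, png = p)
  }
  manifest <- list(
    package = "mechimg",
    version = tryCatch(as.character(utils::packageVersion("mechimg")),
                       error = function(e) "dev"),
    written = format(Sys.time(), tz = "UTC", usetz = TRUE),
    case = sol$case[c("compression_fraction", "n_increments", "kinematics")],
    materials = list(E_kpa = as.list(sol$mats$E), nu = sol$mats$nu),
    plate_force_n = sol$plate_force,
    convergence = sol$log,
    checksums = as.list(tools::md5sum(unname(paths))))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, manifest = mp))
}
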