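#' Configuration for a lesion-location / stiffness sweep
#'
#' Validated settings for [run_sweep()]. Resolution presets: `"desk"`
#' (4 mm voxels, the default used for tests and result reproduction on a
#' single CPU) and `"fine"` (2 mm voxels).
#'
#' @param cup `"A"` or `"B"`.
#' @param voxel_mm Voxel pitch (mm); overrides the preset when given.
#' @param k Stiffness ratios to sweep (default `c(15, 30, 50)`).
#' @param locations `"default"` for the cup's location registry
#'   ([default_locations()]) or a data frame with columns `x`, `y`, `z`
#'   (optionally `loc_id`).
#' @param n_increments Plate-travel increments per solve.
#' @param kinematics Solver kinematics (see [compression_case()]).
#' @param compression_fraction Plate compression fraction (default 0.5).
#' @param lesion_diameter Lesion diameter (mm, default 15).
#' @param preset `"desk"` or `"fine"`.
#' @param out_dir Optional directory for incremental per-case records (the
#'   sweep is resumable from them).
#' @return A `sweep_config`.
#' @export
sweep_config <- function(cup = "A", voxel_mm = NULL, k = c(15, 30, 50),
                         locations = "default", n_increments = 5,
                         kinematics = "linear", compression_fraction = 0.5,
                         lesion_diameter = 15,
                         preset = c("desk", "fine"), out_dir = NULL) {
  preset <- match.arg(preset)
  cup <- if (inherits(cup, "cup_spec")) cup else cup_spec(cup)
  voxel_mm <- voxel_mm %||% switch(preset, desk = 4, fine = 2)
  if (!is.numeric(voxel_mm) || voxel_mm <= 0) {
    stop2("mi_config_error", "voxel_mm must be a positive number")
  }
  if (!all(k > 0)) stop2("mi_config_error", "stiffness ratios must be > 0")
  if (!identical(locations, "default")) {
    locations <- as.data.frame(locations)
    if (!all(c("x", "y", "z") %in% names(locations))) {
      stop2("mi_config_error", "locations need columns x, y, z")
    }
    if (is.null(locations$loc_id)) {
      locations$loc_id <- sprintf("loc%02d", seq_len(nrow(locations)))
    }
  }
  structure(list(cup = cup, voxel_mm = voxel_mm, k = sort(unique(k)),
                 locations = locations, n_increments = n_increments,
                 kinematics = kinematics,
                 compression_fraction = compression_fraction,
                 lesion_diameter = lesion_diameter, preset = preset,
                 out_dir = out_dir),
            class = "sweep_config")
}

#' Enumerate the cases of a sweep configuration
#'
#' Locations crossed with stiffness ratios, with deterministic case ids.
#' The default registries give 7 x 3 = 21 cases for cup A and
#' 52 x 3 = 156 for cup B.
#'
#' @param config A [sweep_config()].
#' @return Tibble with `case_id`, `loc_id`, `band`, `x`, `y`, `z`, `k`.
#' @export
sweep_cases <- function(config) {
  stopifnot(inherits(config, "sweep_config"))
  locs <- if (identical(config$locations, "default")) {
    default_locations(config$cup)
  } else {
    tibble::as_tibble(config$locations)
  }
  if (!"band" %in% names(locs)) locs$band <- "custom"
  out <- merge(locs, data.frame(k = config$k), by = NULL)
  out <- out[order(out$loc_id, out$k), ]
  out$case_id <- sprintf("%s_k%02d", out$loc_id, as.integer(out$k))
  rownames(out) <- NULL
  tibble::as_tibble(out[, c("case_id", "loc_id", "band", "x", "y", "z", "k")])
}

#' Run the full compression sweep
#'
#' Builds the cup outline and its tetrahedral mesh once, then for every
#' (location, stiffness) case relabels the lesion voxels, solves plate
#' compression, extracts the sensor map, and records the per-case metrics:
#' mean covered-tile surface pressure, lesion-projection pressure, RMPA and
#' plate force. Per-case solver failures are recorded and skipped; the sweep
#' aborts if more than 10% of cases fail. With `config$out_dir` set, each
#' record is persisted as it completes and a re-run resumes after the
#' existing case ids.
#'
#' @param config A [sweep_config()].
#' @param verbose Print one line per case.
#' @return A `sweep_result`: `records` tibble, `config`, `mesh_info`.
#' @export
run_sweep <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  cases <- sweep_cases(config)
  phantom <- build_outline(config$cup, config$voxel_mm)
  mesh <- classify_boundaries(voxels_to_tets(phantom))
  mesh$origin <- phantom$origin
  geom <- fem_geometry(mesh)
  case_def <- compression_case(
    compression_fraction = config$compression_fraction,
    n_increments = config$n_increments, kinematics = config$kinematics,
    thickness0 = config$cup$extent_y)
  sensor_conf <- if (config$kinematics == "linear") "reference" else "deformed"

  rec_file <- NULL
  done <- character(0)
  records <- list()
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    rec_file <- file.path(config$out_dir, "records.csv")
    if (file.exists(rec_file)) {
      prev <- utils::read.csv(rec_file, stringsAsFactors = FALSE)
      done <- prev$case_id
      records <- split(prev, seq_len(nrow(prev)))
    }
  }

  n_fail <- 0
  warm <- NULL  # converged contact sets carry over between cases: the
                # linear solution is path-independent, so later cases solve
                # in one warm-started increment
  for (ci in seq_len(nrow(cases))) {
    cs <- cases[ci, ]
    if (cs$case_id %in% done) next
    row <- tryCatch({
      ph2 <- insert_lesion(phantom, lesion_spec(
        c(cs$x, cs$y, cs$z), config$lesion_diameter, cs$k))
      m2 <- mesh
      m2$labels <- as.integer(ph2$labels[mesh$voxel_of])
      sol <- solve_compression(m2, material_table(cs$k), case_def,
                               geom = geom, init_active = warm)
      if (config$kinematics == "linear") {
        warm <- list(plate = sol$active_plate, support = sol$active_support)
      }
      map <- pressure_map(sol, m2, configuration = sensor_conf)
      lc <- c(cs$x, cs$y, cs$z)
      lcd <- if (sensor_conf == "deformed") {
        lc + displacement_at(sol, m2, lc)
      } else lc
      ls <- suppressWarnings(lesion_surface_stress(map, lcd,
                                                   config$lesion_diameter))
      rp <- suppressWarnings(rmpa(map, lcd))
      data.frame(case_id = cs$case_id, loc_id = cs$loc_id, band = cs$band,
                 x = cs$x, y = cs$y, z = cs$z, k = cs$k,
                 surface_kpa = sensor_mean(map), lesion_kpa = as.numeric(ls),
                 rmpa = rp$rmpa, plate_force_n = sol$plate_force,
                 n_covered = sum(map$covered),
                 lesion_tile_i = rp$lesion_tile[1],
                 lesion_tile_j = rp$lesion_tile[2],
                 disc_coverage = attr(ls, "covered_fraction"),
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(case_id = cs$case_id, loc_id = cs$loc_id, band = cs$band,
                 x = cs$x, y = cs$y, z = cs$z, k = cs$k,
                 surface_kpa = NA_real_, lesion_kpa = NA_real_,
                 rmpa = NA_real_, plate_force_n = NA_real_,
                 n_covered = NA_integer_, lesion_tile_i = NA_integer_,
                 lesion_tile_j = NA_integer_, disc_coverage = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    if (!is.na(row$error)) n_fail <- n_fail + 1
    if (n_fail > 0.1 * nrow(cases)) {
      stop2("mi_solver_error", sprintf(
        "sweep aborted: %d of %d cases failed (last: %s)",
        n_fail, nrow(cases), row$error))
    }
    records[[length(records) + 1]] <- row
    if (!is.null(rec_file)) {
      utils::write.table(row, rec_file, sep = ",", row.names = FALSE,
                         col.names = !file.exists(rec_file),
                         append = file.exists(rec_file))
    }
    if (verbose) {
      message(sprintf("[%3d/%3d] %-28s surf %5.2f lesion %6.2f rmpa %5.3f F %5.2f %s",
                      ci, nrow(cases), cs$case_id, row$surface_kpa,
                      row$lesion_kpa, row$rmpa, row$plate_force_n,
                      ifelse(is.na(row$error), "", "FAILED")))
    }
  }
  recs <- tibble::as_tibble(do.call(rbind, records))
  recs <- recs[order(recs$case_id), ]
  structure(list(records = recs, config = config,
                 mesh_info = list(n_tets = nrow(mesh$tets),
                                  n_nodes = nrow(mesh$nodes),
                                  voxel_mm = config$voxel_mm)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result %s> %d cases (%d failed), voxel %g mm\n",
              x$config$cup$name, nrow(x$records),
              sum(!is.na(x$records$error)), x$config$voxel_mm))
  invisible(x)
}

#' Per-stiffness summary of a sweep (stress-table layout)
#'
#' Mean, sample standard deviation (n - 1) and range of the surface and
#' lesion-location pressures per stiffness ratio, plus the two-sided exact
#' Wilcoxon signed-rank p-value comparing the paired per-location surface
#' and lesion pressures.
#'
#' @param result A `sweep_result` (or its `records` tibble).
#' @return Tibble with one row per stiffness ratio.
#' @export
summarize_sweep <- function(result) {
  recs <- if (inherits(result, "sweep_result")) result$records else result
  recs <- recs[is.na(recs$error), ]
  ks <- sort(unique(recs$k))
  rows <- lapply(ks, function(kk) {
    r <- recs[recs$k == kk, ]
    if (nrow(r) == 0) {
      warning("empty stiffness group k = ", kk, " omitted", call. = FALSE)
      return(NULL)
    }
    p <- wilcoxon_signed_rank(r$lesion_kpa, r$surface_kpa)$p_value
    tibble::tibble(
      k = kk, n = nrow(r),
      surface_mean = mean(r$surface_kpa), surface_sd = stats::sd(r$surface_kpa),
      surface_min = min(r$surface_kpa), surface_max = max(r$surface_kpa),
      lesion_mean = mean(r$lesion_kpa), lesion_sd = stats::sd(r$lesion_kpa),
      lesion_min = min(r$lesion_kpa), lesion_max = max(r$lesion_kpa),
      rmpa_min = min(r$rmpa), rmpa_max = max(r$rmpa),
      force_mean_n = mean(r$plate_force_n),
      p_wilcoxon = p)
  })
  out <- do.call(rbind, rows)
  if (length(out) && nrow(out) == 1 && is.na(out$surface_sd)) {
    out$surface_sd <- 0
    out$lesion_sd <- 0
  }
  out
}

#' Format a sweep summary like the published stress tables
#'
#' @param summary Output of [summarize_sweep()].
#' @return Tibble with character columns `lesion_stiffness`,
#'   `surface_kpa`, `lesion_kpa`, `p_value` (p to three decimals).
#' @export
format_stress_table <- function(summary) {
  tibble::tibble(
    lesion_stiffness = summary$k,
    surface_kpa = sprintf("%.2f±%.2f", summary$surface_mean,
                          ifelse(is.na(summary$surface_sd), 0,
                                 summary$surface_sd)),
    lesion_kpa = sprintf("%.2f±%.2f", summary$lesion_mean,
                         ifelse(is.na(summary$lesion_sd), 0,
                                summary$lesion_sd)),
    p_value = ifelse(summary$p_wilcoxon >= 5e-4,
                     sprintf("%.3f", summary$p_wilcoxon),
                     sprintf("%.0e", summary$p_wilcoxon)))
}

#' Exact Wilcoxon signed-rank test (two-sided)
#'
#' Paired two-sided Wilcoxon signed-rank test. Zero differences are dropped
#' before ranking (the standard reduction). For n <= `exact_max` nonzero
#' differences the null distribution is computed exactly over all 2^n sign
#' assignments (via the generating-function recursion, with midranks doubled
#' to stay integer under ties); above that a normal approximation with tie
#' correction and continuity correction is used.
#'
#' @param x,y Paired samples of equal length (or `y = NULL` for differences
#'   already in `x`).
#' @param exact_max Largest n solved exactly (default 25).
#' @return List with `statistic` (W, sum of positive-difference ranks),
#'   `n` (nonzero differences), `p_value`, `method`.
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 5, 4, 6, 8, 7), rep(1, 7))$p_value # 2/2^7
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  stopifnot(is.null(y) || length(x) == length(y), length(d) >= 1)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; p = 1", call. = FALSE)
    return(list(statistic = 0, n = 0L, p_value = 1, method = "degenerate"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))  # doubled midranks are integers
    tot <- sum(r2)
    # generating function over sign assignments: counts of 2W values
    cnt <- numeric(tot + 1)
    cnt[1] <- 1
    for (rr in r2) {
      shifted <- c(rep(0, rr), cnt[seq_len(tot + 1 - rr)])
      cnt <- cnt + shifted
    }
    probs <- cnt / 2^n
    w2 <- as.integer(round(2 * W))
    p_lo <- sum(probs[seq_len(w2 + 1)])
    p_hi <- sum(probs[(w2 + 1):(tot + 1)])
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    v <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (abs(W - mu) - 0.5) / sqrt(v)
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "normal approximation"
  }
  list(statistic = W, n = n, p_value = p, method = method)
}

#' Stress and RMPA as a function of lesion location
#'
#' Reshapes sweep records into per-band location profiles ordered along the
#' inferior-superior (x) axis: lesion-projection pressure, surface pressure
#' and RMPA per stiffness ratio, the layout of the published
#' stress-versus-location figures.
#'
#' @param result A `sweep_result`.
#' @return Tibble ordered by band, x and k.
#' @export
stress_vs_location_profiles <- function(result) {
  recs <- if (inherits(result, "sweep_result")) result$records else result
  recs <- recs[is.na(recs$error), ]
  out <- recs[order(recs$band, recs$x, recs$k),
              c("band", "loc_id", "x", "y", "z", "k",
                "lesion_kpa", "surface_kpa", "rmpa")]
  tibble::as_tibble(out)
}
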