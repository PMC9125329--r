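# sensor map construction, RMPA, lesion-projection stress

synthetic_map <- function(tiles, covered = NULL) {
  if (is.null(covered)) covered <- matrix(TRUE, nrow(tiles), ncol(tiles))
  structure(list(tiles = tiles, covered = covered, origin = c(0, 0),
                 tile_mm = 10, raster = NULL, raster_mm = 1,
                 plate_force = sum(tiles) * 100 / 1000),
            class = "sensor_map")
}

test_that("tile indexing puts on-edge positions in the lower-index tile", {
  expect_identical(tile_index(c(0, 5, 10, 10.0001, 20, 25), 0, 10),
                   c(1L, 1L, 1L, 2L, 2L, 3L))
  expect_identical(tile_index(-85, -85, 10), 1L)
})

test_that("RMPA on a constructed 7x7 map follows hand arithmetic", {
  tiles <- matrix(6, 7, 7)
  tiles[3:5, 3:5] <- 9  # neighborhood of the center tile
  map <- synthetic_map(tiles)
  # center tile of the bump is (4, 4): position (35, 35)
  r <- rmpa(map, c(35, 35))
  expect_equal(r$neighborhood_mean, 9)
  bg <- (9 * 9 + (49 - 9) * 6) / 49
  expect_equal(r$background_mean, bg)
  expect_equal(r$rmpa, 9 / bg)
  expect_identical(r$lesion_tile, c(4L, 4L))
})

test_that("uniform covered map gives RMPA exactly 1", {
  map <- synthetic_map(matrix(5.5, 6, 6))
  expect_equal(rmpa(map, c(25, 25))$rmpa, 1)
})

test_that("RMPA is invariant under global scaling of the map", {
  set.seed(42)
  tiles <- matrix(stats::runif(49, 4, 9), 7, 7)
  m1 <- synthetic_map(tiles)
  m2 <- synthetic_map(tiles * 3.7)
  expect_equal(rmpa(m1, c(35, 35))$rmpa, rmpa(m2, c(35, 35))$rmpa)
})

test_that("uncovered tiles are excluded from the neighborhood mean", {
  tiles <- matrix(6, 5, 5)
  covered <- matrix(TRUE, 5, 5)
  covered[1, ] <- FALSE   # an uncovered edge column
  tiles[1, ] <- 99        # must not contaminate anything
  map <- synthetic_map(tiles, covered)
  expect_warning(r <- rmpa(map, c(5, 25)), "not fully covered")
  expect_equal(r$rmpa, 1)  # covered neighbors all equal the background
})

test_that("degenerate maps raise classed errors", {
  map <- synthetic_map(matrix(1, 3, 3), matrix(FALSE, 3, 3))
  expect_error(rmpa(map, c(15, 15)), class = "mi_empty_map_error")
  expect_error(sensor_mean(map), class = "mi_empty_map_error")
  expect_error(rmpa(synthetic_map(matrix(1, 3, 3)), c(200, 15)),
               class = "mi_placement_error")
})

test_that("tile pressures conserve the plate force", {
  for (fix in list(block_solution(), cupA_homogeneous())) {
    total <- sum(fix$map$tiles) * fix$map$tile_mm^2 / 1000  # N
    expect_equal(total, fix$sol$plate_force,
                 tolerance = 0.01 * fix$sol$plate_force)
  }
})

test_that("uniform block map reads the uniaxial stress on interior tiles", {
  # tiles whose whole neighborhood lies in the patch read the uniform
  # uniaxial stress; tiles at the discrete patch edge exchange binned force
  # with the outside through the node-footprint kernels and are excluded
  b <- block_solution()
  interior <- matrix(FALSE, nrow(b$map$tiles), ncol(b$map$tiles))
  cv <- b$map$covered
  for (i in 2:(nrow(cv) - 1)) {
    for (j in 2:(ncol(cv) - 1)) {
      interior[i, j] <- all(cv[(i - 1):(i + 1), (j - 1):(j + 1)])
    }
  }
  vals <- b$map$tiles[interior]
  expect_gt(length(vals), 0)
  expect_equal(mean(vals), 6.375, tolerance = 0.02 * 6.375)
  expect_lt(diff(range(vals)) / mean(vals), 0.05)
})

test_that("lesion-projection disc has the nominal area and uniform-field mean", {
  b <- block_solution()
  ls <- lesion_surface_stress(b$map, c(0, 0, 20), diameter = 15)
  expect_equal(as.numeric(ls), 6.375, tolerance = 0.02 * 6.375)
  expect_equal(attr(ls, "covered_fraction"), 1)
  # disc area pi r^2 = 176.7 mm^2: count of 1 mm raster cells within radius
  cells <- sum(outer((seq_len(60) - 0.5) - 20, (seq_len(60) - 0.5) - 20,
                     function(a, b) a^2 + b^2 <= 7.5^2))
  expect_lt(abs(cells - pi * 7.5^2), 10)
})

test_that("partial disc coverage warns with the covered fraction", {
  b <- block_solution()
  expect_warning(lesion_surface_stress(b$map, c(20, 0, 0), diameter = 15),
                 "inside the contact patch")
})

test_that("homogeneous phantom RMPA is near 1 at interior tiles", {
  a <- cupA_homogeneous()
  locs <- default_locations("A")
  vals <- sapply(seq_len(nrow(locs)), function(i) {
    suppressWarnings(rmpa(a$map, c(locs$x[i], 0, locs$z[i]))$rmpa)
  })
  # the columnar pressure dome keeps interior neighborhoods within ~10%
  expect_true(all(vals > 0.9 & vals < 1.12))
  expect_lt(abs(stats::median(vals) - 1), 0.1)
})

test_that("lesion elevates the projection stress when k > 1", {
  res <- cupA_sweep()
  recs <- res$records[is.na(res$records$error), ]
  expect_true(all(recs$lesion_kpa > 0))
  # shallow mid-breast lesions read above the background for every k
  sh <- recs[recs$band == "shallow" & abs(recs$x) <= 10, ]
  expect_true(all(sh$lesion_kpa > sh$surface_kpa))
})
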