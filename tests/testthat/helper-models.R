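# Shared fixtures, memoized across test files (test_dir sources helpers once
# per run). All fixtures are built in code at the desk-scale resolution the
# package documents for result reproduction (4 mm voxels, 5 increments).

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, fn) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, fn(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# homogeneous uniaxial calibration block (strictly linear oracle mode)
block_solution <- function() {
  cached("block", function() {
    ph <- block_phantom(40, 40, 40, 10)
    mesh <- classify_boundaries(voxels_to_tets(ph))
    sol <- solve_compression(mesh, material_table(1),
                             compression_case(0.5, single_step = TRUE,
                                              fix_chest_z = FALSE))
    map <- pressure_map(sol, mesh)
    list(phantom = ph, mesh = mesh, sol = sol, map = map)
  })
}

# homogeneous cup A compression at desk scale
cupA_homogeneous <- function() {
  cached("cupA_hom", function() {
    ph <- build_outline(cup_spec("A"), 4)
    mesh <- classify_boundaries(voxels_to_tets(ph))
    mesh$origin <- ph$origin
    sol <- solve_compression(mesh, material_table(1),
                             compression_case(0.5, 5, "linear",
                                              thickness0 = 75))
    map <- pressure_map(sol, mesh)
    list(phantom = ph, mesh = mesh, sol = sol, map = map)
  })
}

# full cup A sweep (21 cases) at desk scale
cupA_sweep <- function() {
  cached("cupA_sweep", function() {
    run_sweep(sweep_config("A", voxel_mm = 4, n_increments = 5))
  })
}

# cup B sweep restricted to k = 15 (52 cases) at desk scale
cupB_sweep_k15 <- function() {
  cached("cupB_sweep", function() {
    run_sweep(sweep_config("B", voxel_mm = 4, k = 15, n_increments = 5))
  })
}

# small deterministic tet mesh wrapping one unit voxel at given edge h
single_voxel_mesh <- function(h = 10) {
  classify_boundaries(voxels_to_tets(block_phantom(h, h, h, h)))
}

# brute-force Wilcoxon signed-rank two-sided p by explicit enumeration of
# all 2^n sign assignments (independent oracle; n <= ~15)
wilcoxon_brute_force <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wall <- as.vector(signs %*% r)
  p_lo <- mean(Wall <= W + 1e-9)
  p_hi <- mean(Wall >= W - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}
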