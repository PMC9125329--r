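# element stiffness, stress recovery, contact solve

# independent single-tet stiffness oracle: energy Hessian by exact finite
# differences of U(u) = V/2 eps:C:eps, with the strain obtained by fitting
# the affine displacement field through the four nodes (no shape-function
# gradient code shared with the implementation)
tet_stiffness_oracle <- function(P, E, nu) {
  mu <- E / (2 * (1 + nu))
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  Xrel <- rbind(P[2, ] - P[1, ], P[3, ] - P[1, ], P[4, ] - P[1, ])
  V <- abs(det(Xrel)) / 6
  energy <- function(uvec) {
    U <- matrix(uvec, 4, 3, byrow = TRUE)
    Urel <- rbind(U[2, ] - U[1, ], U[3, ] - U[1, ], U[4, ] - U[1, ])
    M <- t(solve(Xrel, Urel))          # displacement gradient
    eps <- (M + t(M)) / 2
    V * (lam / 2 * sum(diag(eps))^2 + mu * sum(eps^2))
  }
  K <- matrix(0, 12, 12)
  e <- diag(12)
  u0 <- energy(numeric(12))
  for (i in 1:12) for (j in i:12) {
    K[i, j] <- K[j, i] <-
      energy(e[i, ] + e[j, ]) - energy(e[i, ]) - energy(e[j, ]) + u0
  }
  K
}

one_tet_mesh <- function(P) {
  structure(list(nodes = P, tets = matrix(1:4, 1), labels = 1L,
                 voxel_of = NULL, voxel_mm = 1, chest_nodes = integer(0),
                 surface_nodes = integer(0), surface_faces = NULL),
            class = "tet_mesh")
}

test_that("single-tet stiffness matches the energy-Hessian oracle", {
  set.seed(11)
  for (rep in 1:3) {
    P <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3, byrow = TRUE) +
      matrix(stats::runif(12, -0.15, 0.15), 4, 3)
    mesh <- one_tet_mesh(P)
    K <- as.matrix(assemble_stiffness(mesh, material_table(1, 12.75, 0.3),
                                      stabilize_volumetric = FALSE))
    Ko <- tet_stiffness_oracle(P, 12.75, 0.3)
    expect_equal(K, Ko, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("assembled operator is symmetric and annihilates rigid modes", {
  ph <- block_phantom(20, 20, 20, 10)
  mesh <- voxels_to_tets(ph)
  K <- assemble_stiffness(mesh, material_table(15))
  expect_lt(max(abs(K - Matrix::t(K))), 1e-10)
  X <- mesh$nodes
  modes <- cbind(
    rep(c(1, 0, 0), nrow(X)), rep(c(0, 1, 0), nrow(X)),
    rep(c(0, 0, 1), nrow(X)),
    as.vector(t(cbind(-X[, 2], X[, 1], 0))),   # rotation about z (linearized)
    as.vector(t(cbind(X[, 3], 0, -X[, 1]))),   # rotation about y
    as.vector(t(cbind(0, -X[, 3], X[, 2]))))   # rotation about x
  nrm <- max(abs(K))
  for (c in 1:6) {
    expect_lt(max(abs(K %*% modes[, c])), 1e-8 * nrm)
  }
})

test_that("zero-volume element is reported by name", {
  P <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0.5, 0.5, 0), 4, 3, byrow = TRUE)
  expect_error(assemble_stiffness(one_tet_mesh(P), material_table(1)),
               class = "mi_assembly_error")
})

test_that("uniform strain fields are reproduced exactly (patch test)", {
  # constant-strain field: interior equilibrium residual must vanish for
  # both the plain and the cell-mean stabilized operator
  ph <- block_phantom(30, 30, 30, 10)
  mesh <- classify_boundaries(voxels_to_tets(ph))
  u <- mesh$nodes %*% matrix(c(0.02, 0.01, 0, 0.005, -0.05, 0.01,
                               0, 0.003, 0.015), 3, 3)
  interior <- setdiff(seq_len(nrow(mesh$nodes)), mesh$surface_nodes)
  idof <- as.vector(outer(3 * (interior - 1), 1:3, "+"))
  for (stab in c(TRUE, FALSE)) {
    K <- assemble_stiffness(mesh, material_table(1), stab)
    r <- as.vector(K %*% as.vector(t(u)))
    expect_lt(max(abs(r[idof])), 1e-8 * max(abs(r)))
  }
})

test_that("stress recovery matches Hooke's law on imposed fields", {
  ph <- block_phantom(20, 20, 20, 10)
  mesh <- voxels_to_tets(ph)
  mats <- material_table(15)  # lesion label unused here
  E <- 12.75; nu <- 0.49
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  # pure uniaxial y-compression: eps_yy = -0.5
  u <- cbind(0, -0.5 * mesh$nodes[, 2], 0)
  s <- recover_stresses(mesh, mats, u)
  expect_equal(unname(s[, "yy"]), rep((lam + 2 * mu) * -0.5, nrow(s)))
  expect_equal(unname(s[, "xx"]), rep(lam * -0.5, nrow(s)))
  expect_equal(unname(s[, "xy"]), rep(0, nrow(s)))
  # rigid translation: zero stress
  u0 <- cbind(3, -2, 1)[rep(1, nrow(mesh$nodes)), ]
  expect_lt(max(abs(recover_stresses(mesh, mats, u0))), 1e-10)
})

test_that("stress scales exactly with the stiffness ratio", {
  ph <- block_phantom(20, 20, 20, 10)
  mesh <- voxels_to_tets(ph)
  mesh$labels[] <- 2L  # all lesion
  u <- cbind(0.1 * mesh$nodes[, 2], -0.3 * mesh$nodes[, 2], 0)
  s1 <- recover_stresses(mesh, material_table(1), u)
  s15 <- recover_stresses(mesh, material_table(15), u)
  expect_equal(s15, 15 * s1, tolerance = 1e-12)
})

test_that("homogeneous block at 50% compression reaches sigma = E/2", {
  # frictionless plates, free lateral faces: uniform uniaxial stress
  # |sigma_yy| = E * 0.5 = 6.375 kPa; anchors the reported surface-stress
  # regime
  b <- block_solution()
  syy <- b$sol$sigma[, "yy"]
  expect_equal(mean(syy), -6.375, tolerance = 0.02 * 6.375)
  expect_lt(diff(range(syy)), 1e-6)
  # plate force = sigma x contact area
  expect_equal(b$sol$plate_force, 6.375 * 40 * 40 / 1000,
               tolerance = 0.02 * 10.2)
  # zero travel would mean zero stress: increments scale linearly
  expect_equal(b$sol$log$plate_force_n[1], b$sol$plate_force)
})

test_that("plate and support reactions balance to solver precision", {
  b <- block_solution()
  expect_lt(abs(b$sol$plate_force - b$sol$support_force) /
              b$sol$plate_force, 1e-6)
  a <- cupA_homogeneous()
  expect_lt(abs(a$sol$plate_force - a$sol$support_force) /
              a$sol$plate_force, 1e-6)
})

test_that("external work matches stored energy for the linear block", {
  b <- block_solution()
  expect_equal(b$sol$work_external, b$sol$energy_strain,
               tolerance = 1e-8)
  # on the breast the plate force grows nonlinearly with travel (the
  # contact patch spreads), so the trapezoid work estimate converges to the
  # stored energy as increments refine
  a <- cupA_homogeneous()
  mesh <- a$mesh
  sols <- lapply(c(2, 10), function(n) {
    solve_compression(mesh, material_table(1),
                      compression_case(0.5, n, "linear", thickness0 = 75))
  })
  err <- sapply(sols, function(s) abs(s$work_external - s$energy_strain))
  expect_lt(err[2], err[1])
})

test_that("contact complementarity holds at the converged state", {
  a <- cupA_homogeneous()
  sol <- a$sol
  mesh <- a$mesh
  # no penetration beyond tolerance
  ydef <- sol$nodes_deformed[mesh$surface_nodes, 2]
  expect_lt(max(ydef) - sol$plate_y, 1e-6)
  expect_gt(min(ydef), sol$support_y - 1e-6)
  # no adhesive reactions on active sets
  expect_gt(min(sol$plate_reactions), -1e-6)
  expect_gt(min(sol$support_reactions), -1e-6)
  # active nodes sit on their plane (gap x reaction = 0)
  expect_lt(max(abs(sol$nodes_deformed[sol$active_plate, 2] - sol$plate_y)),
            1e-9)
  expect_lt(max(abs(sol$nodes_deformed[sol$active_support, 2])), 1e-9)
})

test_that("zero plate travel is rejected, thin meshes flagged", {
  mesh <- single_voxel_mesh(10)
  case <- compression_case(0.5, 2, thickness0 = 30)  # final gap 15 > 10
  expect_error(solve_compression(mesh, material_table(1), case),
               class = "mi_solver_error")
})

test_that("mean surface stress is stable between 4 and 3 mm meshes", {
  a4 <- cupA_homogeneous()
  ph3 <- build_outline(cup_spec("A"), 3)
  m3 <- classify_boundaries(voxels_to_tets(ph3))
  m3$origin <- ph3$origin
  sol3 <- solve_compression(m3, material_table(1),
                            compression_case(0.5, 5, "linear",
                                             thickness0 = 75))
  map3 <- pressure_map(sol3, m3)
  expect_equal(sensor_mean(map3), sensor_mean(a4$map), tolerance = 0.05)
})
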