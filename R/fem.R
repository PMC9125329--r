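#' Material table for the compression model
#'
#' Both tissue classes are isotropic linear elastic. Adipose tissue uses
#' E = 12.75 kPa and Poisson's ratio 0.49 (nearly incompressible); the lesion
#' modulus is `stiffness_ratio` times the adipose modulus with the same
#' Poisson's ratio. Units are kPa and mm throughout, so assembled forces are
#' in mN (1 kPa x 1 mm^2 = 1 mN).
#'
#' @param stiffness_ratio Lesion-to-adipose modulus ratio k (15, 30 or 50 in
#'   the default sweeps; any positive value is accepted).
#' @param E_adipose Adipose Young's modulus in kPa.
#' @param nu Poisson's ratio, identical for both classes; must be in
#'   \[0, 0.5).
#' @return A `material_table` with per-label `E` (named "1", "2") and `nu`.
#' @export
material_table <- function(stiffness_ratio = 1, E_adipose = 12.75, nu = 0.49) {
  stopifnot(E_adipose > 0, stiffness_ratio > 0, nu >= 0, nu < 0.5)
  structure(list(E = c("1" = E_adipose, "2" = E_adipose * stiffness_ratio),
                 nu = nu, stiffness_ratio = stiffness_ratio),
            class = "material_table")
}

lame_parameters <- function(E, nu) {
  mu <- E / (2 * (1 + nu))
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  list(mu = mu, lambda = lambda, kappa = lambda + 2 * mu / 3)
}

# sum `x` into `n` bins given by integer bin ids `g`
rowsum_vec <- function(x, g, n) {
  out <- numeric(n)
  r <- rowsum(x, g)
  out[as.integer(rownames(r))] <- r[, 1]
  out
}

# triplet aggregation scaffold: `pattern` is the summed sparse matrix with a
# writable @x slot in compressed-column order, `S` maps raw triplet values to
# those slots so repeated assemblies are a single sparse-dense product
make_aggregator <- function(ii, jj, nr, nc) {
  key <- (as.double(jj) - 1) * nr + as.double(ii)
  keys <- sort(unique(key))
  slot <- findInterval(key, keys)
  pattern <- Matrix::sparseMatrix(
    i = as.integer((keys - 1) %% nr) + 1L,
    j = as.integer((keys - 1) %/% nr) + 1L,
    x = rep(0, length(keys)), dims = c(nr, nc))
  stopifnot(length(pattern@x) == length(keys))
  S <- Matrix::sparseMatrix(i = slot, j = seq_along(slot), x = 1,
                            dims = c(length(keys), length(slot)))
  list(pattern = pattern, S = S)
}

#' Precompute connectivity-dependent assembly scaffolding for a mesh
#'
#' Builds, once per mesh: the per-element degree-of-freedom map, the global
#' stiffness sparsity pattern together with an aggregation operator that
#' turns per-element 12 x 12 stiffness values into the packed column-
#' compressed value slot order, and the same scaffolding for the cell-mean
#' dilatation operator used for volumetric locking relief (cells are the
#' parent voxels of the structured subdivision). None of this depends on
#' node positions or materials, so it is reused across lesion cases and
#' across the geometry updates of the incremental solver.
#'
#' @param mesh A `tet_mesh`.
#' @return An opaque `fem_geometry` list.
#' @export
fem_geometry <- function(mesh) {
  t <- mesh$tets
  ne <- nrow(t)
  nd <- 3L * nrow(mesh$nodes)
  dofcols <- matrix(vapply(1:12, function(c) {
    a <- (c - 1) %/% 3 + 1
    3L * (t[, a] - 1L) + as.integer((c - 1) %% 3 + 1)
  }, integer(ne)), nrow = ne)
  ncomb <- 144L
  ii <- integer(ne * ncomb); jj <- integer(ne * ncomb)
  pos <- 0L
  for (a in 1:4) for (i in 1:3) for (b in 1:4) for (j in 1:3) {
    sl <- pos * ne + seq_len(ne)
    ii[sl] <- dofcols[, (a - 1) * 3 + i]
    jj[sl] <- dofcols[, (b - 1) * 3 + j]
    pos <- pos + 1L
  }
  aggK <- make_aggregator(ii, jj, nd, nd)
  if (!is.null(mesh$voxel_of)) {
    cell <- match(mesh$voxel_of, unique(mesh$voxel_of))
  } else {
    cell <- seq_len(ne)
  }
  ncell <- max(cell)
  aggD <- make_aggregator(rep(cell, 12), as.vector(dofcols), ncell, nd)
  structure(list(ne = ne, ndof = nd, tets = t, dofcols = dofcols,
                 cell = cell, ncell = ncell, aggK = aggK, aggD = aggD),
            class = "fem_geometry")
}

# geometry-dependent element quantities on node positions X:
# shape-function gradients G (ne x 12), volumes V, the two 144-block
# stiffness value vectors (unit-lambda and unit-mu factors), and the
# cell-mean dilatation operator Dv
geom_values <- function(geom, X) {
  t <- geom$tets
  ne <- geom$ne
  e1 <- X[t[, 2], , drop = FALSE] - X[t[, 1], , drop = FALSE]
  e2 <- X[t[, 3], , drop = FALSE] - X[t[, 1], , drop = FALSE]
  e3 <- X[t[, 4], , drop = FALSE] - X[t[, 1], , drop = FALSE]
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  c23 <- cr(e2, e3)
  v6 <- rowSums(e1 * c23)
  if (any(v6 <= 0)) {
    stop2("mi_assembly_error", paste0(
      "zero- or negative-volume element(s): ",
      paste(utils::head(which(v6 <= 0), 5), collapse = ", ")))
  }
  V <- v6 / 6
  G <- matrix(0, ne, 12)
  G[, 4:6] <- c23 / v6
  G[, 7:9] <- cr(e3, e1) / v6
  G[, 10:12] <- cr(e1, e2) / v6
  G[, 1:3] <- -(G[, 4:6] + G[, 7:9] + G[, 10:12])
  dot <- array(0, c(ne, 4, 4))
  for (a in 1:4) for (b in 1:4) {
    dot[, a, b] <- rowSums(G[, (a - 1) * 3 + 1:3, drop = FALSE] *
                             G[, (b - 1) * 3 + 1:3, drop = FALSE])
  }
  K1 <- numeric(ne * 144L); K2 <- numeric(ne * 144L)
  pos <- 0L
  for (a in 1:4) for (i in 1:3) for (b in 1:4) for (j in 1:3) {
    sl <- pos * ne + seq_len(ne)
    K1[sl] <- V * G[, (a - 1) * 3 + i] * G[, (b - 1) * 3 + j]
    K2[sl] <- V * (G[, (a - 1) * 3 + j] * G[, (b - 1) * 3 + i] +
                     (i == j) * dot[, a, b])
    pos <- pos + 1L
  }
  Vcell <- as.vector(rowsum_vec(V, geom$cell, geom$ncell))
  Dv <- geom$aggD$pattern
  Dv@x <- as.vector(geom$aggD$S %*% as.vector(G * (V / Vcell[geom$cell])))
  list(G = G, V = V, K1 = K1, K2 = K2, Vcell = Vcell, Dv = Dv)
}

element_materials <- function(mesh, mats) {
  E <- unname(mats$E[as.character(mesh$labels)])
  if (anyNA(E)) stop("materials do not cover all mesh labels", call. = FALSE)
  lame_parameters(E, mats$nu)
}

# fraction of the volumetric energy kept element-wise when the cell-mean
# dilatation treatment is active: suppresses the near-zero-energy
# checkerboard modes of a pure mean-dilatation operator (which otherwise
# break the Cholesky factorization) at a negligible re-locking cost
VOL_BLEND <- 0.05

build_stiffness <- function(geom, gv, lp, stabilize_volumetric) {
  rep144 <- function(v) rep.int(v, 144L)
  if (stabilize_volumetric) {
    vals <- rep144(VOL_BLEND * lp$kappa - 2 / 3 * lp$mu) * gv$K1 +
      rep144(lp$mu) * gv$K2
  } else {
    vals <- rep144(lp$lambda) * gv$K1 + rep144(lp$mu) * gv$K2
  }
  K <- geom$aggK$pattern
  K@x <- as.vector(geom$aggK$S %*% vals)
  if (stabilize_volumetric) {
    kappa_cell <- as.vector(rowsum_vec(lp$kappa * gv$V, geom$cell,
                                       geom$ncell)) / gv$Vcell
    K <- K + Matrix::crossprod(gv$Dv, gv$Dv * ((1 - VOL_BLEND) *
                                                 kappa_cell * gv$Vcell))
  }
  Matrix::forceSymmetric(K)
}

# internal nodal force vector of a stress field sigma (ne x 6) on geometry gv
internal_force <- function(geom, gv, sigma) {
  sidx <- matrix(c(1, 4, 6, 4, 2, 5, 6, 5, 3), 3, 3)  # (i,j) -> sigma column
  vals <- matrix(0, geom$ne, 12)
  for (a in 1:4) for (i in 1:3) {
    acc <- 0
    for (j in 1:3) {
      acc <- acc + gv$G[, (a - 1) * 3 + j] * sigma[, sidx[i, j]]
    }
    vals[, (a - 1) * 3 + i] <- gv$V * acc
  }
  rowsum_vec(as.vector(vals), as.vector(geom$dofcols), geom$ndof)
}

# stress increment of a displacement increment du (dof vector) on gv
stress_increment <- function(geom, gv, lp, du, stabilize_volumetric) {
  t <- geom$tets
  G <- gv$G
  um <- matrix(du, ncol = 3, byrow = TRUE)
  comp <- function(i, j) {
    out <- 0
    for (a in 1:4) out <- out + G[, (a - 1) * 3 + i] * um[t[, a], j]
    out
  }
  exx <- comp(1, 1); eyy <- comp(2, 2); ezz <- comp(3, 3)
  exy <- 0.5 * (comp(1, 2) + comp(2, 1))
  eyz <- 0.5 * (comp(2, 3) + comp(3, 2))
  ezx <- 0.5 * (comp(3, 1) + comp(1, 3))
  tr <- exx + eyy + ezz
  if (stabilize_volumetric) {
    theta_cell <- as.vector(gv$Dv %*% du)
    svol <- lp$kappa * ((1 - VOL_BLEND) * theta_cell[geom$cell] +
                          VOL_BLEND * tr) - 2 / 3 * lp$mu * tr
  } else {
    svol <- lp$lambda * tr
  }
  cbind(xx = svol + 2 * lp$mu * exx,
        yy = svol + 2 * lp$mu * eyy,
        zz = svol + 2 * lp$mu * ezz,
        xy = 2 * lp$mu * exy,
        yz = 2 * lp$mu * eyz,
        zx = 2 * lp$mu * ezx)
}

#' Assemble the global stiffness operator on the reference geometry
#'
#' Linear 4-node (constant strain) tetrahedra. With
#' `stabilize_volumetric = TRUE` (the default) the volumetric energy is
#' evaluated on the mean dilatation of each parent voxel cell (the 6-tet
#' group) instead of element-wise, which relieves the volumetric locking that
#' plain linear tetrahedra exhibit at Poisson's ratio 0.49 while keeping
#' displacement-element sparsity; the deviatoric part stays element-wise.
#' Uniform strain fields are reproduced exactly either way (the average of a
#' constant is that constant), so the patch test is unaffected.
#'
#' @param mesh A `tet_mesh`.
#' @param mats A [material_table()].
#' @param stabilize_volumetric Use cell-mean dilatation (default `TRUE`).
#' @param geom Optional precomputed [fem_geometry()] for this mesh.
#' @return A symmetric sparse stiffness matrix (kPa.mm units: u in mm gives
#'   forces in mN).
#' @export
assemble_stiffness <- function(mesh, mats, stabilize_volumetric = TRUE,
                               geom = NULL) {
  if (is.null(geom)) geom <- fem_geometry(mesh)
  gv <- geom_values(geom, mesh$nodes)
  build_stiffness(geom, gv, element_materials(mesh, mats),
                  stabilize_volumetric)
}

#' Compression case settings
#'
#' Describes one quasi-static plate-compression run: the breast support is a
#' fixed rigid plane at y = 0, the compression plate is a rigid plane that
#' moves in -y from its starting position to a final gap of
#' `(1 - compression_fraction)` times the initial thickness. Contact with
#' both planes is frictionless and unilateral (nodes slide freely in-plane,
#' cannot penetrate, and release when their reaction turns tensile). Chest
#' nodes (z = 0) are fixed in z; one plate-contact node is additionally fixed
#' in x and z to remove the remaining rigid-body modes.
#'
#' Kinematics: `"updated"` (default) advances the plate in `n_increments`
#' steps, accumulating a small-strain linear-elastic stress increment on the
#' current (deformed) geometry at each step - an incremental updated-
#' Lagrangian scheme, appropriate at the 50% compressions simulated here.
#' `"linear"` keeps the reference geometry throughout (strictly linear
#' theory); `single_step = TRUE` selects linear kinematics in one increment,
#' the configuration used by the closed-form uniaxial oracle.
#'
#' @param compression_fraction Fraction of the initial thickness removed
#'   (default 0.5, i.e. compression to 50% of original thickness).
#' @param n_increments Number of plate-travel increments (default 10).
#' @param kinematics `"updated"` or `"linear"`.
#' @param fix_chest_z Fix z-displacement of chest-plane nodes (default
#'   `TRUE`; disable for free-standing calibration blocks).
#' @param thickness0 Initial breast thickness along y (mm). Default `NULL`
#'   uses the mesh extent; the sweep driver passes the cup's nominal
#'   `extent_y` so the staircase voxel surface does not inflate the travel.
#' @param single_step Strictly linear one-shot solve (oracle mode).
#' @param max_active_iter Active-set iteration budget per increment.
#' @param tol_penetration Allowed residual penetration (mm).
#' @export
compression_case <- function(compression_fraction = 0.5, n_increments = 10,
                             kinematics = c("updated", "linear"),
                             fix_chest_z = TRUE, thickness0 = NULL,
                             single_step = FALSE, max_active_iter = 40,
                             tol_penetration = 1e-8) {
  stopifnot(compression_fraction > 0, compression_fraction < 1,
            n_increments >= 1)
  kinematics <- match.arg(kinematics)
  if (single_step) {
    kinematics <- "linear"
    n_increments <- 1
  }
  structure(list(compression_fraction = compression_fraction,
                 n_increments = as.integer(n_increments),
                 kinematics = kinematics,
                 fix_chest_z = fix_chest_z, thickness0 = thickness0,
                 single_step = single_step,
                 max_active_iter = max_active_iter,
                 tol_penetration = tol_penetration),
            class = "compression_case")
}

solve_spd <- function(K, b) {
  # supernodal Cholesky: substantially faster than the simplicial default
  # on these 3-D elasticity patterns
  ch <- tryCatch(
    suppressWarnings(Matrix::Cholesky(K, LDL = FALSE, perm = TRUE,
                                      super = TRUE)),
    error = function(e) NULL)
  if (is.null(ch)) return(as.vector(Matrix::solve(K, b)))
  as.vector(Matrix::solve(ch, b))
}

#' Solve quasi-static plate compression of a meshed phantom
#'
#' Unilateral frictionless contact against the two rigid planes is resolved
#' by an active-set method: surface nodes that would penetrate a plane get
#' their y-displacement prescribed onto it, nodes whose contact reaction
#' turns tensile are released, iterated to a fixed point within each
#' plate-travel increment. Within an increment the constitutive response is
#' linear elastic; with the default updated-Lagrangian kinematics the node
#' positions and stress state carry over from increment to increment (see
#' [compression_case()]).
#'
#' @param mesh A `tet_mesh` (boundaries are classified on the fly if needed).
#' @param mats A [material_table()].
#' @param case A [compression_case()].
#' @param geom Optional [fem_geometry()] cache.
#' @param stabilize_volumetric Use cell-mean dilatation locking relief
#'   (default `TRUE`).
#' @param init_active Optional warm start: a list with `plate` and `support`
#'   node-index vectors (typically the converged sets of a neighboring
#'   case). Under linear kinematics the solution is path-independent, so a
#'   warm-started solve runs a single increment at full travel and lets the
#'   active-set iteration correct the set; ignored for updated kinematics.
#' @param verbose Print per-increment convergence lines.
#' @return A `displacement_solution`: total nodal displacements `u` (n x 3,
#'   mm), per-tet stress `sigma` (kPa, columns xx, yy, zz, xy, yz, zx;
#'   compression negative), deformed node positions `nodes_deformed`,
#'   `active_plate`/`active_support` node indices with reaction forces (mN,
#'   compressive positive), `plate_force`/`support_force` (N), the final
#'   plate position, an increment log, and energy bookkeeping
#'   (`work_external`, `energy_strain`, N.mm).
#' @export
solve_compression <- function(mesh, mats, case = compression_case(),
                              geom = NULL, stabilize_volumetric = TRUE,
                              init_active = NULL, verbose = FALSE) {
  stopifnot(inherits(mesh, "tet_mesh"), inherits(mats, "material_table"),
            inherits(case, "compression_case"))
  if (length(mesh$surface_nodes) == 0) mesh <- classify_boundaries(mesh)
  if (is.null(geom)) geom <- fem_geometry(mesh)
  lp <- element_materials(mesh, mats)
  nd <- geom$ndof
  updated <- case$kinematics == "updated"

  X0 <- mesh$nodes
  Xc <- X0
  Y0 <- X0[, 2]
  support_y <- 0
  plate_y0 <- max(Y0)
  thick0 <- case$thickness0 %||% (plate_y0 - support_y)
  plate_final <- support_y + (1 - case$compression_fraction) * thick0
  if (plate_final >= plate_y0) {
    stop2("mi_solver_error", "no plate travel: mesh thinner than final gap")
  }

  surf <- mesh$surface_nodes
  fixed_idx <- integer(0)
  if (case$fix_chest_z && length(mesh$chest_nodes)) {
    fixed_idx <- c(fixed_idx, 3L * (mesh$chest_nodes - 1L) + 3L)
  }
  top_candidates <- surf[Y0[surf] > support_y + 0.5 * (plate_y0 - support_y)]
  zmid <- max(X0[, 3]) / 2
  pin <- top_candidates[order(X0[top_candidates, 1]^2 +
                                (Y0[top_candidates] - plate_y0)^2 +
                                (X0[top_candidates, 3] - zmid)^2,
                              top_candidates)][1]
  fixed_idx <- c(fixed_idx, 3L * (pin - 1L) + 1L, 3L * (pin - 1L) + 3L)
  if (!case$fix_chest_z) {
    pin2 <- top_candidates[which.max(abs(X0[top_candidates, 1] -
                                           X0[pin, 1]))]
    fixed_idx <- c(fixed_idx, 3L * (pin2 - 1L) + 3L)
  }
  fixed_idx <- sort(unique(fixed_idx))

  active_plate <- surf[Y0[surf] >= max(Y0[surf]) - 1e-9]
  active_support <- surf[Y0[surf] <= min(Y0[surf]) + 1e-9]
  n_inc <- case$n_increments
  if (!is.null(init_active) && case$kinematics == "linear") {
    active_plate <- sort(union(active_plate, init_active$plate))
    active_support <- sort(union(active_support, init_active$support))
    n_inc <- 1L
  }
  u_tot <- numeric(nd)
  sigma <- matrix(0, geom$ne, 6,
                  dimnames = list(NULL, c("xx", "yy", "zz", "xy", "yz", "zx")))
  log_rows <- list()
  work_ext <- 0
  force_prev <- 0
  plate_prev <- plate_y0
  ydof <- function(nodes) 3L * (nodes - 1L) + 2L
  f_tol <- 1e-7  # mN

  gv <- geom_values(geom, Xc)
  K <- build_stiffness(geom, gv, lp, stabilize_volumetric)

  for (inc in seq_len(n_inc)) {
    plate_t <- plate_y0 + (plate_final - plate_y0) * inc / n_inc
    if (updated && inc > 1L) {
      gv <- geom_values(geom, Xc)
      K <- build_stiffness(geom, gv, lp, stabilize_volumetric)
    }
    f0 <- internal_force(geom, gv, sigma)
    # current node heights in space (Xc only tracks them under updated
    # kinematics; under linear kinematics the accumulated u supplies them)
    Ycur <- Y0 + u_tot[seq(2L, nd, by = 3L)]
    du <- numeric(nd)
    it <- 0L
    repeat {
      it <- it + 1L
      cdof <- c(fixed_idx, ydof(active_plate), ydof(active_support))
      cval <- c(rep(0, length(fixed_idx)),
                plate_t - Ycur[active_plate],
                support_y - Ycur[active_support])
      dup <- duplicated(cdof)
      cdof <- cdof[!dup]; cval <- cval[!dup]
      free <- setdiff(seq_len(nd), cdof)
      Kff <- Matrix::forceSymmetric(K[free, free])
      rhs <- -f0[free] - as.vector(K[free, cdof, drop = FALSE] %*% cval)
      du <- numeric(nd)
      du[cdof] <- cval
      du[free] <- solve_spd(Kff, rhs)
      r <- f0 + as.vector(K %*% du)

      rel_p <- active_plate[r[ydof(active_plate)] > f_tol]
      rel_s <- active_support[r[ydof(active_support)] < -f_tol]
      if (length(rel_p) >= length(active_plate)) {
        rel_p <- setdiff(rel_p, active_plate[which.min(r[ydof(active_plate)])])
      }
      if (length(rel_s) >= length(active_support)) {
        rel_s <- setdiff(rel_s,
                         active_support[which.max(r[ydof(active_support)])])
      }
      ypos <- Ycur[surf] + du[ydof(surf)]
      add_p <- setdiff(surf[ypos > plate_t + case$tol_penetration],
                       active_plate)
      add_s <- setdiff(surf[ypos < support_y - case$tol_penetration],
                       active_support)
      changed <- length(rel_p) + length(rel_s) + length(add_p) + length(add_s)
      active_plate <- sort(union(setdiff(active_plate, rel_p), add_p))
      active_support <- sort(union(setdiff(active_support, rel_s), add_s))
      if (changed == 0L) break
      if (it >= case$max_active_iter) {
        stop2("mi_solver_error", sprintf(
          "contact active set not converged in %d iterations at increment %d (%d pending changes)",
          case$max_active_iter, inc, changed))
      }
    }
    sigma <- sigma + stress_increment(geom, gv, lp, du, stabilize_volumetric)
    u_tot <- u_tot + du
    if (updated) Xc <- Xc + matrix(du, ncol = 3, byrow = TRUE)
    force_now <- -sum(r[ydof(active_plate)]) / 1000
    work_ext <- work_ext + 0.5 * (force_now + force_prev) *
      (plate_prev - plate_t)
    force_prev <- force_now
    plate_prev <- plate_t
    log_rows[[inc]] <- data.frame(
      increment = inc, plate_y = plate_t, iterations = it,
      n_active_plate = length(active_plate),
      n_active_support = length(active_support), plate_force_n = force_now)
    if (verbose) {
      message(sprintf(
        "inc %2d: plate %7.2f mm, %2d it, %4d/%4d contacts, F = %.3f N",
        inc, plate_t, it, length(active_plate), length(active_support),
        force_now))
    }
  }

  umat <- matrix(u_tot, ncol = 3, byrow = TRUE)
  structure(list(
    u = umat, sigma = sigma,
    nodes_deformed = X0 + umat,
    active_plate = active_plate, active_support = active_support,
    plate_reactions = -r[ydof(active_plate)],
    support_reactions = r[ydof(active_support)],
    plate_force = -sum(r[ydof(active_plate)]) / 1000,
    support_force = sum(r[ydof(active_support)]) / 1000,
    plate_y = plate_t, support_y = support_y, pin_node = pin,
    thickness0 = thick0, case = case, mats = mats,
    work_external = work_ext,
    energy_strain = if (updated) NA_real_ else
      0.5 * sum(u_tot * as.vector(K %*% u_tot)) / 1000,
    log = do.call(rbind, log_rows)), class = "displacement_solution")
}

#' @export
print.displacement_solution <- function(x, ...) {
  cat(sprintf(
    "<displacement_solution> plate at y = %.2f mm, F = %.2f N, %d plate / %d support contacts\n",
    x$plate_y, x$plate_force, length(x$active_plate),
    length(x$active_support)))
  invisible(x)
}

#' Recover per-element stress from a displacement field (reference geometry)
#'
#' Constant strain per tetrahedron from the shape-function gradients,
#' Hooke's law sigma = lambda tr(eps) I + 2 mu eps. With
#' `averaged_pressure = TRUE` the volumetric part uses the cell-mean
#' dilatation (consistent with the stabilized stiffness); the plain
#' element-wise law is the textbook oracle path. This is the strictly linear
#' stress map; the incremental solver accumulates its own stress state.
#'
#' @param mesh A `tet_mesh`.
#' @param mats A [material_table()].
#' @param u Nodal displacements, n x 3 matrix (mm).
#' @param geom Optional [fem_geometry()].
#' @param averaged_pressure Use cell-mean dilatation (default `FALSE`).
#' @return m x 6 stress matrix (kPa), columns xx, yy, zz, xy, yz, zx
#'   (tensor shear components). Compression is negative here; reporting
#'   layers convert to positive compressive magnitudes.
#' @export
recover_stresses <- function(mesh, mats, u, geom = NULL,
                             averaged_pressure = FALSE) {
  if (is.null(geom)) geom <- fem_geometry(mesh)
  stopifnot(is.matrix(u), nrow(u) == nrow(mesh$nodes), ncol(u) == 3)
  gv <- geom_values(geom, mesh$nodes)
  lp <- element_materials(mesh, mats)
  stress_increment(geom, gv, lp, as.vector(t(u)), averaged_pressure)
}

#' Total compression-direction plate reaction force
#'
#' Sum of the compression-direction nodal contact reactions on the moving
#' plate, as a positive force in N. By global equilibrium it matches the
#' support-plane reaction to solver precision.
#'
#' @param sol A `displacement_solution`.
#' @return Force in N.
#' @export
plate_reaction <- function(sol) {
  stopifnot(inherits(sol, "displacement_solution"))
  sol$plate_force
}

#' Rectangular calibration block phantom
#'
#' A fully occupied box of adipose-labeled voxels, used by the analytic
#' uniaxial-compression oracle (a homogeneous block between frictionless
#' plates is in a uniform stress state sigma_yy = -E x compression under
#' linear kinematics).
#'
#' @param lx,ly,lz Box edge lengths (mm).
#' @param voxel_mm Voxel pitch (mm).
#' @return A `breast_phantom` whose `cup` field is a synthetic box spec.
#' @export
block_phantom <- function(lx = 40, ly = 40, lz = 40, voxel_mm = 10) {
  d <- c(ceiling(lx / voxel_mm), ceiling(ly / voxel_mm),
         ceiling(lz / voxel_mm))
  cup <- structure(list(name = "block", extent_x = lx, extent_y = ly,
                        extent_z = lz, min_margin = 0), class = "cup_spec")
  structure(list(labels = array(1L, dim = d), voxel_mm = voxel_mm,
                 origin = c(-lx / 2, 0, 0), cup = cup),
            class = "breast_phantom")
}
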