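---
title: "Simulating mechanical imaging of the compressed breast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating mechanical imaging of the compressed breast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mechimg)
```

## The problem

Mechanical imaging (MI) measures the pressure distribution over the breast
surface during mammographic compression with a thin sensor sheet of roughly
1×1 cm elements. Stiff (typically malignant) lesions concentrate load and
leave a local pressure elevation; the clinical contrast statistic is the
RMPA — the mean of the 3×3 sensor tiles centered on the lesion tile divided
by the mean over all tiles fully covering the breast. `mechimg` simulates
the whole acquisition on procedural phantoms so that sensor geometry,
lesion placement and stiffness can be varied systematically — the kind of
exploration that is impossible to control clinically.

## Model and assumptions

**Geometry.** The breast at the start of compression is a half-ellipsoid
truncated by a planar chest wall: semi-axes (85, `extent_y`/2, `extent_z`)
mm in the inferior–superior (x), medial–lateral (y, the compression axis)
and chest–nipple (z) directions. Two presets stand in for bra cup sizes:
cup A (170×75×37 mm, 247 mL analytic volume) and cup B (170×100×50 mm,
445 mL). The interior is uniform adipose tissue; internal anatomy
(fibroglandular tissue, ligaments, skin) is deliberately absent, mirroring
the homogeneous-tissue assumption of compression modeling in virtual
clinical trial pipelines.

**Materials.** Isotropic linear elasticity with E = 12.75 kPa and ν = 0.49
for adipose tissue. A spherical lesion (default diameter 15 mm) is k times
stiffer, k ∈ {15, 30, 50}, with the same Poisson ratio. Units are mm and
kPa throughout, making nodal forces mN.

**Compression.** The breast is squeezed between a fixed support plane
(y = 0) and a rigid plate prescribed to travel until the gap is 50% of the
initial thickness. Contact with both planes is frictionless and unilateral;
chest-wall nodes are fixed in z; one plate-contact node is pinned in x and
z to remove rigid-body modes. Gravity and pre-loading are ignored.

**Outputs.** The compression-direction contact pressure binned on the
1×1 cm tile grid (anchored at the phantom bounding-box corner so tiles are
reproducible), the mean pressure over fully covered tiles ("surface
stress"), the mean pressure over the disc obtained by projecting the lesion
sphere onto the plate ("lesion-location stress"), the RMPA, and the total
plate reaction force.

## Discretization

Each occupied voxel is split into 6 tetrahedra around a globally consistent
cube diagonal (Kuhn subdivision). This mesher is deterministic,
dependency-free and volume-exact: the summed element volume equals the
occupied voxel volume to machine precision, and every tetrahedron inherits
its parent voxel's tissue label. The price is a staircase surface; at the
sensor's 10 mm tile pitch this is acceptable, and the sensor layer is built
to be robust to it (below).

Constant-strain tetrahedra lock volumetrically at ν = 0.49. The volumetric
energy is therefore evaluated on the mean dilatation of each parent voxel's
6-tet group (a Q1/P0-style mixed treatment) while the deviatoric part stays
element-wise. Uniform-strain fields are still reproduced exactly (the patch
test holds), the sparsity pattern stays at displacement-element cost, and
the measured plate force differs from the fully locking formulation by only
~2% at the default meshes — evidence that locking is not a dominant error
source here. A nodal-patch averaging variant was evaluated and rejected: it
couples second-ring neighbors and made the sparse factorization an order of
magnitude more expensive for no measurable accuracy gain at these meshes.

## Contact solve

Within each plate-travel increment an active-set iteration enforces the
unilateral conditions exactly: surface nodes that would penetrate a plane
get their y-displacement prescribed onto it, active nodes whose reaction
turns tensile are released, until the set is stable. The converged state
satisfies complementarity to solver precision (gap ≥ 0, compressive
reaction ≥ 0, gap·reaction = 0) and global equilibrium (plate force equals
support force to 10⁻⁶ relative). The sparse symmetric systems are solved by
CHOLMOD Cholesky factorizations; the entire pipeline is deterministic — no
random number is consumed anywhere.

## Kinematics: why the default is strictly linear

Two kinematic modes are implemented. `kinematics = "linear"` solves
small-strain elasticity on the reference geometry, with increments serving
only to grow the contact set. `kinematics = "updated"` is an incremental
updated-Lagrangian scheme: after each increment the node positions advance
and the stress state accumulates, so the strain measure approaches a
logarithmic one.

Measurement on the homogeneous cup A phantom settles the default. The
uniaxial anchor for these material parameters is E·ε = 6.375 kPa, and the
published clinical and simulated MI surface pressures sit at 6.2–6.5 kPa —
on the *linear* prediction. The updated mode accumulates |σ| → E·ln 2 ≈
8.8 kPa at the patch center (covered-tile mean ≈ 7.9–8.5 kPa, plate force
30 N for cup A), a ~30% overshoot of that scale, because a linear-elastic
constitutive applied incrementally on deformed geometry is effectively a
stiffening log-strain law in compression. The linear mode reproduces the
block oracle exactly and the surface-pressure scale within ~10%, and its
contact maps are smoother at desk resolutions; it is therefore the default,
with the updated mode retained for sensitivity studies. Consistently, the
sensor read-out for linear kinematics is taken in the reference
configuration (a nominal-stress map — mixing small-strain forces with
deformed areas would be kinematically inconsistent), while updated-mode
maps use deformed positions.

## Sensor construction

The tile map is assembled conservatively from the nodal contact reactions.
Raw per-node binning is exact in aggregate but aliases badly at desk
resolutions: a 10 mm tile covers 2.5 node spacings of a 4 mm lattice, so
tile readings would jump with the integer node count (±40%). Each nodal
force is instead spread over its physical contact footprint — a square one
node spacing wide — on a 1 mm raster, and tiles integrate that field. Total
force is conserved exactly (a package invariant tested to 1%; the
underlying accumulation is exact), individual terrace-edge nodes of the
staircase surface cannot spike the field, and the lesion-projection disc is
integrated on the same raster. "Fully covered" tiles are those whose entire
1 mm rasterization lies inside the contact footprint, taken as the union of
surface triangles whose nodes are all within half a voxel of the plate —
the tolerance closes the seams that staircase terraces leave in the
footprint. Positions exactly on a tile edge map to the lower-index tile, a
deterministic tie-break.

## Lesion-location registries

The default sweeps use fixed registries: 7 centers for cup A and 52 for
cup B, so the stiffness crossing gives the 21- and 156-case designs. The
published description constrains but does not enumerate the coordinates
(increments of 20 mm for cup A and 5 mm for cup B, minimum skin margins of
7.5 and 10 mm beyond the lesion surface, a fixed chest–nipple offset for
the thin cup A). Within those constraints the registry places, for cup A,
all centers 15 mm from the chest wall in two depth bands 20 mm apart
(y = 50 mm: x = −30, −10, 10, 30; y = 30 mm: x = −20, 0, 20); for cup B,
four bands at 5 mm x-increments: near-plate (y = 70, z = 20; 13 centers),
mid-breast 50 mm from the plate (y = 50, z = 20; 21 centers), the
near-plate line moved 5 mm toward the chest (y = 70, z = 15; 13), and a
short mid-thickness line (y = 50, z = 25; 5). Every center is verified
against the exact point-to-ellipsoid distance (margins ≥ 7.56 mm for cup A,
≥ 10.48 mm for cup B). Notably, a naive single line of 7 cup A centers at
x = −60…60 cannot satisfy the margin rule at all — the ±60 mm positions lie
within 3 mm of the skin — which is what forces the two-band arrangement.

## Problem sizes and runtime

All shipped tests and the result-reproduction script run the desk-scale
configuration: 4 mm voxels (cup A: ~23,000 tets, 15,000 DOF; cup B:
~42,000 tets, 25,000 DOF), 5 plate increments. Three ingredients keep the
sweeps cheap: the connectivity/assembly scaffolding is built once per cup
and shared across cases; the factorizations use supernodal Cholesky; and
because the linear contact solution is path-independent, each sweep case
warm-starts from the previous case's converged contact set and solves at
full travel in one increment (verified to agree with cold incremental
solves to 10⁻⁹). Both default sweeps together complete within minutes on
one CPU. A finer 2 mm preset exists for convergence studies; the
homogeneous-phantom surface pressure changes by under 5% between 4 and
3 mm.

## Known limitations

* **Geometric nonlinearity is out of scope**, and it matters at 50%
  compression. The linear default under-predicts the plate reaction force
  (cup A ≈ 17 N and cup B ≈ 23 N here, versus 22 N and 39 N for
  finite-strain reference solutions of the same configurations) because the
  true contact patch grows by lateral bulging that linear kinematics only
  represents to first order. The updated-Lagrangian mode recovers the cup B
  force (≈ 40 N) but overshoots the surface-pressure scale by ~30%;
  no small-strain configuration reproduces both at once.
* **Lesion contrast is resolution-limited.** The stress concentration above
  a stiff inclusion is real in the solution (σ_yy ≈ +58% over the far field
  above a shallow k = 50 lesion at 4 mm) but the surface read-out through a
  4 mm lattice and 1 cm tiles retains only part of it: lesion-location
  pressures come out around 7.4–7.9 kPa for cup A against published
  finite-strain values of 10–11.4 kPa, and the maximum RMPA is ≈ 1.19
  versus ≈ 1.46. Finite-strain cover-layer thinning over the stiff
  inclusion — absent under linear kinematics — is the main missing
  amplifier.
* The phantom is homogeneous adipose tissue by design; clinical pressure
  maps show far larger spatial variance than these simulations, and skin,
  ligaments and glandular tissue would be needed to emulate it.
* Hyperelastic constitutive laws, friction, gravity pre-loading and plate
  compliance are not modeled.

## Degenerate inputs and tie-breaks

Zero-diameter lesions are no-ops; placement violating the margin rule (or
outside the outline) raises a classed placement error naming the offending
distance; meshes with no occupied voxel, zero-volume elements, and contact
loss are classed errors rather than silent results. Sensor tiles use the
lower-index tie-break on edges; the pin node is the plate-contact candidate
nearest the (0, plate, mid-z) axis with the lowest node index on ties.
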