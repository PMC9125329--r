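# mechimg — finite-element simulation of breast mechanical imaging

Mechanical imaging (MI) records the pressure distribution over the breast
surface with a thin sensor sheet mounted on the compression plate during
mammography. Because malignant lesions are considerably stiffer than adipose
tissue, a stiff inclusion leaves a localized pressure elevation on the
surface map, quantified clinically by the **RMPA** (relative mean pressure
over lesion area): the mean pressure of the 3×3 sensor tiles (1×1 cm each)
centered over the lesion, divided by the mean over all tiles fully covering
the breast.

`mechimg` is a desk-scale simulator of MI acquisition for virtual clinical
trial work. It provides the whole pipeline in R:

1. **Phantom** — procedural half-ellipsoid breast outlines on a voxel grid
   (cup A ≈ 250 mL, 170×75×37 mm; cup B ≈ 450 mL, 170×100×50 mm) with
   spherical stiff lesions (default 15 mm diameter) placed under an exact
   skin-margin rule.
2. **Mesher** — structured Kuhn 6-tetrahedra subdivision of each occupied
   voxel; volume-exact, deterministic, label-preserving.
3. **FE solver** — sparse linear-elastic tetrahedral elasticity
   (E = 12.75 kPa, ν = 0.49 for adipose tissue; lesion k ∈ {15, 30, 50}
   times stiffer), frictionless rigid-plate contact by an active-set method,
   compression to 50% of the initial thickness. Volumetric locking at
   ν = 0.49 is relieved by a cell-mean dilatation (Q1/P0-style) formulation.
4. **Sensor** — 1×1 cm tile pressure map assembled conservatively from the
   contact reactions, coverage flags, RMPA, and the mean pressure over the
   lesion's projection disc.
5. **Study** — the default sweeps (cup A: 7 locations × 3 stiffness ratios
   = 21 cases; cup B: 52 locations × 3 = 156), Table-style summaries
   (mean ± sd, range), and an exact Wilcoxon signed-rank test comparing
   lesion-location versus surface pressure.

The model at its core: quasi-static equilibrium `div σ = 0` with
`σ = λ tr(ε) I + 2 μ ε`, unilateral frictionless contact
(`gap ≥ 0`, `p ≥ 0`, `gap · p = 0`) against the two rigid plates, chest-wall
nodes fixed along the chest–nipple axis. A homogeneous block between
frictionless plates then carries the uniform uniaxial stress
`|σ_yy| = E · ε = 12.75 × 0.5 = 6.375 kPa`, which anchors the ~6.2–6.5 kPa
surface pressures the pipeline reports.

## Worked example

```r
library(mechimg)

# cup A phantom with a stiff lesion, desk-scale resolution
cup <- cup_spec("A")
ph  <- build_outline(cup, voxel_mm = 4)
ph  <- insert_lesion(ph, lesion_spec(c(-10, 50, 15), diameter = 15,
                                     stiffness_ratio = 50))
mesh <- classify_boundaries(voxels_to_tets(ph))
mesh$origin <- ph$origin

sol <- solve_compression(mesh, material_table(50),
                         compression_case(0.5, n_increments = 5,
                                          kinematics = "linear",
                                          thickness0 = cup$extent_y))
map <- pressure_map(sol, mesh)

sensor_mean(map)                           # 6.608 kPa mean covered-tile pressure
plate_reaction(sol)                        # 17.54 N compression force
lesion_surface_stress(map, c(-10, 50, 15)) # 8.745 kPa over the lesion disc
rmpa(map, c(-10, 50, 15))$rmpa             # 1.177
```

The lesion's projection reads ~32% above the background here; a homogeneous
phantom reads RMPA ≈ 1. Deeper lesions and smaller stiffness ratios give
smaller contrasts, reproduced case by case in the sweep:

```r
res <- run_sweep(sweep_config("A", voxel_mm = 4, n_increments = 5))
format_stress_table(summarize_sweep(res))
#>   lesion_stiffness surface_kpa lesion_kpa p_value
#>                15   6.40±0.08  7.43±0.61   0.016
#>                30   6.46±0.09  7.72±0.76   0.016
#>                50   6.50±0.10  7.87±0.84   0.016
```

Surface pressure is nearly independent of the lesion (sd ≤ 0.1 kPa across
locations) while the lesion-location pressure rises with stiffness, and the
paired exact Wilcoxon test shows the elevation is systematic (all seven
locations elevated: p = 2/2⁷ = 0.016).

A thin CLI covering the same pipeline ships in `inst/scripts/mi`
(`mi phantom`, `mi solve`, `mi sweep --config sweep.yaml`, `mi report`).

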