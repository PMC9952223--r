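# callusim

Simulation of the **initial fracture-callus growth** phase of long-bone
healing on a *growing* voxel mesh — no pre-meshed callus domain.

After a diaphyseal fracture is stabilized with an intramedullary nail, the
primary callus forms where migrating cells accumulate at the fracture
edges. `callusim` models this with three coupled pieces, iterated with a
shared time step Δt:

1. **Cell diffusion.** Mesenchymal stem cell (MSC) and chondrocyte
   concentrations obey Fick's second law, ∂c/∂t = D Δc, with
   region-constant diffusivities (nail 0, cortical 1, marrow/periosteum
   100, callus 50 µm²/min). The solver uses trilinear hexahedral finite
   elements (one per 1 mm voxel), a consistent mass matrix and implicit
   (backward-Euler) stepping: `(M/Δt + N) c⁺ = f + (M/Δt) c`.
2. **Growth triggering.** An element face bordering empty space may grow
   once the dimensionless concentrations α = c_MSC/c_MSC^max and
   β = c_cho/c_cho^max at its nodes exceed thresholds (α₀, β₀ = 1/32,
   1/16). Its volumetric growth velocity is the normalized sigmoid law

       v = v_max · φ(α, β),   φ(α, β) = 4A / ([1+e^{-a(α-α₀)}][1+e^{-b(β-β₀)}]) + B,

   with A, B fixed by φ(α₀, β₀) = 0 and φ(1, 1) = 1 exactly
   (v_max = 5 mm³/day, a = b = 5 by default).
3. **Free mesh growth.** A face that has accrued one voxel volume spawns a
   new callus element at the neighbouring lattice site: the new centroid is
   placed at distance L, path vectors locate the 8 corners, existing nodes
   are reused and missing ones created — the mesh stays watertight with no
   duplicated nodes, and occupied sites are never overwritten.

Per-day records track callus volume, **bridging** (a 6-connected path of
non-nail tissue joining the main fragments) and **closure** (every
cutter-removed site refilled — the gap "filled seamlessly"), plus the count
of sealed interior voids.

Three presets reproduce classic nailed femoral-shaft scenarios on a 43 mm
idealized section (11 mm nail, 1 mm voxels): `transverse` (6 mm gap),
`oblique` (30°, 3 mm gap) and `comminuted` (transverse + oblique cuts with
an inert intermediate fragment). See the methods vignette
(`vignettes/callus-growth-model.Rmd`) for the model's assumptions,
calibration and limitations.

## Worked example

A miniature, fully traceable instance: two 3×3×3 trabecular blocks with a
2-voxel gap, cells entering from the outer end cross-sections.

```r
library(callusim)

toy <- toy_two_block_model()
cfg <- simulation_config(time = list(horizon = 60),
                         model = toy$model,
                         boundary_nodes = toy$nodes,
                         boundary_values = toy$values)
res <- run_simulation(cfg)
print(res)
#> <callus_sim> 9 days simulated, 18 callus elements (18 mm^3)
#>   bridging day: 9, closure day: 9
```

Cells need ~8 days to diffuse through the 3 mm blocks and lift the fracture
faces over the trigger thresholds; the 18-voxel gap then fills from both
sides within a day, so bridging and closure coincide on day 9. The per-day
table (`res$days`) shows the same story: `unfilled` stays at 18 until day
8, then drops to 0 as 18 mm³ of callus is added.

A full scenario runs in a few minutes:

```r
res <- run_simulation(preset_config("transverse"))
res$events
#> $bridging_day
#> [1] 16
#> $closure_day
#> [1] 36
```

with the callus collar overtopping the periosteum and endosteal callus
surrounding the nail at bridging (`res$days[res$days$day == 16, ]`).

Models and fields export to legacy-ASCII VTK for visualization
(`export_vtk()`), labeled segmentations import via
`import_labeled_volume()` (array or NIfTI), and a thin command-line
wrapper lives at `system.file("cli", "callus-sim", package = "callusim")`:

```sh
Rscript inst/cli/callus-sim run --preset transverse --out out/
```

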