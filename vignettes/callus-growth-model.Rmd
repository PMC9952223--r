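---
title: "Modeling initial fracture-callus growth on a free voxel mesh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling initial fracture-callus growth on a free voxel mesh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(callusim)
```

## The model

`callusim` simulates the first stage of long-bone fracture healing: the
formation of the primary (soft) callus that bridges and then fills the
interfragmentary gap, before mineralization and remodelling begin. The
model couples three ingredients on a lattice of cubic voxels:

1. **Cell migration as diffusion.** The local concentrations of the two
   cell species that drive early callus formation — mesenchymal stem cells
   (MSCs) and chondrocytes — each obey Fick's second law,
   $\partial c/\partial t = D\,\Delta c$, with a piecewise-constant
   diffusion coefficient per tissue: zero in the intramedullary nail, very
   low in cortical bone (1 µm²/min), high in the marrow/trabecular space
   and the periosteum (100 µm²/min), and intermediate in newly formed
   callus (50 µm²/min). The equations are discretized with trilinear
   8-node hexahedral elements (one per voxel), a consistent mass matrix,
   and backward-Euler time stepping
   $(M/\Delta t + N)\,c_{t+\Delta t} = f + (M/\Delta t)\,c_t$,
   which is unconditionally stable. Concentrations are used
   dimensionlessly: $\alpha = c_\mathrm{MSC}/c_\mathrm{MSC}^{\max}$,
   $\beta = c_\mathrm{cho}/c_\mathrm{cho}^{\max}$, with the reference
   maxima fixed at 1.

2. **A sigmoid growth-trigger law.** An element face that borders empty
   space ("free face", detected by looking up the six neighbouring
   centroids in an occupancy index) may grow only when both dimensionless
   concentrations at its nodes exceed trigger thresholds
   $(\alpha_0, \beta_0)$. Above threshold, the face accrues volume at
   $$v \;=\; v_{\max}\,\varphi(\alpha, \beta), \qquad
     \varphi(\alpha,\beta) \;=\;
     \frac{4A}{\left[1+e^{-a(\alpha-\alpha_0)}\right]
               \left[1+e^{-b(\beta-\beta_0)}\right]} + B,$$
   a normalized sigmoid surface on $[\alpha_0,1]\times[\beta_0,1]$. The
   slopes $a$ and $b$ summarize the influence of the signalling molecules
   (TNF-α, BMP-2) that modulate healing rate. The normalization constants
   are chosen so that $\varphi(\alpha_0,\beta_0)=0$ and $\varphi(1,1)=1$
   hold exactly: with
   $k = 1/\big(\,[1+e^{-a(1-\alpha_0)}][1+e^{-b(1-\beta_0)}]\,\big)$ this
   gives $A = 1/(4k-1)$ and $B=-A$; the corner conditions are imposed
   exactly rather than through any intermediate closed form.

3. **Free mesh growth.** The callus mesh is not pre-meshed. When a face
   has accrued one element volume ($L^3$, with $L = 1$ mm voxels), a new
   centroid is placed at distance $L$ in the free direction and the
   centroid-to-corner path vectors locate the eight corner positions;
   existing nodes there are reused and missing ones created, so no node is
   ever duplicated and the growing mesh stays watertight. Occupied target
   sites are rejected, which also prevents growth into the opposite
   fragment.

Each iteration of the simulation runs the three phases in order —
diffusion advance, trigger evaluation with volume accrual, element
addition — with a single shared time step (default $\Delta t = 0.25$ day).

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `v_max` | 5 | mm³/day | maximum volumetric face growth rate |
| `a`, `b` | 5, 5 | — | sigmoid slopes (chemical modulation) |
| `alpha0`, `beta0` | 1/32, 1/16 | — | trigger thresholds |
| `D` (nail/cortical/marrow/periosteum/callus) | 0/1/100/100/50 | µm²/min | diffusivities, converted internally to mm²/day (×1440·10⁻⁶) |
| `dt` | 0.25 | day | shared iteration step |
| `c_high`, `c_low` | 1.0, 0.3 | — | prescribed dimensionless concentrations |
| `scale` | 0.16 | — | calibration scale on the prescribed values |
| `roi_halfwidth` | 5 | mm | axial half-width of the growth band around the gap |

## Boundary conditions and their calibration

Healing chronologies for nailed femoral-shaft fractures constrain this
model family only loosely: numeric boundary concentrations are essentially
never reported, and subject-specific geometry (canal diameter, cortical
thickness) varies. Both gaps have to be filled by explicit modelling
decisions, and they are the two places where `callusim` is calibrated
rather than predictive:

* **Where cells come from.** The well-perfused compartments — the
  marrow/trabecular space and the periosteal shell — act as a cell
  reservoir: every node incident to those regions is held at the high
  prescribed concentration (essential condition). Cortical bone is
  prescribed only on the section's two end cross-sections (at `c_low`) and
  diffuses freely elsewhere; all remaining surfaces are natural zero-flux
  boundaries, so no cells leave the bone through the outer surface.
  Prescribing the *end cross-sections only* for all materials (available
  as `boundary$mode = "ends"`) cannot reproduce the observed healing time
  scale: with $D \le 0.144$ mm²/day the diffusion length over a 36-day
  simulation is $\sqrt{4Dt} \approx 4.6$ mm, so sources ~18 mm from the
  fracture could never lift the gap above threshold within weeks. Keeping
  the cortical *volume* free (rather than prescribing it low everywhere)
  matters for a subtler reason: a prescribed sub-threshold cortical
  surface would permanently veto any prospective face that shares nodes
  with it, and the staircase surface of an oblique cut would then retain
  unfillable notches.

* **An idealized diaphysis.** The bone is a concentric-cylinder stand-in:
  outer radius 15 mm, a one-voxel periosteal shell, an 11 mm nail in the
  medullary canal, and free growth space around the bone. The canal
  diameter and cortical thickness of the original femur section are not
  reported; they control how much of the fracture surface sits next to
  the marrow reservoir, and thereby the lag between first bridging and
  complete filling. The two free constants of the stand-in — the boundary
  calibration `scale` and the cortical thickness (5.25 mm by default,
  canal ≈ 19.5 mm) — were fixed *once* against the transverse scenario's
  two reported events (bridging onset near day 18, closure near day 36)
  and are left untouched for every other scenario, which makes the
  oblique and comminuted chronologies out-of-sample predictions.

## Numerical choices

* **Face triggering uses the minimum over the four face nodes** (a face
  grows only when cells have reached its entire front), and **new nodes
  start at zero concentration** (a fresh voxel of granulation tissue
  contains no migrated cells yet). The alternatives — face means and
  parent-face-mean initialization, both available via
  `growth$aggregate = "mean"` and `growth$new_node_init = "parent_mean"` —
  let a face qualify through the already-charged nodes it inherits, so the
  growth front outruns diffusion and a 6 mm gap closes in roughly two
  days, an order of magnitude faster than observed healing; the defaults
  keep the front diffusion-limited, which is the regime the day-scale
  chronology lives in.
* **Growth is restricted to an axial band** (`roi_halfwidth` beyond the
  removed region) so the remote periosteal surface, which sits at the
  reservoir concentration, does not sprout callus far from the fracture.
* **Volume accrual** maps the volumetric velocity to discrete 1 mm³
  additions; faces keep sub-element remainders, and accrued volume
  persists if a face's concentration temporarily drops below threshold.
  Simultaneous requests for one site are merged (lowest parent id and
  direction win; the attributes are identical either way).
* **Dirichlet conditions are enforced by exact elimination** with
  right-hand-side correction; the constrained operator is factorized with
  a sparse Cholesky decomposition and reused while the mesh is unchanged.
  Only elements owning at least one unconstrained node are assembled,
  which keeps the per-step cost proportional to the callus size under
  reservoir boundary conditions.
* **The consistent mass matrix** admits small transient maximum-principle
  violations at low Fourier numbers (≲2·10⁻² on a coarse bar); they stay
  bounded, decay, and do not affect the day-scale chronology. Mass
  lumping would remove them but change the discretization.
* **Closure bookkeeping.** The gap is *bridged* when a 6-connected path of
  non-nail elements joins the two main fragments (an inert comminuted
  fragment may serve as part of the bridge), and *closed* when every site
  removed by the fracture cutter is occupied again. The per-day
  interior-void count reports empty band sites that are no longer
  6-connected to the outside air — the sealed cavities that remain inside
  the callus shortly before closure. (Defining closure as
  "bridged with zero sealed voids" alone would fire the moment a single
  callus strand connects the fragments while the gap mouth is still open,
  which contradicts the intended "filled seamlessly" reading.)

## What the scenarios do and do not show

The three shipped presets (transverse 6 mm; oblique 30°/3 mm; comminuted =
transverse + oblique cuts with an inert intermediate fragment) run on
~27 000–44 000 elements for 25–50 simulated days at $\Delta t=0.25$ day,
a few minutes each on one CPU. With the single transverse calibration:

* the transverse scenario bridges in the mid-teens of days and closes in
  the mid-thirties, with the callus collar overtopping the periosteum and
  endosteal callus surrounding the nail at bridging — the expected
  qualitative morphology;
* the comminuted scenario closes last, in the high forties, because the
  inert fragment contributes no cells and each of its two gaps must fill
  from one active side;
* the oblique scenario, however, closes *earlier* than the transverse one
  (mid-twenties). Under any diffusion-limited refill of an idealized
  cylinder, supply distances scale with the normal gap width, and a 3 mm
  oblique slab simply refills faster than a 6 mm transverse slab. A
  reference chronology in which the oblique case heals slowest per
  millimetre of gap must reflect features of the underlying subject
  geometry (or of its boundary values) that an idealized cylinder does
  not possess. We report the model's honest prediction rather than
  re-tuning the shared calibration against the oblique case.

The synthetic geometry reproduces the topology of a nailed diaphyseal
fracture (annular cross-section, reservoir compartments, fracture gap,
free growth space) but none of the anatomy of a real femur: no curvature,
no cortical thickness variation, no marrow inhomogeneity, no mechanics.
Passing scenario tests therefore demonstrate internal consistency of the
three-phase algorithm and a chronology compatible with the reported
transverse case — not patient-level predictive validity.

## Known limitations

* Tissue differentiation, mineralization, remodelling and mechanical
  stimuli are outside the model: it stops at the primary callus.
* Growth proceeds only in the six axial directions on the lattice; callus
  surfaces are voxelated and no surface smoothing is attempted.
* Both species share diffusivities and boundary levels by default; the
  chemical factors enter only through the slopes $a$ and $b$.
* The day counts of all scenarios inherit the transverse calibration; they
  are not parameter-free predictions.
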