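---
title: "Methods: masticatory loading and cranial bone strain at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: masticatory loading and cranial bone strain at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`craniostrain` implements, end to end and at desk scale, the workflow
used to characterise how different bites load a mammalian cranium:

1. **Geometry** — a parametric, mirror-symmetric "cranium phantom": a
   labelled tetrahedral mesh with separate volumes for bone, teeth,
   pulp, periodontal ligament (PDL) and cranial sutures, a fenestrated
   lateral wall on each side, and named landmark nodes (TMJ contact
   points, tooth tips, muscle strand origins).
2. **Musculoskeletal simulation** — a rigid mandible driven through
   prescribed incisor and molar bite cycles by 130 muscle strands (65
   per side), whose activations are found per time step by a convex
   quadratic program weighted by EMG-style activity profiles.
3. **Finite elements** — one multi-material linear-elastic static solve
   per bite loading regime, with nodal muscle loads at the strand
   origins, truss ("link") chains for wrapped muscles, and six scalar
   contact constraints at the bite point and the two TMJs.
4. **Aggregation** — cumulative peak element strains across all bites,
   dominance maps (which bite mode, which principal strain), 20-µε
   histograms, mechanostat band volume fractions, and a soft-tissue
   sensitivity comparison.

Units are fixed throughout: mm, N, MPa; strains are reported in
microstrain (µε). All stages are deterministic; any randomized test
fixtures take explicit seeds.

# The cranium phantom

No real cranial geometry ships with the package. The phantom is a
deliberately simple stand-in whose job is to exercise every material
type, thin-structure meshing, the fenestration concept and left/right
symmetry — not anatomical realism. It is a hollow box shell
(default 64 × 24 × 16 mm, 2 mm walls) with:

* **tooth pegs** (1 incisor + 5 cheek teeth per side by default)
  passing through the ventral wall, each with a pulp core and a PDL
  layer lining its socket, so that every element path from a tooth into
  bone crosses the PDL;
* **fenestrated lateral walls**: a window divided into rectangular
  openings separated by bone struts (4 openings of default width with
  2 mm struts per side); setting `n_fenestrations = 0` gives the solid
  wall used for volume comparisons;
* **suture seams** crossing the roof (a coronal seam and a mid-sagittal
  seam by default), the full thickness of the roof shell;
* **landmarks**: TMJ contact points on the posterior inner wall corners,
  one node per tooth tip, and one node per muscle strand origin.

## Meshing choices

The phantom is built on a structured voxel grid with a single element
size (1 mm by default). Each cell is split into five tetrahedra; the
split has two mirror chiralities which are alternated in a 3D
checkerboard. This keeps shared faces conforming *and* makes the
connectivity exactly mirror-symmetric about the mid-sagittal plane
(with an even cell count across the width, the mirror image of an
even-parity cell is an odd-parity cell). Exact connectivity symmetry is
what lets the package assert per-element equality of mirrored strain
fields rather than merely statistical similarity.

Because the grid has one global element size, the per-material mesh
densities of a real segmentation-based mesh have no analogue here; the
through-thickness rule is enforced instead: PDL, suture and shell
thicknesses must be at least two element sizes, so thin structures
always carry at least two elements through their thickness. Quadratic
(10-node) tetrahedra are generated from the linear mesh by edge-midpoint
insertion; midside nodes are not snapped to curved geometry because the
phantom is piecewise planar.

# The jaw model and bite cycles

The mandible is a single rigid body whose frame coincides with the
cranium frame at occlusion. A pose is a sagittal gape rotation about the
mediolateral axis through the two TMJ pivots followed by a frontal
excursion rotation toward the working side. Each bite cycle has three
phases: opening to the maximal gape (12° in the mid-sagittal plane),
fast closing to food-bolus contact (molar cycles simultaneously rotate
5.5° to the working side in the frontal plane), and slow closing during
which the bolus is processed and the jaw returns to the midline. The
bolus resists vertically with a force that ramps linearly with
compression up to `R_v` = 30 N (fully compressed at the end of slow
close), and — for molar cycles — with a constant mediolateral resistance
`R_ml` = 30 N opposing the return to the midline. Incisor cycles are
mirror-symmetric: no excursion, no mediolateral resistance.

Default phase durations (0.12 s opening, 0.08 s fast close, 0.15 s slow
close, 5 ms steps) are in the range reported for mammalian reduction
chewing; the bolus-contact gape (2°) sets where slow close begins.

## Muscle strands

The 65 strands per side are grouped into masseter (20 strands, 90 N
total maximum isometric force per side), zygomaticomandibularis (10,
40 N), superficial temporalis (15, 30 N — wrapped over the posterior
roof edge via via-points), deep temporalis (10, 15 N), medial pterygoid
(7, 30 N) and lateral pterygoid (3, 8 N — wrapped around a ventral
via-point). The masseter-dominant proportions follow the leporid
masticatory apparatus. The absolute magnitudes are the package's own
choice: they give every default and reduced phantom comfortable
activation headroom at 30 N bites at every bite point. Origins (and via
points) lie on phantom surface grid nodes so the same layout defines
both the rigid-body model and the FE landmarks.

Strand paths are piecewise straight through their via points (no
curved-surface wrapping — a stated non-goal). Lines of action are
re-evaluated at every pose, so activations account for instantaneous
strand orientations.

## Passive tension

Each strand carries a small passive tension resisting elongation beyond
its slack length `L0` (set to the closed-pose length):

$$T_p(L) = p_\mathrm{cap} F_\mathrm{max}
  \frac{e^{k s} - 1}{e^{k s_\mathrm{max}} - 1}, \qquad
  s = \max(0, (L - L_0)/L_0),$$

clipped at the cap. Defaults: `p_cap` = 0.001 (0.1 % of
`F_max`), shape `k` = 3, cap strain `s_max` = 0.05. The exponential
shape and the 0.1 % cap are fixed by the model description; `k` and
`s_max` are free parameters exposed in the strand configuration.

## Activation solve

At each time step the required generalized load is the negative of the
external bolus wrench about the TMJ midpoint (quasi-static by default —
chewing is slow, and only the maximum-bite-force snapshot feeds the FE
stage; optional inertia terms from finite differences of the prescribed
motion are available and agree with the quasi-static solution within 1 %
on slow cycles). Activations $a_i \in [0,1]$ solve

$$\min \sum_i (a_i / w_i)^2 \quad \text{s.t.} \quad
  \sum_i a_i F_{\mathrm{max},i}\, g_i = b,$$

where $g_i$ is strand $i$'s unit-force moment contribution on the free
axes (the sagittal hinge axis; plus the frontal axis for molar bites)
and $w_i$ are EMG-style weights (working side 1.0, balancing side 0.6
during molar slow close; equal for the symmetric incisor task; floor
0.05). The weighted least-squares objective makes strand pairs with
equal geometry and weights share load equally, and mirrored strand pairs
receive identical activations in symmetric tasks — both verified against
a brute-force grid search on small instances.

When the external load is zero (opening and fast close in quasi-static
mode) the muscles are inactive and the capped passive tensions are
carried by the joint; when external load is present the equality
includes the passive contributions, so the rigid-body force balance at
the bite-force maximum closes to machine precision. Passive tension is
everywhere at most 0.1 % of `F_max` and essentially zero near occlusion,
so it does not materially affect activations or bite forces.

Infeasible demands (beyond total muscle capacity) raise an explicit
error naming the unreachable load component.

## Loading regimes

Each cycle is snapshotted at the instant of maximum bite force (earliest
instant on ties; for molar cycles this is the last instant at which the
mediolateral resistance still acts, giving a bite force of
$\sqrt{R_v^2 + R_{ml}^2} \approx 42\,\mathrm{N} \ge 30\,\mathrm{N}$;
for incisor cycles the vertical ramp peaks at exactly 30 N at full
compression). The snapshot records per-strand forces
$a_i F_{\mathrm{max},i} + T_{p,i}$ along the instantaneous lines of
action, wrapping paths, the bite contact point and the TMJ reactions
(distributed to the two TMJ points minimum-norm along the statically
indeterminate intercondylar axis). Right-side regimes are reflected
across the mid-sagittal plane to produce the left-side set: one incisor
and five molar bites per side, 12 regimes in total with the default
dentition.

# Finite-element stage

Elements are 4-node (constant-strain) or 10-node (quadratic)
tetrahedra; assembly is exact quadrature (1 and 4 points respectively)
of isotropic linear elasticity. Material defaults: bone E = 13 700 MPa,
ν = 0.3; tooth (dentine and enamel merged) 19 890 MPa / 0.31; PDL
50 MPa / 0.49; suture 20 MPa / 0.49; pulp 2 MPa / 0.49; link elements
carry the bone values so wrapped-muscle chains transfer force with
minimal deformation.

Wrapped muscles become chains of axial-only truss elements over the
bone surface: path joints that coincide with mesh nodes are chained
through those nodes; genuinely off-surface joints become new nodes with
a short anchor truss to the nearest surface node plus two further
stabilizing anchors (a truss joint with fewer than three independent
axial directions is a mechanism in statics).

Each regime applies every strand force as a nodal load at its origin
landmark and imposes exactly six scalar displacement constraints —
molar: bite node dorsoventral; working TMJ dorsoventral +
anteroposterior; balancing TMJ all three. Incisor: bite node
dorsoventral; working TMJ all three; balancing TMJ dorsoventral +
anteroposterior. (Axes: mediolateral = x, anteroposterior = y,
dorsoventral = z.) This statically determinate scheme suppresses rigid
motion while letting the cranium deform laterally.

The linear solve is sparse Cholesky by default with a
Jacobi-preconditioned conjugate-gradient alternative (relative
tolerance 1e-10); a residual check reports under-constrained systems
explicitly. Per-element strain tensors are recovered at the centroid
(linear) or as the quadrature average (quadratic); principal strains
come from a closed-form symmetric eigen-solve (verified against an
eigendecomposition oracle), and the equivalent strain uses the
effective-Poisson's-ratio von Mises form

$$\varepsilon_{vM} = \frac{1}{1+\nu_\mathrm{eff}}
 \sqrt{\tfrac12\left[(\varepsilon_1-\varepsilon_2)^2 +
 (\varepsilon_2-\varepsilon_3)^2 +
 (\varepsilon_3-\varepsilon_1)^2\right]},$$

with $\nu_\mathrm{eff}$ the element's material ratio by default
(configurable constant alternative) — the convention of commercial
solvers, which recovers the axial strain in uniaxial stress and
vanishes for hydrostatic strain. Stored strains are never clipped;
plotting saturation is a display concern only.

# Aggregation and statistics

The cumulative peak table keeps, per bone element, the largest
equivalent strain from any regime, the regime that produced it (lowest
regime index on ties), the largest tensile principal strain and the
most negative compressive principal strain, with element volumes.
Teeth, sutures, PDL and pulp are included in every solve but excluded
from the reported statistics, which concern the bone volume.

* **Bite-mode dominance** classifies each element by the mode of its
  argmax regime; fractions are element-volume-weighted (an
  element-count variant is also emitted, since "volume" reporting can
  mean either).
* **Principal dominance** is compressive iff |peak ε₃| > peak ε₁,
  tensile otherwise — ties classify as tensile (documented tie rule).
* **Histograms** count elements in half-open 20 µε bins.
* **Band fraction** is the volume fraction with peak strain strictly
  between 100 and 1500 µε, the range associated with normal bone
  remodelling (mechanostat homeostasis); the strict bounds follow the
  above/below wording of that range.
* **Sensitivity** compares peak tables between a base run and a variant
  with PDL and suture stiffness lowered (×0.1 by default) and reports
  the median |Δpeak| among bone elements near the soft tissues
  (centroid distance ≤ 3 mm by default) versus far from them. On the
  phantom the near-field median exceeds the far-field median: the
  effect of soft-tissue stiffness is local, not structure-wide.

All aggregation operations are checked against straightforward
nested-loop reference implementations, and satisfy idempotence
(aggregating a peak table with itself), monotonicity (adding a regime
never lowers a peak) and partition (fractions sum to 1).

# Problem sizes and determinism

The default phantom meshes to about 45 000 linear tetrahedra (~14 000
nodes); a bite-cycle simulation takes on the order of a second and an
FE solve a few seconds on one CPU. The test suite exercises the full
structure on a reduced phantom (40 × 24 × 10 mm, one cheek tooth per
side, ~26 000 elements) and runs the complete 12-regime pipeline on an
intermediate phantom (56 × 24 × 10 mm); these sizes keep the whole
suite to a few minutes while preserving every geometric and material
feature. The pipeline is deterministic end to end: re-running a
configuration reproduces bit-identical summaries; the seed recorded in
the configuration exists for randomized fixtures derived from the
phantom, not for the pipeline itself.

# What the phantom does and does not show

Passing tests demonstrate that the machinery is correct: equilibrium,
patch-exactness, beam convergence, interface behaviour, symmetry, and
oracle-equal statistics. They do not validate anatomical strain
distributions: the phantom's strain pattern depends on its box-like
geometry, so the published percentage splits for a real cranium
(which depend on a segmented 41-million-element mesh and measured
muscle forces) are not reproduction targets here — the procedures that
compute such percentages are, and those are what the tests pin down.
Known limitations, by design: no curved-surface muscle wrapping, no
Hill-type force–length–velocity muscle dynamics, no TMJ contact
mechanics beyond point constraints, no CT-density-mapped heterogeneous
bone stiffness, and no adaptive remodelling.

# A minimal run

```{r, eval = FALSE}
library(craniostrain)

cfg <- run_config(
  phantom = list(length = 56, height = 10, crown_height = 3),
  bite = list(dt = 0.01),
  out_dir = "run1")
run <- run_pipeline(cfg)
print(run)
plot(run)            # 20-microstrain peak-strain histogram
summary(run)         # fractions, band statistics, sensitivity medians
```
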