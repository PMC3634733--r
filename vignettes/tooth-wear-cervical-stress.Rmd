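---
title: "Occlusal wear and cervical tensile stress: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occlusal wear and cervical tensile stress: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(toothfem)
```

## The scientific question

Non-carious cervical lesions (NCCLs) are wedge-shaped losses of enamel and
dentine at the buccal cervical margin of a tooth. The abfraction hypothesis
attributes them to cyclic tensile stress: when occlusal contact happens on the
steep slopes of an unworn cusp, the contact force — which acts perpendicular
to the wear facet — carries a large non-axial component, the crown is bent,
and tension concentrates where the enamel thins out at the cervix. Occlusal
wear flattens the cusps, re-aligns the load with the tooth long axis, spreads
it over larger contact areas, and should therefore *relieve* cervical
tension. `toothfem` implements a complete in-silico version of that
experiment: a parametric multi-tissue lower second premolar is generated at
several wear stages, loaded through facet-perpendicular occlusal contacts
normalized to a 100 N resultant, solved as a linear elastic problem on
10-node tetrahedra, and compared across wear states at ten homologous
buccal-cervical nodes.

## Coordinate convention and units

x runs lingual → buccal, y runs inferior → superior along the tooth long
axis, z runs mesial → distal; the origin is the centroid of the cervix
(enamel-cementum junction ring). Lengths are mm, forces N, moduli are entered
in GPa and converted to MPa internally, so stresses come out in MPa.

## The synthetic premolar

No tomographic specimen data accompany this package, so the geometry module
is a first-class synthetic generator (`tooth_params()`, `generate_tooth()`).
The implicit solid has five tissues:

* a **crown** built from two cusp cones (buccal taller than lingual) over a
  fossa floor, clipped to a cylindrical footprint of `cervix_radius`;
* an **enamel** cap of `enamel_thickness` over the occlusal relief, with
  lateral walls 0.75 of that thickness, terminating at the cervix plane;
* a **dentine** body continuing into a tapered root, with a **pulp** chamber
  and canal;
* a **periodontal ligament** (PDL) shell around the root;
* an **alveolar bone** block whose planar z-faces are the mesial and distal
  cut surfaces used for boundary constraints; its top sits 1 mm below the
  cervix (an alveolar-crest standoff).

Two geometric choices matter mechanically and deserve explanation:

* **Cusp position.** The cusp tips sit at only `0.2 * cervix_radius` from
  the tooth axis. Lower premolar crowns are lingually inclined, with the
  buccal (functional) cusp tip riding nearly over the root axis and a broad
  buccal slope facing outward below it. This is not cosmetic: the bending
  moment a contact force exerts about the cervix is
  `M = x * Fy - y * Fx`, and placing the cusp far buccally makes the
  eccentric axial term cancel the lateral term, killing the very effect the
  model must express. With the near-axial cusp, an oblique facet load on the
  outer slope produces a distinctly lingual-directed tilt and buccal
  cervical tension.
* **Wear operator.** `apply_wear()` truncates the crown with a horizontal
  plane `wear_depth` below the unworn buccal cusp tip — the computational
  analog of grinding antagonist casts against each other in an articulator
  until the cusp tip is oblate. Smith's ordinal wear stages map onto depth
  bands relative to the enamel cap: stage 1 up to 25 % of the cap, stage 2 up
  to the enamel-dentine junction, stage 3 beyond it (dentine exposed). The
  representative depths used for stage runs are 0.2, 0.75 and 1.4 cap
  thicknesses. The voxel grid spans the *unworn* bounding box for every wear
  state, so all states of one tooth share their node lattice below the
  truncation plane — that is what makes cervical sampling homologous across
  states.

### Meshing

The mesher is a structured voxel-to-tetrahedron subdivision: each grid cell
is split into six positively-oriented tetrahedra (Kuhn subdivision, which is
conforming across cells), each tetrahedron is kept and tissue-tagged
according to the implicit model at its centroid, and the surviving linear
mesh is promoted to 10-node quadratic elements with one shared midside node
per unique edge. The boundary is therefore a staircase; no node snapping is
performed. That is deliberate: snapping risks inverted Jacobians, and nothing
downstream depends on the voxel boundary being smooth — contact geometry and
facet normals come from the *analytic* crown surface, and loads are bridged
onto the nearest volume boundary faces (within 1.5 element edge lengths,
which covers the staircase offset). The price is geometric: voxel boundary
artifacts show up as local stress noise, which is why nodal cervical values
are read as small-band means (below).

Because the PDL (0.2–0.3 mm) is thinner than practical element sizes, a
centroid-classified mesh can leave holes in the ligament. After
classification, every bone tetrahedron sharing a face with root dentine is
re-tagged PDL, guaranteeing a contiguous, at-least-one-element-thick
compliant shell; at coarse meshes the resolved ligament is therefore thicker
than the nominal parameter.

### The antagonist and its facet model

Specimen-based studies detect contacts between real antagonist crowns.
Synthetically, the antagonist surface is generated as the *complement* of
the worn lower crown: the occlusal height field raised by a gap field that
closes to zero over the wear-facet windows, plus a 0.5 mm approach standoff.
The facet windows are:

* a **buccal facet** disk (radius 0.9 mm) on the outer slope of the buccal
  cusp just below the tip — the overlap contact with the upper antagonist;
  its perpendicular load points linguo-apically;
* a **distal marginal facet** (0.25 mm) and, from Smith stage 2 on, a
  **mesial marginal facet** (0.22 mm) — facets multiply as wear advances;
* the **worn plateau**: wherever the unworn relief rises above the truncation
  plane, the ground-flat table is itself a facet (attrition grinds antagonist
  pairs flat against each other), so the flat contact area grows with wear
  depth and its normal is exactly axial.

This reproduces, by construction *of the geometry* (not of the results), the
qualitative contact behaviour reported for real worn teeth: contact areas
increase in number and extension with wear, and the resultant load direction
rotates from oblique (≈36° to the tooth axis at stage 1 with the default
55° cusp slope) to nearly axial (≈7° at stage 3).

### What the generator does not emulate

Real crowns have asymmetric marginal ridges, curved facet planes, anisotropic
enamel, a non-planar enamel-cementum junction, and periodontal geometry far
richer than a uniform shell; real wear is helical, guided by the individual
power stroke, not planar. Passing the pipeline's tests therefore shows that
the *mechanical chain* — facet-perpendicular loading, resultant
normalization, elastic solve, cervical comparison — behaves correctly and
reproduces the direction of the wear effect on an idealized premolar; it
does not validate magnitudes for any real tooth.

## Contact detection

`approach_to_contact()` finds the largest translation of the antagonist
along the approach direction that keeps a residual gap (`gap_tol`, default
0.01 mm), by ray-casting each vertex of either surface onto the other
(vertex-versus-facet closure; first contact through an edge-edge pair is
bounded by the facet size on these well-resolved grids).
`detect_contact_patches()` then marks every lower-surface triangle whose
distance to the antagonist (minimum over its vertices and centroid of the
exact point-to-triangle distance) is at most `epsilon`, and clusters contact
triangles into edge-connected patches. Two triangles touching only at a
vertex stay in different patches. `epsilon` defaults to 0.05 mm, on the
order of the 55 µm resolution of the optical and tomographic surface models
this emulates; a brute-force all-pairs path (`brute_force = TRUE`) exists
purely as the testing oracle for the spatially filtered implementation.

## From patches to a load case

Each patch loads the tooth along the negative of its outward area-weighted
mean normal — compressive, facet-perpendicular contact. Per-patch magnitudes
are proportional to patch area, and one global scalar then sets the
*magnitude of the resultant force vector* to the prescribed total (100 N
default). When patch normals disagree, proportionality to area and a fixed
resultant magnitude cannot both hold exactly; the resultant magnitude is the
hard constraint, which is why the scalar is applied after summing the patch
vectors. The normalization acts on the patch forces *before* they are
converted to consistent nodal loads; since consistent loads integrate the
traction exactly over straight faces, the assembled nodal vector conserves
the resultant to rounding (1e-8 relative is asserted in the tests). On a
straight-sided quadratic face under uniform pressure the corner nodes carry
zero force and each midside node carries one third of the face load — the
classic consistent-load pattern, used as a closed-form test.

## The elastic solver

All tissues are homogeneous, linear elastic and isotropic, with the standard
dental property set (enamel 84.1 GPa / 0.3, dentine 18.6 / 0.31, pulp
0.002 / 0.45, PDL 0.0689 / 0.45, alveolar bone 11.5 / 0.3); trabecular and
cortical bone are collapsed into the single bone entry of that table.
Stiffness uses the 4-point degree-2 Gauss rule, exact for straight-sided
quadratic tetrahedra; surface loads use the 3-point mid-edge rule, exact for
the same reason. Assembly exploits the Lamé closed form of the stiffness
integrand and is vectorized across elements. Boundary conditions follow the
cut-mandible protocol: mesial cut face fixed in x only (linguo-buccal),
distal cut face fixed in y and z. A rigid-body-mode check runs before every
solve: the six rigid modes are tested against the constrained DOF set, and a
singular pattern fails loudly naming the free mode rather than being
auto-fixed. Constraints are eliminated by row/column reduction (exact zeros
on constrained DOFs, testable), and the reduced SPD system is solved with a
supernodal sparse Cholesky factorization.

Stress is evaluated at the integration points, extrapolated linearly to the
element nodes, and volume-weight averaged over the elements sharing a node
— separately per tissue, so the enamel-dentine junction and the
dentine-ligament interface are never averaged across materials. A node's
combined value comes from its dominant (largest accumulated volume) region.
Principal stresses are the sorted eigenvalues of the nodal tensor; σ1 > 0 is
read as tension, the failure driver in brittle tissues, and the whole
analysis is conducted on the maximum-principal-stress criterion.

## Cervical sampling and the wear comparison

The buccal cervical margin is operationalized as the tooth-surface nodes
within ±0.5 mm of the cervix plane on the buccal half. Ten homologous sample
points are the nodes nearest ten equally spaced parametric positions along
that arc (azimuth mapped to [0, 1]); ties break to the lowest node id, and
because wear states of one tooth share the node lattice at the cervix, the
sampled arc positions are *identical* across states — homology by parameter,
not by node id. Sampled σ1 values are read from the enamel-region average
and, by default in the pipeline, as the mean over the cervix-band nodes
within one element length of the sample point. The band mean matters:
single-node values at the cervical bimaterial edge sit on a weak elastic
singularity and are recovery-noise prone on voxel boundaries, whereas the
small-band mean is stable across mesh resolutions (verified at element sizes
0.85, 1.0 and 1.2 mm).

The same robustness argument applies to the anatomical zone report
(`pattern_report()`): zones (buccal/lingual cervical bands, mesial/distal
flanks up to 40 % of crown height, root apex below 75 % of root length) are
summarized by mean and extreme σ1 and σ3, but the *dominant-tension flag* is
assigned on the zone mean. Raw nodal maxima live at bimaterial corners and
under load application faces, where the linear elastic peak grows without
bound under refinement; the zone mean corresponds to reading the color map
of a stress plot, which is how such patterns are reported.

`compare_wear_states()` aligns two states on their arc positions, reports
per-position σ1 pairs and deltas (less worn minus more worn), and the load
obliquity of each state — the angle between the resultant force and the
tooth axis.

## Numerical choices and degenerate inputs

* Element quality is enforced, not repaired: non-positive Jacobians and
  displaced midside nodes are construction errors.
* `approach_to_contact` errors when no contact is achievable along the ray;
  zero detected contacts is a valid (empty) result for detection but an
  error for load building.
* Patch configurations whose area-weighted normals cancel below 1e-6 of the
  total area are rejected as an indeterminate normalization.
* The 100 N total is configurable; because the problem is linear, every
  stress scales exactly with it (asserted to 1e-9 relative by doubling).
* Default problem sizes: the test suite runs the premolar at 1.2 mm elements
  (≈7k tetrahedra per state), the acceptance script at 0.85 mm (≈20k); the
  qualitative wear results were additionally checked at 1.0 mm.

## Known limitations

Isotropic enamel (a stated simplification of the modelled protocol as well),
static maximum intercuspation only — no power-stroke kinematics, no
deflection/break-free pathway simulation, no food-bolus contact; no fatigue
or crack propagation, which is the mechanism NCCL formation would ultimately
involve; one idealized tooth shape rather than a specimen population. The
package quantifies the elastic precondition of abfraction — cervical
tensile stress and its relief by wear — not lesion formation itself.
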