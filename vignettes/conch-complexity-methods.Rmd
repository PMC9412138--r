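---
title: "Quantifying shell ornamentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying shell ornamentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conchmetrics)
options(conchmetrics.log_level = "error")
```

## The problem

Shelled invertebrates — ammonites above all, but also gastropods, bivalves
and echinoids — carry sculptural relief on top of their basic conch
geometry: ribs crossing the whorl, spiral ridges running along it,
tubercles, spines, keels.  Comparing the *strength* of that ornament across
taxa is hard because ornament types differ, and because the obvious
surface-complexity measures confound ornament with body size and conch
shape.

`conchmetrics` implements a metric suite for 3D-scanned shell meshes built
around the **ornamentation index**

$$\mathrm{OI} = \frac{S}{S'} - 1,$$

where $S$ is the surface area of the specimen mesh and $S'$ the surface
area of a smooth reference model with the same conch geometry (built
manually in practice, synthetically here).  OI is the fractional extra area
created by ornament alone.  Because both areas scale identically under
similarity transforms, OI is size-free; because the reference shares the
conch geometry, it is also (to first order) shape-free.

The companion measures it is compared against are:

* **S/V ratio** ($\mathrm{mm}^{-1}$): surface area over enclosed volume.
  Scale-dependent by dimensional analysis — isometric growth by $k$ divides
  it by $k$.
* **Rugosity** $S/S_p$: surface area over the projected silhouette area
  $S_p$ on a reference plane.  Dimensionless but shape-dependent: a wider
  whorl adds area without adding silhouette.
* **Bouligand–Minkowski multiscale fractal dimension**
  $D = 3 - \lim_{r \to 0} \log V(r) / \log r$, where $V(r)$ is the
  influence volume of the voxelized surface dilated by spheres of radius
  $r$.

## Conventions and units

All coordinates are millimetres; there is no unit-conversion layer.
Meshes downloaded from archives are assumed to be in mm (this matters for
the default voxel spacing and silhouette pixel size, both calibrated to
0.2 mm-resolution surface scans).

For bilaterally symmetric planispiral shells the working object is the
*unilateral model*: one half of the shell cut along the plane of symmetry,
with the body-chamber aperture opened.  Rugosity then divides the one-sided
area by the silhouette on the symmetry plane and lands in the familiar
$\ge 1$ range.  For a *closed* mesh the same formula divides a two-sided
area by a one-sided silhouette, so a sphere gives 4 and closed shells give
$\ge 2$; `rugosity()` documents rather than hides this convention, and
`estimate_symmetry_plane()` (least-variance principal direction of the
area-weighted face centroids) automates the choice of projection normal for
planispiral material.  For taxa without a natural projection plane the
caller must supply a normal explicitly, and the value should be treated as
non-standard.

Negative OI is legitimate — a polished real shell can measure slightly
below its virtual reference — and is passed through; values below $-0.05$
trigger a warning suggesting a mismatched reference.

## Numerical choices

**Areas and volumes.** Surface area is the sum of half cross-product
magnitudes.  Enclosed volume is the absolute divergence-theorem sum, which
makes it insensitive to global orientation; it *refuses* non-watertight
meshes instead of silently capping holes, so the S/V column is absent for
open unilateral models.  Watertightness is diagnosed combinatorially: every
undirected edge shared by exactly two faces of opposite winding.
Degenerate faces (area $< 10^{-12}\,\mathrm{mm}^2$) are dropped with a
logged count, never an error — scanned meshes routinely contain slivers.

**Silhouette area.** Projected triangles are rasterized on a pixel grid
(default pixel 0.05 mm) and covered pixels counted once, so self-overlap in
projection — universal in scanned shells — is handled correctly.
Rasterization was chosen over exact polygon union for robustness; its
discretization error shrinks with pixel size, and the test suite checks it
against analytic silhouettes (disk, square) at the 1% level.  Note that
rugosity is a ratio of a physical area to a rasterized one: under
`scale_mesh(k)` it is exactly invariant only when the pixel size is scaled
by $k$ too, which is how the invariance tests evaluate it.

**Voxel dilation.** The surface is voxelized face-aware: every voxel whose
centre lies within half a spacing of a triangle (exact point-to-triangle
distances) is a seed.  This is tessellation-invariant, unlike seeding at
mesh vertices; vertex seeding is retained as an option
(`seed = "vertex"`) for strict replication of vertex-based workflows, and
the two coincide when the mesh is tessellated at voxel resolution.  The
grid is aligned so the bounding-box corner falls on a voxel centre
(axis-aligned surfaces voxelize one voxel thick) and padded by at least the
largest dilation radius so spheres never clip.  $V(r)$ is computed from an
exact Euclidean distance transform (Felzenszwalb–Huttenlocher lower
envelope, squared distances) and thresholding; the test suite proves exact
integer agreement with brute-force sphere stamping.  Distances are
Euclidean, not chamfer, matching the expanding-sphere definition.

**Fractal dimension.** A single least-squares fit of $\log V(r)$ on
$\log r$ over the default radii 3–20 (voxel units, spacing 0.2 mm) gives
the scalar $D = 3 - \text{slope}$.  The multiscale curve is always
attached: finite differences of $\log V$ between consecutive radii,
reported at the log-$r$ midpoints ($n-1$ values for $n$ radii).  Midpoint
differencing was chosen over centred-with-one-sided-endpoints because the
midpoint derivative estimate is exact for the secant it represents and
avoids manufacturing endpoint values; either scheme integrates back to the
same fit.  $D$ outside $[0, 3]$ by more than 0.2 triggers a warning (a
fit-window artifact, not an error).  $D$ depends on mesh resolution
relative to the voxel spacing; the package reports the spacing alongside
the value rather than pretending resolution-independence.

**Correlations.** `pearson_matrix()` uses the product-moment estimate with
the two-sided $t$-transform p-value on $n-2$ degrees of freedom
(`stats::cor.test`), on pairwise-complete observations — open meshes lack
S/V, and listwise deletion would discard their other metrics.  The per-pair
$n$ is reported so the choice is visible.  Stars follow the conventional
thresholds (\*\*\* $p<.001$, \*\* $p<.01$, \* $p<.05$), unadjusted by
default to match the conventional pairwise presentation; `adjust = "holm"`
is available.  A constant variable yields an undefined (flagged) row, never
zero.

## The synthetic generator

Real OI studies build the smooth reference by hand in a CAD package.  For
testing and simulation that step is replaced by `generate_pair()`: a
parametric conch plus a controlled ornament field.

The smooth conch is a logarithmic-spiral sweep of an elliptical aperture
with the classic coiling-morphospace controls: whorl expansion rate per
revolution, a Raup-style umbilical ratio fixing the inner whorl margin,
axial translation (0 = planispiral), and aperture semi-axes at the final
whorl.  The swept tube is capped at both ends, giving a watertight mesh;
with zero translation the vertex set is exactly mirror-symmetric about the
coiling plane and the coiling axis is recoverable by
`estimate_symmetry_plane()`.

Ornament is a displacement field along the *cross-section outward normal*,
evaluated from the sweep parametrization $(\theta, \varphi)$ stored as mesh
metadata — not from discrete normal estimation, which would inject
tessellation noise into the very quantity under study:

$$f(\theta, \varphi) = A_r \max(0, \sin(k_r \theta))^2
  + A_s \max(0, \sin(k_s \varphi))^2
  + \sum_j A_n e^{-d_j^2 / 2\sigma^2},$$

with ribs ($A_r$, $k_r$ ribs/whorl), spiral ridges ($A_s$, $k_s$ around the
aperture) and Gaussian nodes at seeded, jittered lattice positions.  The
squaring sharpens ridges; the rectification makes $f \ge 0$, so ornament
only adds material outward — matching real ribs and guaranteeing
$S \ge S'$.  Ornamented and smooth meshes share vertex count and face
topology exactly, and the same seed reproduces bitwise-identical meshes
(the generator saves and restores the caller's RNG state).

Default fixture sizes were chosen so a matched pair stays under 100k faces
(`steps_per_whorl = 256`, `sections = 64`); the test suite uses the
documented minimums (64/32) so that property sweeps over many pairs run in
seconds.  Default shell proportions (expansion 2, umbilical ratio 0.55,
final aperture 3 mm x 4 mm semi-axes, 2 whorls) give an evolute,
non-self-overlapping planispiral conch about 35 mm across — a typical small
ammonite — chosen so the swept tube is embedded and the divergence-theorem
volume is unambiguous.

What the generator does *not* emulate: scan noise and holes, diagenetic
damage, allometric ornament growth along ontogeny, septa and sutures, and
heteromorph (open-coiled) shells.  Passing tests on synthetic pairs
therefore validate the *metrics* — their oracles, invariances and
orderings — not the upstream manual-modelling step that real studies
perform, which remains outside the package's scope by design (an automated
strong-smoothing reference would conflate the metric with a reconstruction
heuristic).

## Invariance experiments

Two experiments frame what OI does and does not promise.

*Size.*  Scaling a matched pair by $k \in \{0.5, 2, 10\}$ leaves OI and
rugosity unchanged to machine precision while S/V scales exactly as $1/k$.
This is the executable form of the headline size-invariance claim, and the
acceptance suite asserts it at $10^{-9}$ relative.

*Shape.*  Doubling the whorl width of a regenerated pair leaves the
silhouette on the coiling plane nearly unchanged and inflates rugosity by
tens of percent.  OI also moves, but much less — and this deserves honesty:
OI is *first-order* proportional to ornament amplitude relative to shell
size, so regenerating a larger shell with the same absolute ornament
genuinely lowers OI (the shell *is* relatively less ornamented), and even
with ornament scaled in proportion a residual second-order shape
sensitivity of order 10–20% remains, driven by the mean-curvature term of
the displaced-surface area.  The test suite therefore encodes the
comparative claim — OI's relative change is smaller than rugosity's under
the same shape change — rather than an exact constancy that no
geometry-faithful construction satisfies.

## Problem sizes used in the checks

The shipped tests and the acceptance script run entirely on generated
inputs: primitives up to 5120 faces (icosphere subdivision 4), conch pairs
at 64–96 steps per whorl (4–19k faces), voxel grids up to $242^2 \times 43$
for the dimension-recovery fixtures, and dilation oracle grids at
$\le 50^3$ where brute-force sphere stamping is exact and affordable.
These sizes were chosen as the smallest at which each analytic bound
(discretization error of inscribed polyhedra, edge effects of finite
sheets) is comfortably met.

## Known limitations

* OI requires a smooth reference of the *same* specimen geometry; the
  package computes the index but cannot verify that the reference is
  faithful beyond warning on strongly negative values.
* Rugosity and S/V are reported for comparison purposes and inherit their
  documented shape and size dependence.
* The fractal dimension is resolution-sensitive by construction; values
  are only comparable across meshes scanned and voxelized at the same
  settings.
* The silhouette is rasterized; at the default 0.05 mm pixel the error is
  negligible for cm-scale shells but grows for sub-mm objects (decrease
  `resolution` accordingly).
* Volume (and hence S/V) is undefined for open meshes and refused rather
  than approximated.
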