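# conchmetrics

Surface-complexity metrics for 3D-scanned shells, built around the
**ornamentation index**

> OI = S / S′ − 1

— the fractional extra surface area that ribs, nodes, spines and other
sculpture add to a shell, measured by comparing the specimen mesh (area
*S*) against a smooth reference model of identical conch geometry (area
*S′*). OI is dimensionless, size-free, and far less shape-sensitive than
the measures it is usually compared with, which the package also computes:

| Metric | Formula | Depends on size? | Depends on shape? |
|---|---|---|---|
| Ornamentation index | S/S′ − 1 | no | weakly |
| S/V ratio | S/V (mm⁻¹) | yes | yes |
| Rugosity | S/Sp (silhouette area Sp) | no | yes |
| Multiscale fractal dimension | D = 3 − lim log V(r)/log r | no | yes |

The intended users are palaeontologists and malacologists working with
surface scans of ammonites, gastropods, bivalves and echinoids (OBJ/PLY/STL
meshes, coordinates in mm), plus anyone who needs watertight-mesh
area/volume, silhouette rugosity, or a Bouligand–Minkowski fractal
dimension from voxel dilation in R.

## What's in the box

* `read_mesh()` / `write_mesh()` — OBJ, PLY (ASCII + binary), STL (ASCII +
  binary) with validation (`validate_mesh()`: watertightness, manifoldness,
  components, degenerate faces).
* `surface_area()`, `enclosed_volume()`, `sv_ratio()`, `projected_area()`,
  `rugosity()`, `ornamentation_index()`, `oi_from_meshes()`,
  `estimate_symmetry_plane()`.
* `voxelize_surface()`, `dilation_volume_profile()`, `fractal_dimension()`,
  `mfd_for_mesh()` — influence volumes V(r) via an exact Euclidean distance
  transform, D from the log–log fit over dilation radii 3–20 at 0.2 mm
  voxels, with the multiscale derivative curve attached.
* `generate_pair()` — a parametric generator of matched ornamented/smooth
  conch pairs (logarithmic-spiral sweep + seeded ornament displacement
  field) for testing, calibration and simulation.
* `compute_all_metrics()`, `pearson_matrix()`, `write_report()` — batch
  tables (tibbles in, tibbles out), pairwise Pearson correlations with
  significance stars, CSV/JSON reports. `tidy()`, `glance()` and
  `autoplot()` methods throughout.
* A CLI (`exec/conchmetrics`, or `cli_main()` in-process) with subcommands
  `compute`, `fd`, `synth`, `report`.

## Worked example

Generate a ribbed shell and its smooth reference, then measure it:

```r
library(conchmetrics)

coil <- coil_params(steps_per_whorl = 96, sections = 48)
pair <- generate_pair(coil, ornament_params(rib_amplitude = 0.8,
                                            rib_frequency = 12, seed = 1))
pair
#> <shell_pair 'conch': 9266 vertices, 18528 faces, max ornament displacement 0.8 mm>

oi_from_meshes(pair$ornamented, pair$smooth, plane_normal = c(0, 0, 1))
#>        specimen_id    S S_ref    V    Sp     OI sv_ratio rugosity
#> 1 conch_ornamented 1651  1336 1821 499.1 0.2359   0.9066    3.307
```

Reading the row: the ribs add 23.6% extra surface area (`OI = 0.2359`,
reported as 23.59% in CSV exports) on top of a smooth conch of 1336 mm²;
the enclosed volume is 1821 mm³, so S/V is 0.91 mm⁻¹, and the surface is
3.3× its silhouette on the coiling plane. Scaling both meshes by any
factor leaves `OI` and `rugosity` unchanged and divides `sv_ratio` by that
factor — the point of the index.

Fractal dimension of a smooth closed surface sits near 2, as a 2-manifold
should:

```r
fd <- mfd_for_mesh(make_primitive("icosphere", radius = 10, subdivisions = 4))
fd
#> <fd_result: D = 2.0127 (slope 0.9873 over r in [3, 20])>
glance(fd)
#> # A tibble: 1 × 6
#>       D slope r_min r_max n_radii spacing_mm
#> 1  2.01 0.987     3    20      18        0.2
```

And the correlation report used to contrast metrics across a sample:

```r
pearson_matrix(tibble::tibble(x = 1:5, y = c(2, 1, 4, 3, 5)), c("x", "y"))
#> <correlation_matrix (Pearson )>
#>   x     y
#> x 1.000 0.800
#> y 0.800 1.000
```

From the shell instead:

```sh
exec/conchmetrics synth --out pairs --seed 42 --sweep 0,0.4,0.8
exec/conchmetrics compute --mesh pairs --out metrics --normal 0,0,1
exec/conchmetrics fd --mesh specimen.obj --out fdout --spacing 0.2 --radii 3:20
```

Every run writes its resolved configuration (`config.json`) and a log
beside its outputs; batch runs never abort on a single bad file.

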