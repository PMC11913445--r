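# elysar

3D quantification of giant endosomal–lysosomal organellar assemblies
(ELYSAs) in single cells imaged as multi-channel confocal z-stacks.

Mammalian oocytes concentrate lysosomes, endosomes and autophagic membranes
into giant (up to 7–10 µm) assemblies that enlarge and move to the cell
periphery during maturation from the germinal-vesicle (GV) to the
metaphase-II (MII) stage, and disperse over the 2-cell stages. `elysar` is
for cell biologists who need those structures measured reproducibly: it
reconstructs 3D objects from a fluorescence channel, sizes them, locates
them radially, tests marker colocalization, builds ratiometric acidification
images, and compares stages statistically — plus a synthetic confocal-scene
generator with exact ground truth, so every step is testable without raw
microscopy.

## The quantities at its core

* **Equivalent-sphere diameter** of an object of volume $V$:
  $d = (6V/\pi)^{1/3}$.
* **Distal distance** of an object from the 3D cell center $c$:
  $\lVert \bar{x} - c\rVert_2 + \overline{d_s}$, where $\bar{x}$ is the
  unweighted centroid of member voxel centers and $\overline{d_s}$ the mean
  centroid-to-surface distance (surface = face-exposed voxels). The second
  term keeps large cortical assemblies from being scored as interior.
* **Zones**: distal distance > 30 µm ⇒ peripheral, < 25 µm ⇒ medial
  (strict; the band between is "intermediate").
* **Object-based colocalization**: a partner-channel object counts as
  colocalized iff the voxel containing its geometric center carries a
  reference-channel label; reference objects with ≥ 1 partner center are
  double-positive.
* **Ratio imaging**: background-corrected mean projections of two acidity
  channels divided pixel-wise, with a denominator floor masking unstable
  pixels.
* **Group statistics**: per-cell summaries compared by one-way ANOVA +
  Tukey HSD with a compact letter display.

Segmentation follows the classic 3D-object-counting recipe: optional
in-plane Gaussian blur, blank-region background subtraction, strict
intensity threshold, 3D connected components (6/18/26-connectivity),
measurement, and volume filtering (default 0–5000 µm³).

## Worked example

Simulate an MII-like cell (81 z-planes at 1 µm, 0.35 µm pixels, 25
assemblies with known ground truth), reconstruct its LAMP1 objects and
summarize:

```r
library(elysar)

scene <- render_scene(preset_stage_scene("MII", seed = 1))
stack <- scene$stack
stack
#> <image_stack> 81 z-planes x 256 x 256 px, 3 channel(s): LAMP1, RAB5, LC3
#>   voxel size (dz, dy, dx): 1 x 0.35 x 0.35 um

geom <- find_cell_geometry(get_channel(stack, "LAMP1"), stack$voxel_size_um)
seg  <- segment_objects(stack, segmentation_params(threshold = 1000),
                        channel = "LAMP1", cell_geometry = geom)
objects <- seg$table |>
  add_surface_distance(seg$labels, stack$voxel_size_um) |>
  distal_distance(geom) |>
  add_zones()

dplyr::select(objects, label, volume_um3, equivalent_diameter_um,
              distal_distance_um, zone)
#> # A tibble: 25 × 5
#>   label volume_um3 equivalent_diameter_um distal_distance_um zone
#>   <int>      <dbl>                  <dbl>              <dbl> <fct>
#> 1     1       24.9                   3.62               36.1 peripheral
#> 2     2       92.9                   5.62               32.2 peripheral
#> 3     3      163.                    6.77               32.9 peripheral
#> 4     4       31.4                   3.91               32.2 peripheral
#> 5     5      155.                    6.66               34.5 peripheral
#> 6     6       35.3                   4.07               33.1 peripheral
#> # i 19 more rows

zone_counts(objects, d_min_um = 4)
#> # A tibble: 1 × 3
#>   n_peripheral n_medial n_intermediate
#>          <int>    <int>          <int>
#> 1           12        0              0

volume_fraction_above(objects, 3)
#> [1] 1
```

All 25 simulated assemblies are recovered; every one larger than 4 µm sits
in the peripheral zone (the MII regime the preset encodes), and — this
preset containing only 3–7 µm assemblies — objects above 3 µm carry all of
the LAMP1-positive volume. `bin_by_diameter(objects)` gives the size
distribution, `autoplot()` plots it, and `compare_groups()` handles
multi-stage comparisons of per-cell summaries. `run_pipeline(run_config(...))`
chains all of the above (including RAB5/LC3 colocalization and ratio
imaging) over many cells and writes CSV tables plus a checksummed manifest.

A thin command-line front end lives at `inst/scripts/elysa-quant.R`
(`simulate`, `analyze`, `compare` subcommands).

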