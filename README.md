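# wmhshape

3D shape and location features for white matter hyperintensities (WMH) on
brain MRI, beyond total lesion volume.

WMH are the hallmark of cerebral small vessel disease on FLAIR MRI, and they
are usually summarized by a single volume — a measure that barely
discriminates between disease processes. This package quantifies each lesion
individually: given a binary WMH segmentation mask (NIfTI) co-registered with
a ventricle mask and a lobe label map, it separates lesions by 26-connected
component labeling, excludes fragments under 5 voxels (< 0.014 ml at a
0.96 × 0.96 × 3.00 mm FLAIR grid), builds a closed triangular surface mesh
per lesion, and computes:

* **shape features** — surface area (optionally /ICV), eccentricity
  `D_max / D_min` (largest 3D caliper diameter over the smallest width
  orthogonal to it; 1 = spherical), three compactness measures
  (`V²/A³`, bounded by the isoperimetric constant `1/(36π)`;
  `V/(dx·dy·dz)`; `V/d_max³`), box-counting fractal dimension of the lesion
  boundary, and the medians of the curvature-based shape index
  `(2/π)·atan((k₁+k₂)/(k₁−k₂))` and curvedness `√(k₁²+k₂²)` at Gaussian
  scale σ = 1 voxel;
* **location features** — minimum ventricle distance (exact anisotropic
  distance transform), classification as *punctuate deep* (> 1.0 cm from the
  ventricles **and** maximum diameter < 1.5 cm, both strict) versus
  *non-punctuate*, manual-correction overrides, lobe assignment, and
  per-voxel mean eccentricity maps;
* **cohort statistics** — per-subject summaries by lesion class, the
  ×10000-then-log transform for volumes, age- and sex-adjusted linear
  regression reporting B and standardized Beta with 95% CIs, per-lobe
  chi-square and Mann-Whitney U comparisons, and feature distribution
  summaries (mean/min/max/skewness/KS);
* **synthetic data** — analytic shape phantoms, a toy atlas, and two-group
  cohort generation with injected, known effects, so the entire pipeline is
  testable without patient data.

## Worked example

A digital ellipsoid with semi-axes 9 × 3 × 3 mm:

```r
library(wmhshape)
ph     <- make_phantom("ellipsoid", c(9, 3, 3), grid_shape = c(26, 12, 12))
lesion <- label_components(ph)[[1]]
round(unlist(shape_features(lesion, ph, icv = 1450)), 4)
#>         lesion_id          n_voxels         volume_ml  surface_area_mm2
#>            1.0000          360.0000            0.3481          302.9257
#>  surface_area_icv      eccentricity      compactness1      compactness2
#>            0.2089            2.8355            0.0044            0.5371
#>      compactness3 fractal_dimension       shape_index        curvedness
#>            0.0597            1.9973            0.5916            0.6146
#>   max_diameter_mm         bbox_x_mm         bbox_y_mm         bbox_z_mm
#>           18.0555           18.0000            6.0000            6.0000
```

The eccentricity 2.84 reads as "nearly three times longer than wide" (the
analytic value for a 3:1 ellipsoid is 3; voxelization at this size accounts
for the rest), compactness2 says the lesion fills ~54% of its bounding box,
and the volume 0.348 ml matches 360 voxels of 1 mm³ within the half-voxel
surface placement of the mesh.

A full synthetic two-group study, from simulation to group comparison:

```r
dir <- tempfile(); dir.create(dir)
cfg <- run_config(output_dir = dir, seed = 42, n_per_group = 12, quiet = TRUE)
cmd_simulate(cfg)                                  # masks + atlas + tables
cfg$masks_dir    <- file.path(dir, "masks")
cfg$atlas_dir    <- file.path(dir, "atlas")
cfg$subjects_csv <- file.path(dir, "subjects.csv")
rec <- cmd_extract(cfg)                            # lesion table (CSV)
res <- cmd_stats(cfg)                              # report tables
res$table3[res$table3$stratum == "punctuate_deep" &
           res$table3$outcome == "eccentricity", ]
#>        patients      controls    b beta beta_lo beta_hi        p n_used
#>  2.94 +/- 0.40 2.23 +/- 0.25 0.69 0.73    0.38    1.08 0.000307     24
```

The generator injected a +0.4 log-elongation shift into the patients'
punctuate-deep lesions; the age/sex-adjusted regression on per-subject median
eccentricity recovers a positive standardized effect (Beta 0.73,
95% CI 0.38–1.08) already at 12 subjects per group.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/wmhshape.R simulate --out study --seed 42 --n-per-group 12
Rscript inst/cli/wmhshape.R extract  --masks study/masks --atlas study/atlas \
        --subjects study/subjects.csv --out study
Rscript inst/cli/wmhshape.R stats    --subjects study/subjects.csv \
        --lesions study/lesions.csv --out study
```

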