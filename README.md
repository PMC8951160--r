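# tomocloud

Reconstruction of volumetric and surface **3-D point-cloud models from
micro-CT slice stacks**, with the morphometrics needed to monitor how an
object deforms across repeated scans. Written for the imaging workflows of
archaeological conservation — waterlogged wooden artefacts, bone, ceramics —
where the questions are: *where are the internal cracks, pores and
fractures*, and *how much has the object shrunk, bent or cracked since the
last scan*.

## What it computes

A scan is an ordered stack of 2-D grey slices plus voxel spacing
(dx, dy, dz in µm). Each voxel is placed at

```
x = (j - 1) dx,   y = (i - 1) dy,   z = k dz
```

with `k` the 1-based slice position — the `k dz` term is what makes the
model volumetrically faithful rather than a stretched pile of images.
Two reconstruction modes:

* **direct** — every voxel passing an optional grey window becomes a point
  (exhaustive; huge clouds);
* **segmented** — per slice, the solid object (above-air grey, largest
  8-connected component) contributes its boundary; a feature grey window
  (internal voids are darker than sound wood) plus an edge detector —
  Roberts cross by default, `Gx = p(i,j) − p(i+1,j+1)`,
  `Gy = p(i,j+1) − p(i+1,j)`, edge where `√(Gx² + Gy²) > t` — contributes
  the internal feature boundaries; labels: `outer_surface`,
  `internal_feature`, `wood_boundary`.

Morphometrics: principal-axis length/width/thickness, voxel-count volume
(`count · dx dy dz`), percent-change/index tables across scan years
(`index = 100 + 100·(x − x_base)/x_base`), cloud-to-cloud nearest-neighbour
distance fields and point-to-point ICP registration for deformation
monitoring. Models are exchanged as vertex-only Wavefront OBJ with label
colours. A parametric phantom (tapered ellipsoid body with planted cracks
and pores, full ground truth and closed-form volume) makes the whole
pipeline testable without scanner data. See
`vignettes/reconstruction-methods.Rmd` for the methods account.

## Worked example

Deformation monitoring on the published measurements of the repeatedly
scanned Palaeolithic wooden point (µm / µm³ per scan year, base 2009):

```r
library(tomocloud)
reps <- palaeo_point_reports()
subset(change_table(reps, base = "2009"), quantity == "volume")
#>  quantity label   value  index percent
#>    volume  2009 70653.6 100.00    0.00
#>    volume  2013 80404.1 113.80   13.80
#>    volume  2015 66382.8  93.96   -6.04
#>    volume  2017 65238.9  92.34   -7.66
#>    volume  2018 63871.9  90.40   -9.60
#>    volume  2019 63289.4  89.58  -10.42
```

The +13.80 % entry is the swelling from the resin-irrigation phase of
conservation; the later rows are the drying shrinkage that monitoring is
meant to catch.

Synthetic end-to-end run (96³ voxels at 20 µm, noise sd 5):

```r
spec  <- phantom_spec(noise_sd = 5, seed = 42)
ph    <- generate_phantom(spec)
cfg   <- recon_config("segmented", spec$spacing,
                      feature_window = grey_window(100, 140))
cloud <- segmented_reconstruct(ph$stack, cfg)
cloud
#> point cloud 'phantom-seed42': 18693 points
#>
#> internal_feature    outer_surface    wood_boundary
#>             7122             8957             2614
round(bounding_dimensions(cloud), 1)
#>    length     width thickness
#>      1660      1000       640
ph$truth$analytic_volume                                  # 557495094 µm³
voxel_volume(sum(ph$truth$body_mask), spec$spacing)       # 557664000 µm³
```

The 18,693-point segmented cloud stands against 884,736 voxels in the
direct mode — the size contrast that makes the segmented algorithm the
practical one. The voxelized body volume agrees with the closed-form
phantom volume to 0.03 %.

The same pipeline from the shell:

```sh
Rscript inst/exec/tomocloud phantom --out stack/ --seed 42
Rscript inst/exec/tomocloud reconstruct --in stack/ --mode segmented \
    --window 100:140 --dx 20 --dy 20 --dz 20 --out model.obj
Rscript inst/exec/tomocloud morph report model.obj
```

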