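# octreg3d

Motion correction, registration and averaging of volumetric OCT scans.

## What this is for

Retinal OCT acquires a volume as a raster of fast B-scans over several
seconds, during which the eye drifts, microsaccades and blinks. A single
volume therefore shows broken vessels, axial jumps, small in-plane rotation
and heavy speckle. The standard remedy is to acquire many volumes, register
them to a common reference and average them. octreg3d implements that
pipeline using intensity data only — no phase, no angiographic flow signal —
so it works across OCT systems (custom research systems and commercial
devices alike), for researchers processing serially acquired OCT/OCTA
volumes.

The pipeline:

1. **Preprocessing** — intra-volume axial motion correction against the
   center B-scan; quality ranking (motion, SNR, clarity) to pick the
   reference volume; rigid transverse alignment by phase-only correlation
   (POC) of en-face projections; optional nonrigid en-face alignment for
   motion-tracked acquisitions; subvolume/sub-B-scan axial alignment;
   automatic microsaccade detection from adjacent-B-scan offsets, removing
   flagged frames ±3 neighbors.
2. **Coarse-to-fine B-scan registration** — per-subvolume en-face POC
   matching, then per-B-scan matching at pixel precision with
   tolerance-based outlier rejection (3–5 px band) and interpolation of
   excluded frames, producing a per-frame displacement field
   (Δx, Δy, Δz).
3. **Strip-wise affine rotation** — each en-face strip is rotated within
   ±1° by a bracketed search maximizing normalized cross-correlation, and
   the angle is applied at every depth.
4. **Averaging and evaluation** — voxelwise averaging excluding vacated
   borders; MSE, SSIM, multi-scale SSIM and CNR versus the number of
   averaged volumes.

The shift primitive is 2D POC: the normalized cross-power spectrum
`R = Gr∘Gt* / |Gr∘Gt*|` is inverted and its argmax gives the displacement;
a plain normalized cross-correlation variant handles speckle-dominated
frame-to-frame matching. A synthetic phantom generator (layered curved
retina, vessels with shadows, multiplicative speckle, ground-truth motion
traces) makes every stage testable by parameter recovery; see the methods
vignette (`vignettes/octreg3d-methods.Rmd`) for the models and design
decisions.

## Worked example

```r
library(octreg3d)

# a synthetic study: 4 co-located acquisitions with drift-type eye motion
params <- phantom_params(shape = c(64, 96, 96), speckle_variance = 0.05, seed = 5)
ens <- make_ensemble(params, n = 4, motion_model = "drift_only")

cfg <- default_config()
cfg$output_dir <- tempfile("octreg_run")
cfg$stages$axial_motion <- FALSE   # synthetic traces are inter-volume only
res <- run_register(cfg, volumes = ens$volumes)

res$reference_index
#> [1] 3
print(res$report)
#>   k         mse   ms_ssim
#> 1 1 0.012820178 0.7793993
#> 2 2 0.006865861 0.8869972
#> 3 3 0.006010837 0.8994257
```

The ranking scored acquisition 3 highest and made it the reference. The
metric curve compares the average of the best k registered targets with
the reference: the mean squared error of the en-face projection halves
from a single registered volume (k = 1) to the 3-volume average, and the
multi-scale structural similarity rises from 0.78 to 0.90 — the
quantitative signature of speckle averaging down while registered
structure reinforces. The output directory contains the
averaged volume (`averaged.tif` + JSON sidecar), per-volume displacement
CSVs, rotation-plan CSVs, the ranking table, the evaluation curve
(CSV + PNG), the resolved configuration and a log of every applied shift.

A shell interface wraps the same functions:

```sh
Rscript inst/cli/octreg3d.R simulate --out sim/ --preset combined --n 5 --seed 1
Rscript inst/cli/octreg3d.R register --config run.yaml
Rscript inst/cli/octreg3d.R evaluate --reference ref.tif --candidate avg.tif
Rscript inst/cli/octreg3d.R export-field --field field_acq02.csv --volume acq02.tif --out reg.tif
```

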