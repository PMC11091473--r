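---
title: "Registration and averaging of motion-corrupted OCT volumes: methods"
author: "octreg3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registration and averaging of motion-corrupted OCT volumes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Optical coherence tomography acquires a retinal volume as a raster of fast
B-scans stacked along a slow axis over several seconds. Involuntary eye
motion — slow drift from respiration and cardiac pulsation, abrupt
microsaccades, blinks — displaces the beam between (and occasionally within)
B-scans, so a single volume carries vessel discontinuities, axial jumps and
small in-plane rotations; speckle further degrades contrast. Acquiring many
volumes and averaging them removes speckle and fills in motion-damaged
regions, but only after every volume has been registered to a common
reference. octreg3d implements a system-agnostic, intensity-only pipeline
for that task: it uses no phase information and no angiographic flow
contrast, so it applies to any OCT system that produces intensity volumes.

All volumes are 3D arrays in the canonical order `(slow, depth, fast)`: a
frame (fast B-scan) is `data[i, , ]`, and the en-face projection is the mean
over depth. Indexing is R's native 1-based; the center of an n-frame block
is `floor(n/2) + 1`, so the center of a 10-frame subvolume is its 6th
member.

## Shift estimation primitives

Two primitives estimate integer displacements between 2D images.

**Phase-only correlation (POC).** With Fourier transforms $G_r$, $G_t$ of
the (zero-meaned) reference and target, the normalized cross-power spectrum
$R = G_r \circ G_t^{*} / |G_r \circ G_t^{*}|$ is inverted and the argmax of
$r = \mathcal{F}^{-1}(R)$ gives the displacement $(\Delta x, \Delta y)$ of
the target relative to the reference. POC whitens the spectrum, which gives
a sharp, contrast-invariant peak on structured images. Shifts are
pixel-precision throughout (no subpixel interpolation); argmax coordinates
past half the image size wrap to negative shifts; exact ties break toward
the smallest $(|\Delta y|, |\Delta x|)$, preferring the null shift under
ambiguity; spectrum bins below $10^{-12}$ of the peak cross-power magnitude
are zeroed rather than normalized. A Hann window (the default for en-face
inputs) suppresses the spectral leakage of non-periodic content.

**Normalized cross-correlation (`xcorr_shift`).** The same FFT machinery
without whitening: the value at each shift is the Pearson correlation of
the circularly overlapped pair. Whitening weights all frequencies equally,
so when two images share structure only at low frequencies while their high
frequencies are *independent* speckle — the situation for any two B-scans of
the same tissue — the POC peak drowns. Frame-to-frame operations (adjacent
B-scan motion detection, fine frame matching, axial tile matching)
therefore use plain correlation, while projection-based operations
(transverse, coarse, nonrigid) use POC; where a single corrupted stripe can
poison a POC estimate, the POC and correlation candidates are arbitrated by
the overlap correlation each implies.

Both estimators accept an admissible shift window. Layered B-scans are
quasi-periodic, and unrestricted circular correlation produces wrap aliases
near half the image width that can outscore the true peak under speckle;
every coarse-to-fine caller restricts its search to the physically
plausible range.

**Frame preprocessing.** Frame-level matching operates on 3×3
box-smoothed, doubly centered frames: subtracting per-depth row means
removes the laterally uniform layer pattern (which correlates equally at
every lateral shift), and subtracting per-A-line column means removes the
axial speckle streaks each A-line carries. What remains — vessels, shadows,
texture — is what actually encodes lateral displacement.

## Pipeline

### Stage 1: preprocessing

1. **Intra-volume axial correction** (`axial_motion_correct`): every fast
   B-scan is shifted axially to maximize correlation with the volume's
   center frame; a second pass does the same along the slow direction.
   This flattens acquisition wobble (and, inevitably, some true curvature,
   consistently across volumes).
2. **Quality ranking** (`rank_volumes`): volumes are scored on motion
   (lower decile of adjacent-frame correlations on preprocessed frames — a
   few saccade breaks drag it down, re-scanned duplicate lines do not),
   an SNR proxy (inverse coefficient of variation over the bright half,
   which falls as multiplicative speckle grows), and clarity (median
   fast-axis gradient energy of the projection; the median ignores the
   strong artificial edges motion artifacts create). Each term is min-max
   normalized within the set — a term whose relative spread is under 5% is
   neutralized rather than letting noise be amplified to full scale — and
   combined as `0.5·motion + 0.3·snr + 0.2·clarity`. The top volume becomes
   the reference.
3. **Transverse alignment** (`transverse_align`): Hann-windowed POC between
   en-face projections, arbitrated against a cross-correlation candidate;
   the target is rigidly shifted by the negated estimate (zero fill).
4. **Nonrigid en-face alignment** (`nonrigid_enface_align`, motion-tracked
   acquisitions only): block-wise POC displacements on a regular grid are
   fit with quadratic surfaces by least squares and the smooth warp is
   applied identically at every depth (bilinear). More than half the blocks
   degenerate triggers a rigid fallback.
5. **Motion detection and removal** (`detect_motion`): walking outward from
   the center frame, the fast-axis offset of each adjacent frame pair is
   estimated; offsets of at least `threshold_px` (default 2 px — 1 px is
   within quantization noise) flag the outer frame, and flagged indices
   dilated by ±3 frames are removed. The offset estimator is guarded
   against the two impostors a thresholded pairwise statistic suffers
   from under speckle: weak-texture near-ties (the best off-zero peak must
   beat the best near-zero correlation by a significance margin, with a
   2-frame-stack fallback at a stricter margin where single-frame texture
   is too weak to decide) and individual steep vessels whose crossing
   point wanders between B-scans (amplitudes clamped so the broad texture
   outvotes single vessels; the search window bounded at ±12 px, the
   plausible microsaccade range at this field size; and a
   separation-invariance test — a rigid jump persists unchanged one frame
   further across the boundary, while a marching vessel's offset grows and
   a one-frame wobble decays). A rare residual false alarm (about one
   flagged frame per hundred motion-free volumes in validation) costs only
   recoverable frames: removal blanks them and registration reconstructs
   them by interpolation. In the pipeline this runs *before*
   axial alignment: a saccade frame's lateral offset exceeds the axial
   tiles' search window, so aligning it axially first fragments the frame
   and hides the very offset the detector needs. Removed frames are
   blanked in place (shape is kept; they are rebuilt later by displacement
   interpolation); physical deletion via `remove_motion` refuses to drop
   more than half a volume.
6. **Axial alignment** (`axial_align`): volumes are split into subvolumes
   of 10 frames; the center frame of each reference subvolume is the local
   reference; each target frame is split into sub-B-scans of 64 A-lines
   and each (depth × width) tile's depth displacement is estimated by
   overlap-only correlation — each candidate shift is scored on the rows
   the tiles actually share, because circular correlation lets zero-border
   penalties outweigh small misalignments of the smooth axial profile. The
   reference's own frame-versus-center displacement (retinal curvature, not
   motion) is measured the same way and subtracted before the correction is
   applied.

### Stage 2: coarse-to-fine B-scan registration

The target is divided into evenly spaced subvolumes (default 8 frames,
halved automatically when more than 20% of subvolumes fail to match). Each
subvolume's en-face strip is matched against the same rows of the reference
projection (POC/correlation arbitrated by overlap score); the per-subvolume
$(\Delta x, \Delta y)$ identifies the best reference subvolume, and
per-frame displacements are linearly interpolated between subvolume
centers. Weak strips (overlap score under half the median) are treated as
unmatched and interpolated.

The fine stage matches every target frame against each reference frame of
its coarse-matched subvolume (±2 frames of margin), at pixel precision,
using 3-frame preprocessed stacks — the frame and its slow neighbors
stacked row-wise, so a match must be consistent over a local neighborhood —
with the fast search window centered on the coarse estimate (±12 px) and a
tight depth window (±3 px). The best correlation peak selects the
reference frame (`dy`); the lateral correction (`dx`) is then re-estimated
from the single center frame against that reference frame, so one
corrupted B-scan keeps its own shift (and gets excluded) instead of
inheriting its neighbors' consensus. Outliers are
rejected in two passes: a frame whose shift differs from *both* adjacent
matched frames by more than `tolerance_px` (default 4, the midpoint of the
empirical 3–5 px band; Chebyshev distance on `(dx, dy)`) is excluded, and a
second pass excludes frames deviating from the running 7-frame median by
more than the tolerance — the adjacent-only rule cannot see a short run of
consistently wrong matches. Excluded frames are rebuilt by linear
interpolation (interior) or extrapolation (ends), with provenance labels.
More than 30% exclusions warns; more than 60% is a hard failure.

`apply_field` shifts each frame by its integer `(dx, dz)`, reassigns it to
slow position `i + dy[i]`, averages collisions, linearly interpolates
unfilled positions, and clamps out-of-bounds reassignments with a warning.
All-zero (blanked) frames never contribute.

### Stage 3: strip-wise affine rotation

Residual in-plane rotation is small (assumed within ±1°). The en-face
projections are divided into equally spaced slow-axis strips (default 8);
for each strip a bracketed search maximizes the normalized cross-correlation
between the two strips under a candidate rotation, and the optimum is
applied at every depth index of the strip. Numerical design of the
objective, each element of which proved necessary:

- rotations are about the *full* en-face centroid, so each strip transform
  is the restriction of one global rotation (a strip-centroid rotation
  differs from a global rotation by a translation and cannot recover it);
- strips are rotated with 3 rows of neighboring context and cropped back,
  so boundary pixels sample real content;
- projections are mean-centered and the correlation is evaluated only over
  pixels sampled inside both supports and at least 2 px from the image
  boundary — a handful of fill pixels otherwise dominates the correlation;
- the candidate rotation is split half onto each side (reference by
  −a/2, target by +a/2) so both carry identical resampling blur at every
  candidate angle; a one-sided rotation biases the estimate toward zero
  because interpolation blur competes with alignment.

The search scans at 0.1° to bracket the peak (the correlation need only be
unimodal locally), then golden-section refines to a 0.02° bracket. A strip
whose optimum does not beat the unrotated baseline keeps angle 0, so
en-face agreement with the reference never decreases; an optimum pinned at
the ±1° bracket edge logs a warning. `upsample_factor = 2` (bilinear
upsample before rotation, box downsample after) reduces quantization for
high-lateral-resolution data and is used in the validation studies.

## Averaging and evaluation

`average_volumes` takes the voxelwise mean, excluding zero-filled voxels
from the denominator so shifted borders are not darkened. Metrics compare
en-face projections after joint min-max normalization to [0, 1]:

- **MSE**: mean squared difference over all pixels.
- **SSIM**: the standard luminance–contrast–structure statistic with
  $c_1 = (0.01 L)^2$, $c_2 = (0.03 L)^2$, $L = 1$, evaluated in an
  11-pixel Gaussian window (σ = 1.5) and averaged; a single-window global
  form is available for closed-form checks.
- **MS-SSIM**: the dyadic multi-scale extension with the conventional
  exponent weights (0.0448, 0.2856, 0.3001, 0.2363, 0.1333), contrast and
  structure at every scale, luminance at the coarsest, terms clamped at
  zero; the scale count reduces automatically (with renormalized weights)
  when an image side drops below the window, and one scale reduces exactly
  to SSIM.
- **CNR**: $(\mu_{fg} - \mu_{bg}) / \sigma_{bg}$ between caller-supplied
  masks, with a combined-variance denominator available.

`metrics_vs_k` averages the first k registered *targets* (quality order)
and evaluates MSE and MS-SSIM against the reference for k = 1..K; the k = 1
entry is a single registered volume, and the reference itself never enters
the average (putting it there would start the curve at MSE 0 and invert the
trend). An 8-pixel margin is cropped from the projections first: vacated
borders carry fill whose extent differs per member, which otherwise adds
spurious wobble to the curve. As k grows, MSE falls toward the reference's
own noise floor and MS-SSIM rises.

## The synthetic phantom and what the tests show

`generate_phantom` builds retina-like volumes from: an axial profile of
smooth intensity bands with a thin hyperreflective band (retinal pigment
epithelium analogue — a sharp axial landmark), a smooth elevation surface
that curves the layers (without it, B-scans are laterally
translation-invariant and single-frame matching is ill-posed), a branching
vessel pattern embossed at superficial and deep bands with shadowing below
the superficial vessels (columnar lateral landmarks), two-scale lateral
texture (smooth shading plus a granular cellular-mosaic analogue with
2–3 px features — coarse enough to survive bilinear resampling), a dark
structureless pre-retinal band (vitreous analogue, a signal-free region for
noise measurements), and multiplicative gamma speckle with ~9 px axial
correlation (OCT speckle decorrelates laterally A-line to A-line but is
correlated along depth over the axial point-spread function; with iid
speckle, en-face projections average implausibly clean and single-volume
image quality is unrealistically high). Defaults: 64×96×96 voxels, vessel
density 0.1, speckle variance 0.05 — sizes chosen so a full pipeline run
takes seconds and the whole validation suite minutes.

`corrupt` applies a ground-truth `motion_trace` with a sampling (gather)
model of a raster scan under eye motion: the frame recorded at slow
position p images the retina at p − dy[p], displaced by (dx[p], dz[p]),
optionally after a global rotation and a smooth quadratic warp; fresh
speckle is drawn per acquisition. A scatter model (placing frames at
displaced positions, averaging collisions and interpolating holes) was
rejected as unphysical: a scanner records a real frame at every position,
and blended frames corrupt quality ranking. Presets: `drift_only`
(sinusoidal transverse drift ≤ 4 px fast / 2 px slow), `saccades` (drift
plus 1–3 abrupt 3–10 px jumps lasting 2–5 frames), `rotation` (±0.2–0.8°),
`tracked_warp` (≤ 4 px quadratic warp), `combined` (drift, saccades, and
smooth axial displacement ≤ 6 px). `make_ensemble` gives member 1 a zero
trace — the clean, reference-grade acquisition a ranking should discover.

The validation studies (tests and `scripts/acceptance.R`) run the pipeline
with the intra-volume axial stage and the affine stage toggled off for the
*translation* recovery study: the traces model inter-volume motion only,
the intra-volume stage exists for raw-acquisition wobble and consistently
flattens each volume's own curvature (contaminating the trace comparison),
and the translation presets contain no rotation. The rotation study
exercises the affine stage on noise-free phantoms: a ±1° rotation moves
content by less than a pixel at this field size, so under speckle the
correlation is flat and the estimator correctly refuses to rotate —
angle-recovery accuracy is a property of the estimator measured where the
signal exists. The averaging study uses `drift_only` ensembles (n = 11,
k = 1..10) so the metric curve isolates averaging rather than residual
misregistration; recovery under the full `combined` conditions is measured
separately. Background noise reduction is measured as the en-face pixel
variance of the signal-free vitreous band over the interior (borders carry
shift fill), averaged versus single. Contrast-to-noise is measured on the
deep vessel band projection (a deep-plexus slab analogue): over the full
depth projection the background is dominated by the phantom's fixed
texture, which no amount of averaging removes, so full-projection CNR is
flat by construction; within the thin band the background is
speckle-dominated and averaging raises CNR.

What passing these tests does *not* show about real data: the phantom has
no blinks (total signal loss), no intra-B-scan distortion, no A-line-level
jitter, no depth-dependent signal roll-off or defocus, speckle is only a
first-order statistical analogue, and the nonrigid warp is a smooth
quadratic field rather than the piecewise re-scan geometry of tracking
systems. Registration accuracy against a speckled reference is also
intrinsically bounded: every target is matched to the same reference
realization, so matcher errors repeat across members and do not average
out.

## Known limitations

- All shifts are integer pixels by design; sub-pixel residuals persist and
  bound the achievable MSE floor.
- Strips rotate independently; seam discontinuities between strips are
  accepted, as is a single in-plane rotation per strip.
- The quality score's weights (0.5/0.3/0.2) are fixed heuristics; the
  three ingredients are standard but their combination is not calibrated
  to any perceptual scale.
- The coarse stage assumes motion within an 8-frame subvolume is
  negligible; very fast drift violates this.
- `detect_motion` keys on fast-axis offsets, the dominant saccade
  signature; purely axial or purely slow-axis jumps are handled by the
  axial and fine stages instead.
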