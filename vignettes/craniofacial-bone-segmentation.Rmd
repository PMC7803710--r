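---
title: "Methods: ZTE-driven craniofacial bone segmentation from multi-contrast MRI"
author: "CranioSeg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ZTE-driven craniofacial bone segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Rendering the craniofacial skeleton in 3D from MRI, without CT, is hard
because cortical bone has a near-zero T2\* and returns almost no signal in
conventional sequences. Two acquisition strategies get part of the way
there:

* **Black-bone gradient echo (BB)**: short TE/TR and a low flip angle
  flatten soft-tissue contrast and leave bone *dark*. Resolution is high,
  but air is equally dark, so a dark-voxel classifier cannot tell a frontal
  sinus from the bone around it.
* **Zero echo time (ZTE)**: readout begins immediately after the RF pulse,
  so short-T2 bone yields an intermediate signal, clearly above air and
  below soft tissue. Air is therefore *identifiable* — but practical ZTE
  resolution is coarse (about 1 mm in plane, 1.6 mm through plane).

`CranioSeg` implements both the baseline fully automated BB-only pipeline
and the modified pipeline in which the ZTE bone mask *drives* segmentation
of the high-resolution volume (BB or, equivalently, a routine FIESTA-C
acquisition): ZTE says **where** bone is; the high-resolution contrast says
**exactly which voxels** are bone there.

## The pipelines

Both pipelines share a preprocessing front end, applied per volume:

1. **Denoising** — level-set curvature flow (`u_t = kappa |grad u|`,
   explicit Euler, `dt = 0.1` in voxel units). Default 3 iterations:
   enough to cut homogeneous-region noise by more than half, while moving
   coherent edges by far less than a voxel. More aggressive smoothing
   measurably erodes the 1–2 mm orbital and vertex bone shell, which is
   exactly the structure the method needs to keep. A Gaussian smoother and
   `none` are selectable.
2. **Provisional normalisation** — a single linear scale mapping the
   Otsu-foreground median to 1000. (No offset: MR intensities are
   arbitrary-scale, not arbitrary-offset.)
3. **Head mask** — Otsu threshold, 2 mm morphological closing, largest
   connected component, hole filling. The filled mask deliberately includes
   internal air (sinus, oropharynx): those cavities are *inside* the head.
4. **Bias-field correction** — a smooth multiplicative shading field is
   estimated in the log domain as an iteratively reweighted (Tukey
   bisquare) quadratic polynomial of world coordinates over the head mask.
   The robust weights let the dark bone/air tail fall out as outliers, so
   the fit captures coil shading, not anatomy. The fitted log-field is
   centred (mean zero over the mask), exponentiated, clamped to
   `[0.2, 5]`, and divided out. On simulated log-linear shading up to 30 %
   amplitude the field is recovered with RMS log-error below 0.005 — an
   order of magnitude inside the 0.05 requirement — and on bias-free data
   the estimated field stays within 5 % of unity.
5. **Skin removal** — the head mask is eroded by a physical-space ball of
   `skinThicknessMm` (default 3 mm), removing the scalp so surface voxels
   cannot enter the bone classification.
6. **Exact re-normalisation** — the corrected volume is rescaled so the
   median over the skin-removed interior is exactly 1000. Every later
   threshold is expressed against this pinned scale.

The ordering follows the stage list of the published method; since that
list leaves the interplay of normalisation and bias correction open, the
package normalises provisionally before the head mask (so Otsu sees a
stable scale) and exactly afterwards.

**BB-only segmentation** then classifies candidates as voxels darker than
`bbBoneThreshold` (default 0.35) times the soft-tissue reference inside the
interior, and keeps all connected components of at least
`minComponentVoxels` (default 100) — the facial skeleton need not be singly
connected at mask resolution, so keeping only the largest component would
drop the mandible or ossicles. By construction this mask conflates bone
with internal air; the package asserts that failure mode in its tests
rather than hiding it.

**ZTE-driven segmentation** adds:

* **ZTE bone mask.** On the negative-log scale `x = -ln(I/1000)`, soft
  tissue sits near 0, air far above, and bone in a band
  `[zteBoneLow, zteBoneHigh]` (defaults 0.15 and 1.5, set so the phantom's
  three noiseless levels separate exactly; both are config-exposed since
  no published values exist). The mask is restricted to the head and
  cleaned by component size. An **air guard** (`zteAirGuardMm`, default
  2 mm) removes any voxel within 2 mm of clearly-air voxels
  (`x > zteBoneHigh`): denoising produces a partial-volume rim around air
  cavities whose intensities pass through the bone band, and without the
  guard that rim would re-admit cavity air into the search region. The
  guard is the operational form of ZTE's defining property — air is
  identifiable — and costs nothing at bone/soft interfaces, which have no
  adjacent air.
* **Grid transfer.** The ZTE mask is brought onto the high-resolution grid
  by nearest-neighbour resampling (masks must stay binary), by default
  through header geometry alone. Optional rigid registration
  (`registrationEnabled`) estimates the 6-parameter inter-acquisition
  motion by normalised mutual information (the two volumes have different
  contrasts), with Parzen-smoothed joint histograms, centre-of-mass
  initialisation, and a 6 / 3 / 1.5 mm multiresolution Nelder-Mead
  schedule. Registration is off by default to reproduce the published
  processing path; it recovers simulated motions of up to 5 mm / 5
  degrees to better than 0.5 mm / 0.5 degrees when enabled.
* **Search region.** The transferred mask is dilated by `searchDilationMm`
  (default 3 mm, about twice the ZTE z-spacing, absorbing resampling
  quantisation). Dark candidates are accepted as bone only inside it, so
  oropharynx air, tendons and muscle attachments far from real bone are
  excluded; recall of true bone grows monotonically with this dilation.
* **Render volume.** The output is deliberately not a binary mask: the
  windowed intensities (window `[0, 1500]` mapped to `[0, 32767]`) are
  inverted (`32767 - v`, so dark bone renders bright) and masked by the
  bone mask dilated by one voxel. The one-voxel halo keeps the cortical
  surface gradient, so an end user can still tune the rendering transfer
  function with their own anatomical judgement.

## The digital head phantom

No volunteer data accompany the method, so the package ships a parametric
multi-contrast head phantom that poses every failure mode the pipelines
are claimed to handle:

* ellipsoidal head (semi-axes 26 × 32 × 28 mm — a compact, roughly
  half-scale head, the package's chosen problem size; all voxel spacings
  are the real acquisition spacings: ZTE 0.9 × 0.9 × 1.6 mm, BB
  0.5 × 0.5 × 1.2 mm, FIESTA-C 0.4 × 0.4 × 0.7 mm),
* a closed 3 mm skull shell with 2 mm (or 1 mm in the `thin_bone` spec)
  patches at the orbits and vertex,
* a 3.5 mm scalp layer,
* a small frontal sinus carved so it shares a wall with the inner table,
  and a much larger oropharynx embedded in soft tissue (their ~1:15 volume
  ratio mirrors real frontal-sinus vs airway volumes),
* tendon/muscle confounders near the mandible and nose whose BB intensity
  (300) sits below the bone threshold but whose ZTE intensity is
  soft-tissue-like,
* per-modality intensity triplets (air 0.05, bone 0.5, soft 1.0 of the
  soft-tissue level; the ZTE bone/soft ratio is a modelling choice, as no
  quantitative ratio is published), Rician noise (magnitude of complex
  Gaussian; default sigma 5 % of soft tissue, SNR 20), a log-linear
  multiplicative bias field (default amplitude 15 %), and an optional
  2 mm / 1 degree inter-acquisition motion of the ZTE volume.

Labels are rasterised once at 0.4 mm isotropic (the finest acquisition
spacing, so no modality grid is under-resolved) and *nearest*-resampled to
each acquisition grid before noise and bias are applied. Nearest sampling
keeps tissue levels piecewise constant, which is what makes the exact
threshold-separability tests meaningful. What the phantom therefore does
**not** emulate: partial-volume mixing at tissue interfaces, k-space
artefacts, bone-marrow signal, pulsation, or anatomical shape realism.
Passing on the phantom demonstrates the mechanisms (air/bone separation,
confounder removal, resolution inheritance), not clinical-grade accuracy.

## Numerical choices

* Coordinates are LPS millimetres (DICOM convention, since input may be a
  DICOM series); NIfTI IO converts to/from RAS on the way through.
* Interpolation: linear for intensities, nearest for masks.
* Morphology uses physical-radius balls (a 2 mm radius spans different
  voxel extents on the anisotropic BB grid), implemented exactly through
  the Euclidean distance transform; component tie-breaks go to the lowest
  linear index.
* Connected-component cleanup keeps *all* components above
  `minComponentVoxels` rather than the single largest.
* Mesh export triangulates the voxel-boundary surface of the mask in
  physical coordinates with welded vertices and outward windings — a
  watertight, exactly reproducible surface. Marching cubes would yield a
  smoother surface at the cost of a far larger implementation; smoothing,
  when wanted, is available explicitly as Laplacian iterations and is off
  by default because smoothing trades geometric accuracy for aesthetics.
* DICOM export writes explicit-VR little-endian secondary-capture series
  with content-derived UIDs (deterministic reruns produce byte-identical
  series) and a full-range rescale: slope and intercept map the volume
  range onto `[0, 32767]`, so recovery is exact to one quantisation step.
* Degenerate inputs fail loudly: absent orientation metadata, empty
  threshold results, erosions that annihilate the mask, non-positive
  normalisation medians and mixed DICOM series are all hard errors.

## Known limitations

* Cavity air within `searchDilationMm` of real bone — a thin rim over the
  sinus walls — remains classified as bone. This is the published method's
  own residual behaviour and is asserted by a characterisation test, not
  patched.
* Teeth/occlusal-plane leakage is not specially handled.
* The phantom's ellipsoidal geometry cannot exercise sutures, foramina or
  trabecular texture.
* Registration assumes rigid inter-acquisition motion; deformable motion
  is out of scope.

## Problem sizes used by the test-suite and acceptance script

All suites run on the compact phantom: master label grid about
160 × 190 × 170 voxels, BB grid 128 × 152 × 57, ZTE grid 72 × 85 × 43,
FIESTA-C grid 160 × 190 × 98. A full ZTE-driven segmentation of the BB
phantom takes on the order of 15 s on one CPU; the acceptance script
regenerates every phantom and re-runs every pipeline from scratch.
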