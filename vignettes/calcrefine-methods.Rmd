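---
title: "Mask-guided inpainting refinement for microcalcification detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mask-guided inpainting refinement: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calcrefine)
```

## The model

Microcalcification detection is treated as pixel-level anomaly detection in
a 2D grayscale image on a 12-bit intensity scale (0–4095, DICOM-style
units). The method assumes:

* deposits are **hyperintense**: brighter than their local background;
* deposits are **sparse**: ground-truth pixels cover < 1.5 % of the breast
  region, so a candidate mask covering ~1 % of the breast still leaves
  ample calcification-free context around every candidate;
* an upstream **Stage-1** detector supplies a high-sensitivity candidate
  mask `M` — the method refines `M`, it does not find deposits on its own.

Stage 2 inpaints the image under `M`: the masked pixels are replaced by
virtual calcification-free values interpolated from the unmasked context,
and a candidate pixel is retained iff the original exceeds its virtual
value by more than a threshold τ (intensity units). Writing `Î` for the
virtual image,

```
R = { x ∈ M : I(x) − Î(x) > τ }.
```

Three structural facts follow directly from this definition and are
enforced as exact invariants throughout the test suite: `R ⊆ M` (the
refinement only removes pixels), `R` is antitone in τ, and the virtual
image equals the original outside `M` bit for bit.

Differences are clipped at zero before thresholding: under the
hyperintensity assumption only positive evidence (original brighter than
virtual) indicates calcium, and negative residuals are inpainting noise.

## Inpainting backends

The default backends are classical PDE fills on the masked set, with
boundary data from the unmasked pixels:

* **harmonic** — the discrete Laplace equation `Δu = 0` (5-point stencil;
  Neumann/mirror handling at image borders). Satisfies a discrete maximum
  principle: filled values stay within the range of the boundary values.
* **biharmonic** (default) — `Δ²u = 0`, the square of the same Laplacian.
  Smoother, matches gradients at the mask boundary, and therefore tracks
  tissue ramps across a masked blob better than the harmonic fill.

Both reproduce constant and affine images exactly (up to floating point),
which is what makes the refinement discriminative: a false-positive
candidate on locally smooth tissue inpaints back to itself, so its
difference falls below any reasonable τ.

The masked-pixel linear systems are solved by sparse direct factorisation
(`Matrix`), not an iterative scheme: the systems are symmetric positive
definite principal submatrices of the grid operator, the factorisation is
deterministic, and at the mask sizes this package targets (a few hundred to
a few thousand pixels per image) it is faster than iterating. The
`solver_tol` parameter (default 1e-6) is retained as a post-hoc residual
check; a residual above it raises an error rather than returning a silent
misfit. The grid operators depend only on the image shape and are cached
per shape for the lifetime of the session.

### The learned backend

The unsupervised training scheme — draw random box masks over
calcification-free patches and train the model to reproduce the masked
pixels — is implemented with a deliberately small model: a learned
8-neighbour diffusion kernel. Projected full-batch gradient descent fits
the eight neighbour weights to minimise masked-pixel reconstruction error;
after every step the weights are projected to the simplex (non-negative,
summing to one), so constants are reproduced exactly and the induced
linear system at inference is well posed. Inference solves
`(I − W) u = W x` on the masked set and composites the solution into the
mask only, so the outside-mask identity holds for this backend by
construction too. Training is seeded and deterministic; a model trained
for zero epochs is flagged untrained and refused by `inpaint()`. The
backend exists to exercise the training contract end to end, not to model
any particular network architecture.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `tau` | 50 | intensity units | The refinement's selling point is access to absolute contrast, so the threshold is absolute. 50 is well above the inpainting residual on textured tissue (texture sd 30 in the default phantoms) and well below the weakest object contrast the generator emits (150). |
| `patch_size` | 512 | px | Full-field images are processed as overlapping 512×512 patches. |
| `overlap` | 0.5 | fraction | Stride = `patch_size · (1 − overlap)`. Overlapping patches are merged by unweighted per-pixel averaging, and the refined mask is recomputed from the merged virtual image — *after* merging, not per patch — so stitching seams cannot create positives. |
| GBD sigmas | 1, 2, 4, 8 | px | Geometric ladder spanning the phantom object radii (1–3 px) with headroom; per-scale maps are min–max normalised then averaged so one threshold works across scales. |
| THT radii | 2, 4, 8, 16 | px | Same reasoning for the top-hat disk ladder. |
| `sp_threshold` | 0.3 | — | Binarisation threshold on the normalised multi-scale maps, shared by the SP detectors and SP refinements. |
| Stage-1 mock: `dilation_radius` | 2 | px | Over-segmentation halo of a high-sensitivity detector. |
| Stage-1 mock: `target_activation` | 0.012 | fraction | Calibrates the mock to the ~1.2 % breast activation profile typical of a high-sensitivity segmentation network. |
| `ring_width` | 5 | px | Width of the dilation ring used for exterior density. Ground-truth pixels are excluded from rings so adjacent objects do not contaminate each other's measurements. |

## The phantom generator

Each synthetic patient is one image (patient ↔ image): a half-ellipse
breast region anchored on the left edge, a textured background
(Gaussian-smoothed white noise, correlation length `texture_sigma` = 4 px,
sd `texture_amplitude` = 30 units, around `background_level` = 800), one
contiguous dense patch (15 % of the breast, +150 units) emulating locally
dense tissue, and 3–8 bright disk objects of radius 1–3 px (5–29 pixels,
i.e. the small-object regime) with contrast drawn uniformly from 150–600
units — a range whose centre matches the few-hundred-unit contrasts
typical of real deposits. Intensities are rounded to integers and clipped
to [0, 4095], so phantoms round-trip losslessly through 16-bit TIFF.
Objects are placed fully inside the breast with a 2-px moat between
objects; the generator enforces the < 1.5 % sparsity invariant and errors
out if a spec cannot satisfy it after bounded retries. Everything is a
deterministic function of the spec, including its seed; a global
experiment seed fans out to per-patient seeds through a fixed splitting
rule so any subset of a cohort reproduces independently.

**What the phantoms do not emulate:** anatomical structure (ducts,
vessels, Cooper's ligaments), the point-spread function and heteroscedastic
noise of real detectors, clustered calcification morphology, and
non-calcification bright structures (surgical clips, skin folds). Passing
tests on phantoms therefore demonstrates the *mechanism* of the refinement
— absolute-contrast evidence separates bright deposits from candidate
pixels on plain tissue — not clinical performance; on real mammograms the
inpainting residual on structured tissue is larger and τ trades
sensitivity against precision less cleanly.

### Interior/exterior density

"Interior" and "exterior" density needed an operational definition: here
`exterior_density` is the mean intensity over the morphological dilation
ring (width `ring_width`) around an object, excluding all ground-truth
pixels, and `interior_density` is the object's mean intensity minus that —
i.e. contrast above local surroundings. This is a stated convention of the
package. Objects are 4-connected components; a discrete disk of radius r
contains the pixels whose centre distance is ≤ r.

## Evaluation protocol

Pixel metrics are computed within the breast region only; predictions
outside it are ignored. Per image: sensitivity, PPV, Dice, activation rate
(predicted fraction of breast), true activation rate (ground-truth
fraction). Cohorts aggregate as unweighted mean ± sample sd over images; a
single-image cohort reports sd 0. Degenerate images: no ground truth ⇒
sensitivity undefined (dropped from that average); no predicted positives ⇒
PPV 0 when ground truth exists, undefined when the image has neither.

Method comparisons use the exact two-sided Wilcoxon signed-rank test on
per-image paired differences with zero differences dropped (all-zero ⇒
p = 1). The test statistic was an open choice — the protocol only demands a
paired significance test — and the signed-rank test is the standard
distribution-free choice for paired per-image metrics; when tied absolute
differences make the exact distribution unavailable the implementation
falls back to the usual normal approximation.

Patient-level analysis: a patient is detected if at least one ground-truth
object overlaps ≥ 1 predicted pixel. Conditional strata keep objects with
`size_px < 50`, and optionally `exterior_density ≥ 900` (high-surround) or
`interior_density ≤ 300` (low-contrast); patients with no remaining objects
are omitted, and the error rate is the fraction of retained patients with
no retained object detected.

Virtual-normal fidelity is reported separately over ground-truth normal
breast pixels and ground-truth abnormal pixels: RMSE; PSNR with peak 4095
(the declared 12-bit scale), capped at 99 dB as RMSE → 0; and the error
ratio, the percentage of region pixels whose absolute original-vs-virtual
difference strictly exceeds 1 unit ("exceeds" is read strictly, so a
difference of exactly 1 is not an error).

## Numerical choices and degenerate inputs

* Min–max normalisation treats a response map whose dynamic range is below
  1e-8 intensity units as zero, so constant images yield empty detections
  instead of amplified floating-point residue.
* `binarize` uses a strict `>`, so ties break negative and threshold 1
  always gives an empty mask.
* Gaussian blur is implemented as banded 1D convolution matrices with
  symmetric (mirror) boundary handling, applied as `K_r X K_cᵀ`; the
  reflection iterates, so kernels wider than the image fold back
  correctly. Grayscale morphology runs on reflectively padded images wide
  enough for both passes of the opening.
* `sample_boxes` draws box positions on the box-aligned tiling grid
  (uniformly, with replacement) rather than at arbitrary offsets: the
  coverage = 1 contract (full tiling) is then reachable in finite time,
  and the overshoot above the coverage target is bounded by one box.
* The baseline generative mode inpaints each tile of a disjoint box tiling
  with the rest of the image as context and accumulates the per-box
  difference maps; it shares τ and the backend with the mask-guided
  refinement so the comparison isolates the masking strategy.
* Coordinates are 1-based (row, col) everywhere, matching R's matrix
  indexing; the object CSV uses the same convention.
* A full-field patch whose Stage-1 sub-mask is empty (or covers the whole
  patch, leaving no context) passes through unchanged.

## Problem sizes

The package's own experiments — the test suite and the acceptance script —
use 20-patient cohorts of 256×256 phantoms for the end-to-end comparison,
a 600×600 phantom for full-field stitching checks, and 24–96 px images for
unit-level properties. These sizes were chosen so that a complete
experiment is a sub-minute, single-CPU affair while every mechanism
(multi-patch stitching, per-patient seeding, all seven method arms) is
still exercised at realistic sparsity.

## Known limitations

* PDE inpainting reproduces smooth tissue, not texture: inside large masks
  (the baseline generative mode's boxes) the fill is smoother than real
  tissue, which is precisely why exhaustive masking produces false
  positives. A stronger generative model would narrow that gap but not
  change the refinement's structural guarantees.
* The Stage-1 mock derives from ground truth; it calibrates sensitivity
  and activation by construction but cannot reproduce the error
  *structure* of a trained segmenter (correlated false positives along
  bright linear structures, missed low-contrast deposits).
* τ is global per image; spatially adaptive thresholds (e.g. scaled by
  local inpainting residual) are out of scope.
* Patient-level analysis treats one image as one patient; multi-view
  fusion is out of scope.
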