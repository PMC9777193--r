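---
title: "Training-free corneal ulcer segmentation: model, parameters, and validation design"
author: "ulcerseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Training-free corneal ulcer segmentation: model, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4.5)
library(ulcerseg)
```

## The problem

Corneal ulcers are epithelial defects that take up fluorescein dye and
fluoresce green under cobalt-blue slit-lamp illumination. Grading them
requires localizing the stained region on an ocular-surface photograph. This
package implements a fully automated, training-free segmentation pipeline for
such photographs: it needs no labeled data, every step is a classical image
operation, and the only learned quantity is a per-image threshold. The
pipeline is deliberately simple to audit: each stage produces a binary mask
that can be inspected on its own.

## The pipeline

Given an RGB image with intensities in $[0,1]$:

1. **Specular-reflection masking.** The blue channel is squared and
   binarized (Otsu by default). Saturated highlights from the tear film and
   the light source dominate the bright tail of the squared blue channel
   under cobalt-blue light. The binarized highlight mask is closed with a
   disk (radius 5 px) and complemented, giving a keep-mask that is FALSE
   over reflections.
2. **Green-channel cleanup.** The green channel (the fluorescein signal) is
   smoothed with a Gaussian ($\sigma = 2$ px), multiplied by the keep-mask,
   squared and binarized. Squaring before thresholding spreads the bright
   fluorescein responses away from the dimmer background and moves the Otsu
   split toward the bright mode.
3. **Elliptical pre-mask and thinning.** The centroid and second moments of
   the binarized green image define an axis-aligned ellipse, inflated by
   1.15, that discards far-field clutter. The closed, pre-masked binary
   image is thinned (Zhang–Suen) to a 1-px skeleton — the edge evidence for
   border recognition.
4. **Eye-border recognition.** The eye aperture outline is modeled by the
   Gielis Superformula
   $$ r(\varphi) = \left[\,\left|\cos(m\varphi/4)/a\right|^{n_2} +
      \left|\sin(m\varphi/4)/b\right|^{n_3}\,\right]^{-1/n_1}, $$
   with $n_1=n_2=n_3=1$, $m=2$, $a=b=1$: a lens shape with sharp lateral
   corners, like a palpebral aperture. Anisotropy is carried by per-axis
   pixel scales, so the dimensionless curve stays fixed while the search
   varies the semi-axes. A generalized Hough transform scores each
   (center, semi-axes, rotation) pose by the fraction of template points
   with edge support within ±1 px; the global accumulator maximum is the
   recognized border. A stride-1 center refinement with half-grid-step
   scale perturbations sharpens the coarse peak.
5. **Cornea disk and candidates.** A disk centered on the recognized border
   represents the cornea. The raw green channel restricted to the disk and
   the reflection keep-mask is squared and binarized over the disk support,
   yielding candidate ulcer segments.
6. **Eyelid-stain rejection.** Fluorescein also pools along the eyelid
   margins. A candidate component is rejected iff it touches the rendered
   border (within 2 px) *and* its moment axis ratio exceeds 3 — the
   signature of a stain strip along the lid rather than a compact ulcer.
   Whatever survives, clipped to the cornea disk, is the ulcer mask.

A healthy eye legitimately produces an empty mask; that outcome is a
success, not an error.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `gaussian_sigma` | 2 | px | suppress sensor noise without erasing point ulcers |
| `closing_radius` | 5 | px | specular highlights are compact blobs |
| `threshold_method` | otsu | — | parameter-free on bimodal fluorescein images; `fixed` override available |
| `ellipse_dilation_factor` | 1.15 | — | pre-mask must not clip the true border |
| `max_reflection_fraction` | 0.25 | — | a "reflection" split covering a quarter of the frame is the illuminated eye, not a highlight |
| `hough$scale_steps` | 12 | — | semi-axis grids over 0.25–0.75 of each half-dimension |
| `hough$center_stride` | 2 | px | coarse center grid; refinement pass runs at stride 1 |
| `hough$rotation_range` | ±10° | rad | slit-lamp eyes are near-horizontal; `rotation_steps = 1` disables rotation |
| `hough$min_vote_fraction` | 0.15 | — | below this a fit is indistinguishable from clutter |
| `cornea$radius_mode` | semi_minor | — | see below |
| `extract$ratio_threshold` | 3 | — | elongation cutoff for lid-stain strips |
| `extract$border_dilation_px` | 2 | px | absorbs rasterization gaps in the contact test |
| `extract$min_contrast` | 0.10 | intensity | empty-cornea guard (below) |
| `extract$min_area` | 4 | px | despeckle candidates before analysis |

All of these live in `seg_control()` and can be set from a YAML file via
`read_config()`.

## Design choices that were genuinely open

**Cornea disk radius.** The construction rule ties the disk to the
recognized border's semi-minor axis. Read literally, the disk *diameter*
equals the semi-minor axis; `cornea_disk_from_fit()` defaults to that
literal rule. The full pipeline, however, defaults to
`radius_mode = "semi_minor"` (radius equal to the semi-minor axis): in a
typical slit-lamp framing the iris spans essentially the whole vertical
palpebral aperture, and only a disk that reaches the border lets lid-margin
stain strips enter the candidate set where the rejection rule can see them.
Both behaviors are one config switch apart.

**Wiring of the ellipse pre-mask.** The pre-mask is derived from the
binarized green image and applied to its morphological closing before
thinning. Applying it instead to the reflection keep-mask would produce a
filled ellipse whose skeleton carries no border information, so that wiring
cannot feed the recognizer.

**Hough vote semantics.** A pose's score counts *template points with edge
support* (each template offset votes for a center cell at most once,
however many edge pixels are nearby), bounded by the template size.
Counting raw (edge, offset) pairs instead double-counts dense edges and
lets wrong poses outscore the true one. Ties are broken deterministically:
lowest row, then lowest column, then the earlier (smaller) scale/rotation
cell in iteration order.

**Guards around Otsu.** Otsu's method always splits its input, which has
two failure modes here. On a reflection-free frame the squared-blue split
lands between eye and background, flagging the whole eye as "reflection";
since true highlights are compact, a split covering more than
`max_reflection_fraction` of the frame is rejected and the image treated as
reflection-free. On a fluorescein-free cornea the candidate threshold would
binarize sensor noise; if the mean foreground-minus-background intensity
over the cornea support is below `min_contrast`, the candidate mask is
declared empty. Components under `min_area` pixels are discarded as specks.

## The synthetic scene generator

Real labeled slit-lamp data cannot ship with the package, so every stage is
validated on seeded synthetic scenes (`generate_scene()`,
`generate_suite()`) that emulate the salient structure of fluorescein
photographs: a dark background; a lens-shaped (Gielis, default parameters)
eye aperture; a blue-dominant sclera field; a darker iris/cornea disk
spanning the aperture height; a green tear-film meniscus strip (6 px,
green 0.75) along the whole lid margin — the physically ubiquitous
fluorescein tear strip, and the border evidence the thinning stage
extracts; bright-green ulcer blobs inside the cornea rendered as plateaus
with a 2 px cosine edge ramp, ground truth at the half-peak level set;
saturated white highlight disks on the sclera; optionally an elongated
high-green lid-stain arc hugging the border; additive Gaussian noise
(σ = 0.01 / 0.02 / 0.05 for easy / medium / hard suites). Scene geometry is
sampled once per suite: 240×320 px frames, semi-axes 85–115 × 50–70 px,
center jitter ±8 px. About 10% of suite scenes are healthy negative
controls. Every scene ships its full ground truth (border pose, cornea,
ulcer, reflection and lid-stain masks) and is bit-reproducible from its
seed.

What the generator does *not* model — photometric vignetting, eyelashes,
motion blur, uneven illumination, camera optics, the wide morphological
variety of point-flaky ulcers — bounds what passing tests can show: they
demonstrate that the pipeline's stages implement their contracts and that
the method recovers its own study conditions, not that it attains any
particular accuracy on clinical photographs.

Scene colors were fixed from channel-statistics reasoning (which Otsu split
must win at each stage), with the tear strip's blue held at sclera level so
the squared-blue threshold isolates only saturated highlights.

## Numerical choices

* Images are plain base-R arrays, `(row, col)` indexed, intensities in
  $[0,1]$; 8-bit inputs are divided by 255 on read.
* Otsu thresholds use 256 histogram bins; on a degenerate plateau any point
  of the plateau yields the same mask.
* Moment semi-axes are twice the standard deviation along the principal
  axes (exact for a filled ellipse); the minor axis is floored at 0.5 px so
  1-px-wide segments have a finite axis ratio.
* Template rasterization rounds curve samples to integer offsets and
  deduplicates; the ±1 px vote band stands in for unit-thickness
  rasterization.
* Filling a fitted border exploits that the default Gielis curves are
  star-shaped about their center: a pixel is inside iff its unit-frame
  radius does not exceed $r(\varphi)$.
* Degenerate inputs are handled explicitly: constant channels warn and
  return neutral masks, an empty binarized green image is a
  "no fluorescein response" error, sub-5-px cornea disks are rejected, and
  each stage error carries its stage name.

## Problem sizes used in validation

The test-suite and the acceptance script validate at desk scale, chosen so
the whole suite runs in minutes on one CPU: dense-grid Superformula checks
(20 001 angles), accumulator-vs-oracle equivalence on 50×50 edge images
with 3×3 coarse scale grids, 20-scene noiseless pose-recovery studies (with
a 500-noise-pixel robustness variant), a 50-scene easy suite for
end-to-end Dice and healthy-eye false positives, 12–16 medium scenes for
lid-stain rejection, and 200 random mask pairs for the metric identities.

## Evaluation conventions

`evaluate_batch()` reports accuracy, specificity, sensitivity, Jaccard/IoU
and Dice per image plus two aggregate rows: metrics of the pooled confusion
counts and the mean of per-image metrics. Both are emitted because the two
conventions genuinely differ whenever image sizes or prevalences vary.
Undefined ratios (e.g. sensitivity on a healthy image) are reported as
missing, never as zero, so negative controls do not silently drag the
aggregates.

## Worked example

```{r example}
scene <- generate_scene(scene_params(
  ulcer_blobs = list(list(center = c(115, 150), semi_axes = c(14, 16),
                          peak = 0.85)),
  seed = 1))
seg <- segment_ulcer(scene$image)
seg
compute_metrics(confusion(seg$ulcer_mask, scene$truth_ulcer))
```

```{r plot}
plot(seg, main = "recognized border (yellow) and ulcer outline (red)")
```

## Known limitations

* One eye per image; the single global accumulator maximum is taken.
* The recognizer needs border evidence in the binarized green image; on
  images whose lid margins carry no fluorescein signal the fit degrades.
* The recovered semi-axes inherit a small inward bias (the skeleton of a
  detected border strip lies a few pixels inside the anatomical border);
  at the default scale grid this stays within one grid step.
* The eyelid rule cannot distinguish a genuinely elongated ulcer touching
  the border from lid stain; such a lesion would be rejected.
* Runtime is dominated by Hough voting (about a second per 240×320 frame
  at the default 12×12×5 search grid on one CPU).
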