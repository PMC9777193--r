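# ulcerseg

Training-free segmentation of corneal ulcers in fluorescein-stained
slit-lamp photographs.

Corneal ulcers take up fluorescein dye and fluoresce green under
cobalt-blue illumination; localizing the stained region is the first step
of grading ocular surface damage. `ulcerseg` implements a fully automated
classical pipeline for that task — no training data, no learned weights —
aimed at ophthalmic image-analysis work where auditability and
reproducibility matter more than squeezing out the last point of Dice.

## Method

For an RGB image with intensities in [0, 1]:

1. **Specular reflections** are masked from the blue channel: square,
   binarize (Otsu), close with a 5 px disk, complement.
2. The **green channel** (the fluorescein signal) is Gaussian-smoothed
   (σ = 2 px), multiplied by the reflection mask, squared and binarized;
   an axis-aligned moment **ellipse pre-mask** (×1.15) discards far-field
   clutter and the result is **thinned** to a 1 px skeleton.
3. The **eye border** is recognized by a generalized Hough transform over
   templates of the Gielis Superformula

   r(φ) = [ |cos(mφ/4)/a|^n2 + |sin(mφ/4)/b|^n3 ]^(−1/n1),

   with n1 = n2 = n3 = 1, m = 2 (a lens shape with sharp lateral corners).
   Edge pixels vote for candidate centers over a grid of per-axis scales
   and small rotations; the score of a pose is the fraction of template
   points with edge support within ±1 px.
4. A **cornea disk** tied to the recognized semi-minor axis restricts the
   search; the green channel inside it is squared and binarized into
   candidate segments.
5. **Eyelid stain rejection**: a candidate touching the rendered border
   whose moment semi-major/semi-minor ratio exceeds 3 is an accumulation
   of fluorescein along the lid margin and is excluded (and recorded).

Pixel-level evaluation (accuracy, specificity, sensitivity, Jaccard/IoU,
Dice) and batch reports are included, as is a seeded synthetic
fluorescein-eye generator with exhaustive ground truth so the whole
pipeline is testable without any external dataset.

## Worked example

```r
library(ulcerseg)

scene <- generate_scene(scene_params(
  ulcer_blobs = list(list(center = c(115, 150), semi_axes = c(14, 16),
                          peak = 0.85)),
  seed = 1))
seg <- segment_ulcer(scene$image)
seg
#> Corneal ulcer segmentation (240 x 320 image)
#> Eye border fit: center (120.0, 160.0), semi-axes 57.3 x 94.5 px, rotation 0.0 deg, vote fraction 0.97
#>   cornea disk: radius 57.3 px (semi_minor)
#>   ulcer pixels: 667 (6.47% of cornea); segments kept 1, rejected 2

compute_metrics(confusion(seg$ulcer_mask, scene$truth_ulcer))
#> accuracy 0.9996 | specificity 1.0000 | sensitivity 0.9570 | IoU 0.9570 | Dice 0.9780
```

The scene is a synthetic 240×320 fluorescein photograph with one elliptical
ulcer (ground-truth semi-axes 14×16 px). The recognized border center
(120, 160) matches the generated eye exactly; the two rejected segments are
the lid-margin tear-strip slivers that enter the cornea disk at the top and
bottom and are correctly discarded by the border-contact × elongation rule.
The final mask overlaps the ground truth at Dice 0.978. `plot(seg)` draws
the image with the fitted border and the ulcer outline;
`summary(seg)` lists every candidate segment with its features.

Batch use, from R (`run_segment()`, `run_evaluate()`, `run_synth()`) or the
shell:

```sh
Rscript inst/cli/ulcerseg synth   --n 20 --difficulty medium --seed 0 --out scenes/
Rscript inst/cli/ulcerseg segment --input scenes/images --truth scenes/truth --out out/
Rscript inst/cli/ulcerseg evaluate --pred out/ --truth scenes/truth --out report/
```

Masks are 0/255 single-channel PNG; reports are CSV and JSON, with
aggregates under both the pooled-counts and mean-of-images conventions.

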