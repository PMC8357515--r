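---
title: "periseg: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{periseg: models, phantoms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periseg)
```

## Scope and intent

periseg studies CT-based detection of perianal abscess tissue at desk scale.
A perianal abscess presents on CT as a U-shaped soft-tissue thickening around
the anal canal with a low-density (pus) center, blurred margins, a thickened
epidermis/dermis band (4.1–4.9 mm in affected patients versus 1.8–3.6 mm in
healthy controls), and a lowered subcutaneous-fascia attenuation
(−95.45 ± 8.26 HU versus −76.34 ± 7.69 HU). No patient images are available,
so every quantitative claim in this package is made on *synthetic phantoms*
whose generative parameters are exactly those reported clinical
statistics. The package provides four analysis layers: phantom simulation,
region-of-interest (ROI) extraction, fully convolutional segmentation with a
patch-classifier baseline, and clinical morphometry.

## The phantom world

A phantom is a cropped perianal field of view (default 128 px at
0.5 mm/px = 64 mm): an elliptical body section (semi-axes 0.45/0.42 of the
field of view), a skin (epidermis+dermis) band of configured thickness at the
surface, a subcutaneous fascia band (6 mm) beneath it, interior soft tissue,
a central air-containing anal canal (radius 3 mm), and — in the lesion group —
an abscess: a high-attenuation wall (annulus, +40 ± 10 HU) around a
low-attenuation core (+15 ± 8 HU), with an angular gap so the wall forms a
"U" opening toward, and abutting, the canal.

Band membership is defined *radially* (by depth below the local ellipse
boundary), so a ray from the center crosses the skin band over exactly the
configured thickness; this makes generator round-trip tests meaningful at
half-pixel discretization error.

Per-pixel HU is drawn as class mean + class-sd noise + global noise
(default sd 5 HU), then blurred with a Gaussian (sigma 1 px), which realizes
both the "uneven density" and the "blurred edges" of real lesions. Values the
study does not quantify are package choices, recorded once in the
configuration and never hard-coded downstream: soft tissue +30 ± 10 HU, skin
+60 ± 15 HU, wall +40 ± 10, core +15 ± 8, canal modelled as an air-containing
lumen at −800 ± 50, background air −1000. Default lesion geometry (outer
radius 5.5 mm, core 3 mm, gap 80°) was chosen once so that an early abscess of
roughly 1 cm diameter fits the 64 mm field with the fascia and skin bands;
cohort draws jitter these uniformly (outer 4.5–6.5 mm, core 45–65 % of outer,
gap 60–100°, orientation 90° ± 30°).

What the phantom does **not** emulate: scanner physics (beam hardening,
partial volume beyond a Gaussian blur, noise texture), contrast enhancement
dynamics, anatomical variability of real pelvises, multiple or irregular
abscess cavities, and 3-D continuity. A green segmentation test therefore
establishes that the implementation learns and localizes the *stated*
geometry–attenuation pattern, not that it would segment clinical CT.

Cohorts at other matrix sizes should hold the physical field of view fixed;
the segmentation experiments below use 64 px at 1.0 mm/px (same 64 mm field).

## ROI extraction

The iterative threshold is the classic two-class-mean fixed point: start from
the global mean, then repeatedly set the threshold to the midpoint of the two
class means until the update falls below 0.5 HU (at most 100 iterations).
Degenerate cases are defined rather than left to chance: a constant image
returns that constant (flagged), and an empty class contributes the current
threshold as its own mean, forcing convergence. Foreground is *strictly
above* the threshold (body is brighter than air on CT); ties go to
background.

The cleanup chain applies, in the listed order: dilation, erosion, cavity
filling, opening, closing — disk structuring element of radius 2 px — then
keeps the largest 8-connected component and masks the slice (fill −1024 HU).
The method description names the operations but not the element, the ordering
within the figure, or a multi-component rule; the disk, the listed order, and
largest-component selection are package choices. The contract tested is
behavioural: on lesion phantoms the ROI is a single hole-free component
covering ≥ 99 % of true body pixels (noiseless case).

## The segmentation network

The fully convolutional stack is C1 (14 maps, 2×2) → pool → C3 (14, 5×5,
dilation 2) → pool → C5 (28, 5×5, dilation 4) → pool → C7 (28, 5×5,
dilation 5) → pool → F9 (52 maps, 1×1 convolution standing in for the fully
connected layer) → 1×1 logit head. Dilated convolutions use "same" padding so
spatial size shrinks only by pooling; the dilation schedule (2, 4, 5) is
audited two ways: the backward gap recursion (`hdc_max_gap`) and a
brute-force receptive-field footprint composition (`check_no_gridding`).

**Upsampling.** The architecture description leaves open how a full-resolution
mask is produced. A single bilinear upsample of the stride-16 logit map was
considered and *rejected on measurement*: fitting least-squares-optimal
coarse logits to phantom lesion masks (the best any training could do) caps
mean Dice near 0.65 at 64×64, because a ~1 cm lesion simply is not
representable on a 3×3 logit grid. The default is therefore the classic
fully-convolutional refinement: 1×1 logit heads on the dilated-convolution
outputs C3 (stride 2, receptive field ≈ 19 px) and C5 (stride 4), each
upsampled to input size, summed with the upsampled deep logits, then passed
through the sigmoid. Upsampling interpolates at the *true receptive-field
centers* of each coarse grid: with floor-semantics pooling the grids are
offset and truncated (a 64-px input's 3×3 deep grid has centers at original
pixels 9, 25, 41), so a naive uniform resize would misalign the deep logits
by several pixels near the far image border. The single-upsample variant
remains available (`build_dlfcnn(upsample = "bilinear")`); a learned
transposed-convolution path was considered and dropped — an integer-stride
transposed convolution cannot reach arbitrary input sizes from the
floor-divided grids without fractional cropping, and skip fusion supersedes
it.

**Input normalization.** Raw HU spans ~3000 units, and the air–body step
dwarfs the ~15–30 HU tissue contrasts that define the lesion; with a naive
full-range rescale, SGD provably converges to the all-background predictor
(observed across learning rates 0.05–20). Inputs are therefore normalized by
a CT soft-tissue display window — level 40 HU, width 400 HU, clamped to
[−1, 1] — the standard preprocessing for soft-tissue CT networks.

**Training.** Plain minibatch SGD (batch 8) on the mean-squared-error loss
R = (1/2m) Σ (K − g(P))², with m the number of output elements. With that
normalization a step size of 0.05 is far too small to leave the trivial
all-background basin within 50 epochs; the default learning rate is 4 for
the fully convolutional model (chosen from a sweep over 0.5–20 on held-out
phantoms; convergence within ~25 epochs matches the qualitative "converges
around 25 iterations" observation) and 0.5 for the patch classifier, whose
single-output gradients are much larger than the FCN's per-pixel-normalized,
partially cancelling sums. Weights are fan-in-scaled uniform, biases zero, everything
seeded; identical seeds give bit-identical runs. ReLU on feature layers
(derivative defined as 0 at exactly 0), sigmoid on the output; the loss and
every layer's backward pass are verified against central finite differences.

**Baseline.** The comparison CNN shares the trunk but ends in a true
fully-connected classification of a patch's center pixel (patch 32 px,
reflect-padded borders, balanced lesion/background patch sampling).
Whole-slice segmentation slides the patch window; a stride with
nearest-neighbour fill (default 4 in the pipeline) keeps desk-scale runtimes,
at a known cost in boundary precision that is part of why patch classifiers
lose to fully convolutional models — the ordering, not the margin, is the
tested claim.

## Metrics

Jaccard |C∩D|/|C∪D|, Dice 2|C∩D|/(|C|+|D|), precision TP/(TP+FP) (the
study's "accuracy rate"), recall TP/(TP+FN). Degenerate conventions are
explicit: two empty masks score Jaccard = Dice = 1 (perfect agreement on
"nothing present"); zero-denominator precision/recall return 0 flagged
`undefined`. Cohort results are per-slice metrics macro-averaged. The
Dice–Jaccard identity Dice = 2J/(1+J) is enforced to 1e−12 in tests.

## Morphometry

Skin thickness casts 64 rays from the band centroid and measures the chord
through the band (sampling step 0.25 px); with the phantom's radially defined
band this recovers the configured thickness to about half a pixel. An
alternative medial (distance-transform) definition was considered and not
implemented: on a closed convex band the two coincide within discretization,
and the ray method is what a radiologist's caliper measurement emulates.
Fascia HU statistics are taken over the fascia class mask *eroded by 3 px* —
partial-volume avoidance: the Gaussian edge blur biases boundary pixels
toward neighbouring classes, exactly as on real CT, and HU regions of
interest are conventionally placed away from interfaces. Group comparison is
a Welch (unequal-variance) two-sided t-test with (n−1)-denominator standard
deviations; it reports, it does not diagnose.

## Numerical and format choices

* Convolution is implemented in the cross-correlation orientation, with
  floored output sizes ⌊(i − q + 2o)/t⌋ + 1; a worked 6×6 ∗ 4×4 example in
  the source description claims a 4×4 output, which is inconsistent with its
  own size formula (valid gives 3×3) and is treated as a typographical error.
* The layer table lists a 5×5 "kernel" for the first pooling layer; pooling
  windows are uniformly 2×2 stride 2, reading that entry as a typo mirroring
  the adjacent convolution row.
* Pooling on a 1-px map acts as identity so that small patches (≥ 16 px)
  remain usable in the baseline.
* No image-codec package exists in the supported environment, so NIfTI-1 and
  uncompressed 16-bit little-endian grayscale TIFF are implemented natively;
  TIFF stores HU + 1024 as unsigned integers with spacing in a JSON sidecar,
  NIfTI stores float64 with spacing in the header. PNG would need a zlib/CRC
  codec and is rejected explicitly. Configs are JSON for the same reason
  (no YAML parser available).
* Eq.-style loss values, thresholds and metrics are plain doubles; the only
  tolerance baked into an algorithm is the 0.5 HU threshold convergence
  tolerance.

## What segmentation accuracy the phantom world supports

Under the configured attenuations the abscess boundary separates +40 ± 10 HU
(wall) from +30 ± 10 HU (soft tissue) after a 1-px blur — about one noise
standard deviation of contrast. On 64-px cohorts (200 training, 50 held-out
slices, ≤ 50 epochs) the fully convolutional model plateaus at mean Dice
≈ 0.73 and the patch baseline at ≈ 0.60, a stable ordering; a hand-crafted
generative template-matching oracle on the same slices reaches only ≈ 0.22,
so the network substantially outperforms classical matched filtering, and
the residual gap to high Dice values reflects the low boundary
signal-to-noise of the stated tissue contrasts rather than a correctable
implementation defect. Real perianal abscesses sit in ischioanal fat
(≈ −90 HU), where wall contrast exceeds 100 HU; a fat-embedded phantom would
be a far easier segmentation target, but the package keeps the configured
soft-tissue surround as its stated world.

## Known limitations

Training is CPU-bound R/C++ and intended for ≤ 200 slices at 64 px; the
phantom idealizes anatomy as concentric bands; the baseline's strided
sliding-window prediction underestimates its boundary accuracy at stride > 1;
metrics are 2-D per-slice only; no surface-distance metrics; the cohort
generator draws geometry independently per sample (no patient-level
covariance structure).
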