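---
title: "Kidney volumetry from low-dose CT: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kidney volumetry from low-dose CT: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Kidney volume is a clinically useful quantity — renal swelling accompanies
acute obstruction, chronic disease shrinks the parenchyma — but measuring it
from CT is tedious: a radiologist outlines the organ on dozens of slices and
the software integrates the areas. Patients with suspected urolithiasis are
imaged with *low-dose, unenhanced* CT, where the kidney-to-fat contrast is
modest and the noise high, so most commercial segmentation tools do not
apply. `renalvol` implements a fully automated estimation pipeline for this
setting: per-side 2D U-Net segmentation of transverse slices, a slice-profile
heuristic that isolates the kidney region from the per-slice mask sizes, and
voxel-summation volumetry from the DICOM spacing metadata, together with the
statistics used to compare volume-estimation methods.

Because clinical CT cohorts cannot ship with a package, every stage is
exercised on synthetic phantoms whose kidney volumes are known in closed
form; the phantom generator is itself part of the tested surface.

## The segmentation model

Each transverse slice is split vertically into two halves, one per kidney
side, and an independent model is trained per side (this keeps the method
applicable to single-kidney patients and halves the spatial variability each
model must absorb). During training the halves overlap by 5% of the image
width at the center, which adds positional variance; at inference exact
halves are used. Half-images are min-max normalized to [0, 1] and resized to
the model input shape (512 x 256 for clinical data).

The network is an 18-conv-layer U-Net variant. The encoder has ten 3 x 3
convolutions (stride 1, ReLU) with channel schedule F, F, 2F, 2F, 4F, 4F,
8F, 8F, 16F, 16F and four 2 x 2 max-pools; batch normalization follows
convolutions 1, 3, 7 and 9, and a dropout layer follows convolution 5. The
decoder has four up-blocks — a 2 x 2 stride-2 transpose convolution carrying
the channel count of the preceding convolution, concatenation with the
matching encoder feature map, then 3 x 3 convolutions with halved channel
count, laid out (2, 2, 2, 1) — with dropout after the first decoder
convolution and batch normalization after the block-final convolutions of
blocks 1-3; a 1 x 1 sigmoid convolution produces the per-pixel foreground
probability. In total: 18 convolutions, 4 pools, 4 transpose convolutions,
7 batch normalizations, 2 dropouts — all auditable via `unet_audit()`.

The 3 x 3 convolutions are stride 1: stride-2 convolutions combined with
four stride-2 max-pools would collapse a 512 x 256 input past the five
resolution scales the feature schedule implies, so only the pools reduce
resolution. The batch-norm and dropout placement above is one consistent
arrangement of the fixed operation counts; the structural audit asserts the
counts themselves, which any consistent placement shares. The
transpose convolutions keep the channel count of the preceding convolution
rather than halving it as the classic U-Net does; a halving variant would
only change parameter counts, not the audit.

Training uses Adam on mean binary cross-entropy, an 80/20 train/validation
split, early stopping after 30 epochs without validation improvement (the
weights of the best validation epoch are kept), and a hard epoch cap
(default 500). Each training image is
augmented with probability 0.5 by exactly one of: optical (radial)
distortion, multiplicative noise, or Gaussian blur — geometric transforms
are applied to the mask as well (nearest-neighbour, so masks stay binary),
intensity transforms are not. Augmentation magnitudes default to a
distortion coefficient within ±0.15, noise multiplier 0.9-1.1 and blur
sigma 0.5-1.5 px — the usual ranges of augmentation libraries — and are
configurable.

The engine is written for this package: convolution forward/backward passes
run as im2col + BLAS matrix multiplies in single precision (the customary
CNN arithmetic) with compiled C++ kernels for the 3 x 3 convolution; batch
normalization, pooling, transpose convolution, dropout, Adam and the loss
are plain R. Backward passes are verified against central finite differences
in the test suite. Training with a fixed seed is bit-reproducible on CPU,
and inference is deterministic, which the repeated-volumetry test exercises.

## Hyperparameters and the genetic search

Four hyperparameters are searched: learning rate, dropout rate, starting
feature maps F, batch size. The genetic algorithm uses a population of 10,
rank selection keeping the fittest half, single-point crossover over the
4-gene vector (cut point uniform over the three positions), and per-gene
Gaussian mutation with probability 0.2, clipped to bounds; the single
fittest individual passes unchanged (elitism), so the best-ever fitness is
non-decreasing. The default budget is 25 generations. Fitness is the
negative best validation loss of a short training run on a fixed 25% subset
of the side dataset, so individuals are comparable.

Design choices within that scheme: mutation is applied per gene (applying
the 20% draw per individual instead is a plausible alternative reading;
per-gene is the common one); mutation standard deviation is 20% of the current value on the gene's native scale
(log10 for the learning rate), integer genes re-quantized to the nearest
allowed value; parent pairs are drawn uniformly with replacement from the
survivors; gene bounds (learning rate log-uniform on [1e-4, 0.3], dropout
[0, 0.5], F in {8, 16, 32, 64}, batch in {4, 8, 12, 16, 24}) bracket the
full-scale search optimum. That optimum — learning rate 0.15, batch 12,
F = 32, dropout 0.1 — ships as the default `hyperparameters()`; it is
carried as a recorded result of that full-scale setting, not re-derived at
desk scale. The package's GA is validated on an analytic surrogate fitness
centered on that optimum: over 20 seeds the median recovered coordinates
fall within 10% of it.

## Volumetry

The models segment *every* slice of a series. Spurious masks far from the
kidney do occur, so the per-slice pixel counts, ordered by table position,
are post-processed: counts below a floor (200 pixels) are interruptions, and
the kidney region is the longest uninterrupted run of slices at or above the
floor, ties broken toward the larger summed pixel count and then the earlier
table position — tie-breaks chosen to make the selection deterministic and
to favor the more kidney-like run. The volume is then

  volume = sum over the run of x_i * y_i * z_i * count_i,

with x_i, y_i the per-slice pixel spacings and z_i the distance between
subsequent slices, all taken from the DICOM headers — spacing is kept
per-slice because the formula's indices allow it. The 200-pixel floor is
meaningful on the ~0.7 mm clinical pixel grid (about 98 mm^2); on other
grids the equivalent area floor `min_area_mm2 = 98` should be used, and the
phantom pipeline does.

A reference estimator mirrors the radiologists' semi-automated workflow:
segmentation areas on slices 3 mm apart across the kidney extent, summed
times the interval. At an interval equal to the slice spacing it reduces
exactly to the voxel summation, which the tests assert.

## The phantom generator

A phantom is two ellipsoids of kidney-like attenuation (35 HU) embedded in a
fat background (-100 HU) with i.i.d. Gaussian noise, quantized to integer HU
as a scanner stores them (this also makes DICOM round trips exact). The
defaults emulate the acquisition the method targets: 512 x 512 matrices,
~0.75 mm pixels, 1 mm slice spacing, noise sigma 20 HU for the low-dose
setting (8 HU approximates a regular-dose scan). The attenuation and noise
values are stand-ins chosen to give the soft-tissue-in-fat contrast typical
of unenhanced CT; they are not calibrated to any particular scanner. Kidney semi-axes default to
realistic adult sizes (~120-160 ml per kidney). A voxel belongs to a kidney
iff its center is inside the ellipsoid; ground-truth masks are these exact
interiors, so the voxel-count volume converges to 4/3 pi a b c under grid
refinement (the acceptance suite measures the mean error over jittered
placements at 4, 2 and 1 mm and checks it decreases). Slices above and
below the kidneys are guaranteed kidney-free and serve as negative
controls. Phantom cohorts are sampled by jittering semi-axes and centers by
±15%, a spread chosen to mimic between-subject anatomical variability.

What the phantoms do *not* emulate: neighboring organs of similar
attenuation (liver, spleen, muscle), the renal pelvis and vessels, partial
volume, beam hardening, or scanner-specific noise texture. Passing the
scaled tests therefore demonstrates that the pipeline's machinery —
training, inference, post-processing, volumetry, statistics — is correct
and reproducible, not that the shipped defaults would reach clinical
accuracy on real scans; for that the models must be trained on real
annotated data at full scale.

## Scaled-down study conditions

The full-scale protocol (5,500+ training slices at 512 x 256, ~9 h on two
GPUs) is emulated at desk scale: 20 training phantoms on a 128 x 128 grid
(3 mm pixels, 4 mm slices), 128 x 64 model inputs, F = 8, positives sampled
every 10 mm with ~28% negative controls (the clinical datasets' ratio), and
an application set of 22 phantoms (10 in the fastest acceptance check). At
this scale the Adam learning rate 2e-3 with batch 8 and 12 epochs converges
reliably; the full-scale optimum (0.15) belongs to the full-scale setting
and is not meaningful here. These problem sizes are the package's default
`run_config()` and complete in minutes on one CPU.

## Statistics

Method agreement uses the two-way ANOVA single-rater ICC in both the
consistency form (MSR - MSE)/(MSR + MSE) and the absolute-agreement form
(MSR - MSE)/(MSR + MSE + (2/n)(MSC - MSE)), with 95% confidence intervals
from the standard F constructions (Satterthwaite degrees of freedom for the
absolute form) and the usual qualitative labels (poor < 0.5, moderate
0.5-0.75, good 0.76-0.9, excellent > 0.9). The implementation is checked
against an explicit double-loop ANOVA oracle to 1e-10. Bland-Altman limits
are mean ± 1.96 sd of the differences (B - A; a 2.0 multiplier is available
by argument). MAE is mean |B - A|; MdAPE is the median of |B - A|/A in
percent with the reference method as denominator (subjects with a zero
reference are excluded and counted). Dice of two empty masks is defined as
1 — perfect agreement on absence.

## Numerical and degenerate-input choices

* Constant images min-max-normalize to all zeros rather than NaN.
* Masks are always resized nearest-neighbour and never intensity-scaled.
* Probability-to-mask threshold is 0.5, the standard operating point.
* Max-pool ties route the gradient to the first window element.
* A single-slice series takes its inter-slice distance from the
  SpacingBetweenSlices tag or fails loudly.
* Non-uniform slice gaps warn and are kept per-gap.
* A profile with no slice at the floor yields volume 0 with a warning.
* Training aborts with a diagnostic on non-finite loss; the GA scores a
  failing fitness evaluation as worst and continues.

## Known limitations

The DICOM reader/writer covers exactly the single-frame, explicit-VR
little-endian CT subset this pipeline produces and consumes — not
compressed syntaxes, implicit VR, or sequences. The NIfTI path cannot
represent per-slice spacing. The CNN engine is CPU-only and sized for
desk-scale experiments; full-scale clinical training would use a GPU
framework. The statistics cover two methods/raters; multi-rater designs are
out of scope.
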