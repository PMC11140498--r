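---
title: "Semi-supervised lesion detection on synthetic head phantoms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised lesion detection on synthetic head phantoms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pixel-accurate lesion annotation of medical images is expensive: a labeled
training corpus is typically small and drawn from a single institution, while
clinically relevant deployment happens on scanners, protocols and populations
the model never saw. Semi-supervised self-training addresses both problems at
once: a *teacher* model trained on the small labeled set generates *pseudo
labels* on a large unlabeled corpus, and a *student* model — initialized from
the teacher and trained on the combination of real and pseudo labels under
aggressive input noise — generalizes better out of distribution than a model
trained on the labeled data alone.

`noisystudent` implements this workflow end to end at desk scale, on
synthetic head phantoms with known ground truth, together with the
model-comparison statistics needed to decide whether the student actually
beats the baseline: paired bootstrap distributions of metric differences,
a Kolmogorov–Smirnov normality check, Z-derived two-sided p-values,
percentile confidence intervals, and paired t-tests for test–retest designs.

## The synthetic study corpus

`make_study_corpus()` emulates a three-institution study:

* a **labeled** split (default 40 exams) and a **validation** split
  (20 exams) from institution "siteA";
* a large **unlabeled** split (100 exams = 400 images) from "siteB", whose
  reference masks are withheld from the public reading interface
  (`exam_masks()` errors; `private_reference()` exists only for the Oracle
  benchmarks and for evaluation);
* an **out-of-distribution test** split (60 exams) from "siteC".

Each exam is an ordered stack of 4 grayscale 64×64 images. An image is an
elliptical "head" of textured tissue on a dark background. Bright elliptical
lesions (radius 2–6 px, intensity offset 0.25 with a per-lesion conspicuity
factor drawn from U(0.5, 1.2), mimicking variable hemorrhage density) define
the per-pixel reference mask; the exam-level label is positive iff any pixel
of any image is a lesion. 30% of exams per split are positive, a rate in the
range reported for trauma head-CT cohorts.

Two properties make the task non-trivial and were chosen deliberately:

* **Distractors.** Small, *brighter* non-lesion foci (radius 1–2.2 px,
  offset 0.30, up to 3 per image in 70% of images) mimic calcifications and
  streak artifacts. They force the model to learn a joint size–intensity
  discrimination rather than simple thresholding, and they are the source of
  the false-positive pseudo labels that the ranker exists to suppress.
* **Faint lesions.** The per-lesion conspicuity factor makes some lesions
  genuinely subtle, so a model with a miscalibrated operating point misses
  them; without this, exam-level ranking saturates at AUC 1 under any
  realistic shift.

The domain shift of siteC relative to siteA is primarily a contrast-curve
shift (gamma 0.5 vs 1.0) — the axis of variation that the student's
power-law/log augmentation family explicitly covers — plus heavier noise
(SD 0.12 vs 0.04), darker tissue and a wider head-aspect jitter (0.7–1.3
vs 0.9–1.1). SiteB sits at a moderate shift (gamma 0.85, noise 0.07):
close enough to siteA that the teacher's top-ranked detections are real
lesions (so ranked pseudo labels are accurate), far enough that the
teacher also produces false-positive detections on distractors — exactly
the errors the ranker suppresses and the no-ranker ablation trains on.
The shift magnitudes are free parameters of the generator; the defaults
were set once so that a labeled-only baseline loses a clinically
meaningful amount of performance on siteC while the task stays learnable
in-domain, and the `validation` split is the place to tune anything
further.

What the phantoms do **not** emulate: 3D anatomy, skulls (the labeled-domain
role model had skull and scalp removed), Hounsfield calibration, spatially
correlated scanner noise, and lesion texture. Passing the end-to-end tests
therefore demonstrates that the *workflow* behaves as described under a
controlled, detectable domain shift — not that any particular clinical
performance would be reached on real CT data.

## The dual-branch patch network

The model follows the patch-based fully convolutional contract: it takes an
image patch and returns both a patch-level class probability and a per-pixel
probability map. At desk scale the backbone is deliberately small:

* two 3×3 same-padding convolution layers (8 channels, ReLU), giving a 5×5
  receptive field;
* a **segmentation head**: 1×1 convolution to a per-pixel logit, sigmoid;
* a **classification head**: log-sum-exp pooling of the segmentation logits
  with a learnable affine calibration, `w · LSE(z) + b`, sigmoid.

The LSE pooling is a smooth version of "does any pixel look positive?", so
the classification branch is exactly the patch-label definition (a patch is
positive iff it contains a positive pixel) expressed in logits. It also
stabilizes training: hard max pooling routes the whole classification
gradient into one pixel and at this parameter count that reliably destroyed
one branch or the other on some seeds; with LSE both heads shape the same
trunk coherently. Output heads are zero-initialized (an untrained model
predicts exactly 0.5 everywhere), conv weights use He initialization.

Training minimizes `masked pixel BCE + λ · classification BCE` (λ = 1) with
Adam (learning rate 0.015, global-norm gradient clipping at 5) on random
32×32 crops, batch 16. Half of the crops of lesion-bearing images are
centered near a random lesion pixel: at 64×64 with lesions of a few dozen
pixels, uniform crops almost never contain positive pixels and the
segmentation head would need thousands of steps to leave the all-negative
regime. The pixel loss is averaged over non-ignore pixels pooled across the
batch; a pixel in the IGNORE state contributes no loss term at all (tested
by direct recomputation under perturbation).

Inference tiles each image with a deterministic non-overlapping grid of
crop-size patches (edge tiles aligned to the border; overlaps averaged),
stitches the probability maps, and scores each image as
`max(classification probabilities, max pixel probability)` — the rule is a
configuration option (`image_prob_rule`) because the two branches can be
used alone. The exam score is the maximum over its images: the standard
any-positive-slice rule.

Defaults that matter, with rationale:

| parameter | default | why |
|---|---|---|
| `epochs × steps_per_epoch` | 24×30 for both stages | 720 steps make the teacher's probability maps confident enough for the 0.7/0.3 trinarization to produce non-empty positive masks; a half-trained teacher yields all-ignore pseudo labels and the workflow silently degenerates |
| `batch_size` | 16 | canonical minibatch size for this workflow |
| `crop_size` | 32 | half the image side, same ratio as 240-px crops on ~512-px CT |
| `mixing_ratio` | 0.6 | 0.6:0.4 labeled-to-pseudo mix per minibatch |
| `lr` | teacher 0.015, student 0.008 | 0.015 is the largest rate that trains stably from scratch across seeds (with clipping); the student starts from the teacher, and the lower rate makes its training a gentle fine-tune that adds robustness without destroying the teacher's exam ranking |
| `λ (lambda_cls)` | 1 | equal weighting of the two branches |

## Pseudo-labeling and the ranker

The teacher predicts every image of the unlabeled split. Images are pooled
across exams and ranked by predicted probability (stable descending sort);
exactly `floor(C/100 · N)` of them — the top `C` percent, default `C = 10`
from the canonical sweep {5, 10, 15, 20, 25, 30} — are declared
pseudo-positive. Pseudo-positive probability maps are *trinarized*: pixels
with confidence strictly above 0.7 become positive, strictly below 0.3
negative, and everything in between (boundaries included, because the
thresholds are strict inequalities) is IGNORE and generates no loss. All
remaining images are pseudo-negative with every pixel negative.

The ranker encodes the prior that most screening examinations are negative:
without it (the `use_ranker = FALSE` ablation), every image is trinarized
and the student trains on — and then reinforces — the teacher's
false-positive detections, which on these phantoms are mostly distractor
foci. A pseudo-positive image can end up with no positive pixel after
trinarization; patch labels are always derived from the mask, and the
inconsistency is logged rather than silently repaired.

The student is initialized from the teacher's weights and trained on mixed
minibatches (10 labeled + 6 pseudo samples of 16, i.e. `round(0.6·16)`)
under input noise: each sample's image is contrast-transformed by a
power-law (exponent U(0.5, 1.5)), a logarithmic correction
(`log2(1 + x)`, which maps the unit interval onto itself), or left
unchanged — one third probability each — and then head length and width are
independently rescaled by U(0.85, 1.15). Contrast augmentation touches the
image only; geometric augmentation transforms image and mask congruently
(pixel labels are geometric, not photometric; the mask uses
nearest-neighbor sampling so tri-state values survive). Augmentation is
student-only by default, per the noisy-student paradigm; the teacher and
the labeled-only baseline train without noise, and `augment` is an argument
wherever that choice should be revisited.

## Oracle benchmarks

Two benchmarks bracket the semi-supervised result using labels a true
semi-supervised setting would not have:

* **image-label Oracle** (`run_oracle_image`): unlabeled exams enter as
  whole-image patches supervised only through the classification loss by
  their true image labels; pixel loss stays active on the labeled split
  only (audited by a pixel-term counting hook in the training log).
* **pixel Oracle** (`run_oracle_pixel`): the student's pseudo masks are kept
  where the true image label is positive and overridden to all-negative
  where it is negative — perfect false-positive suppression, the upper
  bound of what the ranker approximates.

## Model comparison statistics

`compare_models()` implements the full comparison machinery for exam AUC
(exam units), pooled Dice and pixel AP (image units):

1. **Paired bootstrap**: each of `n_boot = 1000` replicates resamples unit
   indices with replacement and applies the *same* indices to both models;
   Δ = metric(B) − metric(A) per replicate. Pairing is required for the Δ
   distribution to measure a model difference rather than sampling noise.
   Replicates whose resampled references contain one class (AUC undefined)
   are redrawn and counted, not dropped.
2. **Normality check**: one-sample KS test of the standardized deltas
   against the standard normal, with mean and SD estimated from the sample.
   With estimated parameters the test is anti-conservative in the Lilliefors
   sense; it gates a warning only, never the analysis.
3. **Z test**: `Z = Δ_point / σ` where Δ_point is the difference on the
   full unresampled set (the conventional bootstrap-SE test; the mean
   bootstrap delta is also reported) and σ is the empirical SD of the
   deltas; two-sided p = 2·Φ(−|Z|). Degenerate conventions: σ = 0 with
   Δ = 0 gives p = 1; σ = 0 with Δ ≠ 0 gives p = 0 with a warning.
4. **95% CI**: 2.5th and 97.5th percentiles of the deltas (linear
   interpolation).

Pooled Dice treats all pixels of a resampled image set as one global
overlap (with the empty-vs-empty convention Dice = 1, which matters only
when a bootstrap set has no positive pixels); per-image averaging is
available via `dice()` directly. Pixel AP is the non-interpolated
precision-at-each-positive form. `specificity_at_sensitivity()` reports the
operating point at a target sensitivity (such as 0.920) by choosing the
highest threshold whose sensitivity still reaches the target.
`majority_vote()` fuses an odd number of repeated binary reads into a
reference label; `paired_ttest()` covers test–retest comparisons across
repeated reference segmentations.

## Numerical and design choices

* **Determinism.** Every stochastic stage (generation, initialization,
  sampling, augmentation, bootstrap) is seeded; identical configuration and
  seed reproduce bit-identical corpora, weights, predictions and deltas.
  Functions restore the caller's RNG state.
* **Ranker arithmetic.** `floor(C/100 · N)` selected images, stable sort for
  ties; `C = 10` on 400 pooled unlabeled images selects exactly 40. A `C`
  that selects zero images warns and returns an all-negative pseudo set.
* **Strict thresholds.** Probabilities exactly at 0.7 or 0.3 are IGNORE.
* **BCE clamping** at 1e−7; loss computations on logits use the numerically
  stable softplus form.
* **Degenerate inputs** error early and by name: single-class AUC input,
  mask shape mismatches, crops larger than images, empty pools, even-sized
  vote panels, zero-variance paired differences.
* **One teacher→student generation.** Iterated self-training is out of
  scope; the student's provenance records the teacher checkpoint id.
* **Problem sizes.** The default corpus (40/100/20/60 exams of 4 images,
  64×64) trains a teacher or student in under half a minute on one CPU
  (the convolution kernels are C++ im2col + BLAS); the five-seed
  directional experiment used by the end-to-end checks runs in well under
  fifteen minutes. These sizes are the package's chosen study conditions,
  scaled so that the full workflow is routinely re-runnable.

## Known limitations

* The backbone's 5×5 receptive field cannot use shape context beyond small
  neighborhoods; discrimination relies on local size/intensity cues, which
  is exactly what the distractor design probes, but real hemorrhage
  morphology is far richer.
* Exam scores derive from a maximum over images and patches, so a single
  confident false positive dominates an exam; smoother aggregation rules
  are deliberately not implemented (the any-positive-slice rule is the
  field's convention).
* The KS normality check uses estimated parameters (see above).
* With 60 OOD exams, exam-AUC differences between two good models are
  quantized (18 positives × 42 negatives = 756 pairs); seed-to-seed
  variability of single-seed comparisons is substantial, which is why the
  directional claims are evaluated over five seeds.
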