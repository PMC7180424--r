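---
title: "Methods: hierarchical whole-slide polyp classification in polypscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical whole-slide polyp classification in polypscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polypscope)
```

## The classification task and the model

Colorectal polyps excised at colonoscopy are diagnosed on
hematoxylin-and-eosin slides as one of four common types: tubular
adenoma (TA), tubulovillous/villous adenoma (TVA), hyperplastic polyp
(HP), or sessile serrated adenoma (SSA).  The distinction matters
clinically — TVA and SSA are the higher-risk lesions — and it is known
to be a low-agreement call even among expert gastrointestinal
pathologists.  polypscope implements a two-level procedure for making
this call automatically on a whole-slide image:

1. **Patch level.**  The slide is tiled by a sliding window of fixed
   224 × 224-pixel patches (non-overlapping by default) and every patch
   is classified by a convolutional network into five classes: the four
   polyp types plus normal tissue (`NORM`).
2. **Slide level.**  The patch votes are aggregated by a hierarchical
   heuristic that mirrors how a pathologist reasons.  The slide is first
   assigned to the *adenomatous* branch (TA/TVA) or the *serrated*
   branch (HP/SSA) by comparing the two branch patch counts.  Within the
   adenomatous branch the slide is called TVA when its villous fraction
   — the share of TVA patches among adenomatous patches — strictly
   exceeds a threshold $\theta_v$, and TA otherwise.  Within the
   serrated branch it is called SSA when the SSA patch fraction strictly
   exceeds $\theta_s$, and HP otherwise.  Normal patches are counted but
   never enter the fractions.

The reference operating point is $\theta_v = 0.30$ and
$\theta_s = 0.015$, both applied as strict `>`.  The asymmetry reflects
the biology: a diagnosis of TVA requires a substantial villous
component, while even a small area of sessile serrated crypts upgrades a
serrated polyp to SSA.  Both thresholds can be re-estimated for any
cohort with `calibrate_thresholds()`, a grid search over candidate pairs
maximizing (by default) the unweighted mean of the four one-vs-rest
class accuracies on a training set, with ties broken toward the smallest
pair lexicographically so the result is deterministic.

Design choices in the slide rule that the task itself does not fix:

* **Fraction denominators.**  "Villous fraction" is computed within the
  adenomatous branch (TVA over TA + TVA) and the SSA fraction within the
  serrated branch, reading "amount of villous tissue" as a within-lesion
  proportion.  A `denominator = "all_polyp_patches"` switch divides by
  all non-normal patches instead, for sensitivity analysis.
* **Branch ties** (equal adenomatous and serrated counts) go to the
  adenomatous branch, the clinically more consequential call.
* **A slide with zero polyp patches** raises a "no lesion detected"
  error rather than guessing: the four slide classes presuppose a
  lesion, and normal slides are not part of the slide-level vocabulary.

Monotonicity is a designed-in property: raising $\theta_v$ can only move
diagnoses TVA → TA and raising $\theta_s$ only SSA → HP, never the
reverse, and neither threshold can move a slide between branches.  The
test suite verifies this over 10,000 random count vectors.

## The patch classifier

The classifier contract is minimal: a model maps a batch of square
patches to an *n* × 5 matrix of class probabilities (rows summing to 1,
columns in the fixed order TA, TVA, HP, SSA, NORM, which is also the
argmax tie-break order).  The reference backend is a deliberately small
two-block convolutional network — conv 5×5/8 filters, ReLU, 2×2
max-pool, conv 3×3/16, ReLU, 2×2 max-pool, dense softmax — trained by
minibatch SGD with momentum on the cross-entropy loss.  Patches are
area-averaged to a 32 × 32 working resolution before entering the
network (224 = 7 × 32, so the pooling is exact) and centered at zero.
The intent is a backend that trains on one CPU in minutes while
exercising every part of the training and inference machinery; a
ResNet-scale backbone can be slotted in behind the same `predict`
contract without touching the rest of the pipeline.

Training follows the reference schedule: MSRA/He-normal initialization
and an exponentially decaying learning rate
$\mathrm{lr}(e) = 0.001 \times 0.9^{\,e-1}$.  At full scale this
schedule is run for 200 epochs; the package default is 20 epochs, which
suffices for the synthetic textures (the test suite requires ≥ 0.95
held-out patch accuracy from 200 patches per class).  The batch size
defaults to 8: with the small fixed initial rate, smaller batches give
the update count the schedule needs at desk scale.  Augmentation —
right-angle rotations, flips, and brightness/contrast/saturation/hue
jitter with half-ranges 0.1/0.1/0.1/0.05 — is applied to training
patches only; the jitter magnitudes are package choices, as is plain
SGD (momentum 0.9) for the optimizer.  Training is deterministic given
the config seed.

Ensembles average member probability vectors with equal weights
(`patch_ensemble()`, `ensemble_predict()`).  Unweighted softmax
averaging is the package's documented assumption for combining members;
members must agree on the class order, and a single-member ensemble is
exactly its member.

## The synthetic-slide generator

No real whole-slide images ship with the package.  Instead,
`generate_slide()` renders procedural slides on which every downstream
stage is exercised and every planted quantity is recoverable:

* Each patch class has a parametric texture: a base colour modulated by
  a class-specific periodic structure (round tubular lumens for TA,
  elongated fronds for TVA, sawtooth serration for HP, large dilated
  crypts for SSA, sparse pale stroma for normal tissue) plus Gaussian
  pixel noise (sd 0.02).  These are *statistical* patterns, not
  histology simulations: the classes are separable by mean colour,
  gradient energy and dominant period — a texture-statistic vector whose
  mean inter-class distance exceeds three times its intra-class spread
  at the defaults — so a small CPU-trainable network can learn them.
* A slide (default 2048 × 2048 px) is a normal background with three
  rectangular polyp ROIs whose corners are aligned to the 224-px window
  grid (ROI sides of 3–4 cells, i.e. 672–896 px).  For an adenomatous
  slide, a fraction of the ROI cells — rounded at the slide level, so
  the realized area fraction is within 0.5/`n_cells` ≈ 0.02 of the
  request — is drawn with TVA texture; serrated slides analogously with
  SSA texture.  Because cells coincide with inference windows, the
  planted patch-label histogram (`oracle_counts`) is exact, and a
  perfect patch classifier can be simulated with
  `oracle_patch_predictions()`.
* `generate_cohort()` draws per-slide minority fractions uniformly from
  per-class ranges chosen to straddle the reference thresholds with a
  margin of at least 0.05: TA villous fractions in [0.05, 0.22], TVA in
  [0.40, 0.80], SSA fractions in [0.10, 0.40], and HP slides carry no
  SSA texture (a margin of 0.05 below 0.015 is impossible, so the HP
  condition is "none").  With these margins, the hierarchical rule at
  the reference thresholds reproduces every planted label from oracle
  counts, which is the 100%-oracle-accuracy condition the end-to-end
  tests assert.

At the default window geometry (81 windows per slide) one patch is
about 1.2% of a slide, coarser than $\theta_s = 0.015$.  Grid-search
recovery of the planted thresholds therefore uses a counts-level
cohort (`simulate_patch_count_cohort()`, 1000 polyp patches per slide,
fraction resolution 0.001) in which slide labels are assigned by the
rule at the planted thresholds; the default grids (villous 0–1 step
0.05, SSA 0–0.10 step 0.005) contain the planted pair, which is then
the unique maximizer.

What the generator does **not** emulate: realistic H&E appearance,
stain and scanner variation between institutions, tissue folds and
artifacts, multiple lesions with irregular (non-rectangular) outlines,
and spatial correlation between neighbouring patches.  Passing
end-to-end tests on these fixtures demonstrates that the pipeline
machinery is correct and well-calibrated under separable textures; it
does not demonstrate diagnostic performance on real slides.

## Simulated annotator panels

Multi-rater statistics need panels with controllable disagreement.
`simulate_annotator_panel()` labels each slide independently per
annotator from the confusion-matrix row of the slide's true class.  The
default model places probability $a = 0.886$ on the true class and
spreads the remainder uniformly.  That value is calibrated analytically:
for two such annotators on a balanced 4-class cohort the observed
agreement is $p_o = a^2 + (1-a)^2/3$, the chance agreement is
$p_e = 1/4$, and

$$\kappa = \frac{p_o - 1/4}{3/4} = 0.72 \quad \text{at } a = 0.886,$$

the agreement level reported for expert gastrointestinal-pathologist
panels on this task.  The test suite checks that simulated panels
recover this analytic $\kappa$ within Monte-Carlo error.  Annotator
errors are independent across annotators and slides; correlated error
structures (e.g. site effects) are out of scope.

Ground truth from a panel is the strict plurality vote
(`majority_vote()`).  Ties among five raters over four classes are
possible (2-2-1); they are resolved by a designated reference
annotator's label when it is among the tied classes, and flagged.  The
tie policy is a package choice.

## Evaluation statistics

* **Per-class metrics** are one-vs-rest: sensitivity TP/(TP+FN),
  specificity TN/(TN+FP), accuracy (TP+TN)/n, reported in percent.  A
  metric with an empty denominator is reported missing, never zero.
* **Mean rows** are unweighted arithmetic means of the four per-class
  values, computed before rounding.  Reported percentages are rounded
  half-away-from-zero to one decimal; machine outputs keep full
  precision.
* **Confidence intervals** for mean percentages are Wald binomial
  intervals $p \pm 1.96\sqrt{p(1-p)/n}$ on the mean treated as a
  proportion over the $n$ evaluated slides.  This is a reconstruction —
  reference reports of this design do not name their interval — adopted
  because it reproduces the published intervals for both test sets to
  0.1 of a percentage point (verified in the test suite).
* **Agreement** is the mean multiclass Cohen $\kappa$ over all
  $\binom{5}{2} = 10$ annotator pairs, with
  $\kappa = (p_o - p_e)/(1 - p_e)$ and $p_e$ from marginal products;
  two constant, identical raters get $\kappa = 1$ by convention.  The
  interval on the mean is a normal approximation from the spread of the
  10 pairwise values, also a package choice.
* **Proportion comparisons** use the pooled two-proportion z-test (the
  standard reading of a "t test for proportions"); it reproduces the
  published external-accuracy comparison ($P = .90$).  An unpooled
  variant is available via `pooled = FALSE`.

## Visualization

`render_heatmap()` tints each predicted patch with its argmax class
colour at opacity $\alpha = 0.15 + 0.6 \cdot \text{confidence}$
(confidence = maximum class probability), a linear monotone mapping so
more confident predictions are darker; `render_lesion_mask()` paints a
binary highlight over patches predicted as any polyp class.  Colours and
the $\alpha$ curve are package choices; rendering is deterministic and
strictly local to predicted patch boxes.

## Problem sizes and numerical conventions

The package's standard desk-scale configuration, used by the test suite
and the acceptance script: cohorts of 10 slides per class (40 slides) at
2048 × 2048 px; 200 training patches per class after balancing; 20
training epochs; the full 21 × 21 calibration grid; panels of 5
annotators over ~2000 slides for agreement checks (157 for the
headline-scale panel).  All randomness is seeded and every generator,
trainer and pipeline stage is deterministic given its seed; seeds for
sub-streams are derived from the master seed with a fixed integer
recurrence kept below $2^{31}$.

Coordinates everywhere are 0-based, half-open pixel boxes
$[x_0,x_1)\times[y_0,y_1)$ with x = column, y = row, origin top-left.
Sliding windows that would extend past their box are dropped, not
padded (this affects at most one window row/column per ROI and keeps
every patch a pure crop).  `extraction_downsample` defaults to 1
because the package's own images are generated at extraction
resolution; for full-resolution 40× scans (0.25 µm/px) where a 224-px
patch should span 448 µm, set it to 8.

## Known limitations

* The reference network is a toy by design; its accuracy guarantees
  hold only for the synthetic textures.
* Slide-level inference assumes one lesion type per slide; slides with
  multiple distinct polyps are not segmented into separate lesions.
* High-grade dysplasia, adenocarcinoma and traditional serrated adenoma
  are not in the class vocabulary, and entirely normal slides are
  rejected rather than classified.
* The two-proportion z-test and the Wald interval are large-sample
  approximations; they are inaccurate for very small cohorts or
  proportions near 0 or 1.
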