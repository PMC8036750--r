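---
title: "Dual-channel stain texture features: methods and design notes"
author: "StainFOS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-channel stain texture features: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Prostate biopsies are graded by pathologists from Hematoxylin & Eosin
(H&E) stained slides. Benign tissue shows small, uniform glands with
abundant stroma between them; malignant tissue shows irregular, crowded
masses of neoplastic glands, loss of lumina and nucleus-dense sheets of
cells. These differences change the *intensity distribution* of each
stain channel long before they are obvious as shapes, which is what makes
first-order-statistic (FOS) radiomics attractive: the features are cheap,
interpretable, and do not require nucleus segmentation.

StainFOS implements a patch-based dual-channel pipeline for binary tissue
classification (benign vs. malignant, low vs. high grade):

1. gamma correction of each region of interest (ROI),
2. tiling into non-overlapping 64×64 patches,
3. Beer–Lambert colour deconvolution into Hematoxylin (H) and Eosin (E)
   concentration channels,
4. six FOS features per channel per patch (12 per patch),
5. two-step feature selection (recursive feature elimination, then
   one-way ANOVA with eta-squared effect sizes),
6. classification by SVM, logistic regression, bagging tree, boosting
   tree, and a dual-channel bidirectional LSTM (DC-BiLSTM),
7. confusion-matrix / ROC evaluation with an explicit recall hypothesis
   check.

# The stain model

An 8-bit RGB pixel is converted to optical density per channel,

$$OD_c = -\ln\big(\max(v_c, 1)/255\big), \qquad c \in \{R, G, B\},$$

under the Beer–Lambert law; OD is linear in stain concentration. The
floor guard at 1 avoids $\ln 0$ for black pixels while keeping OD exactly
0 for pure white and strictly nonnegative everywhere, and — unlike the
common additive $v + 1$ variant — it introduces no systematic bias, so
the transform inverts the forward model $v_c = \mathrm{round}(255
e^{-OD_c})$ up to 8-bit rounding. That property is what makes the
synthetic generator (below) an exact oracle for the deconvolution.

Deconvolution inverts the linear mixing $OD = c_H v_H + c_E v_E + c_R
v_R$ with the standard Ruifrok–Johnston H&E basis ($v_H = (0.650, 0.704,
0.286)$, $v_E = (0.072, 0.990, 0.105)$, residual completed as their unit
cross product; all rows unit-normalized). The basis is configurable;
blind stain estimation (Macenko, Vahadane) is out of scope. Negative
concentrations — quantization or noise artifacts — are clamped to 0.

**Quantization error budget.** 8-bit pixels limit how well concentrations
can be recovered. A rounding error of ±0.5 gray levels at intensity $I$
perturbs OD by about $0.5/I$, and the deconvolution multiplies OD errors
by the inverse basis (largest coefficient ≈ 1.49 for the H channel). On
the generator's default concentration range $[0, 1.2]$ the worst-case
per-pixel recovery error is about 0.02 OD units, and well under 0.01 for
typical mid-range concentrations; at concentrations near 3 the bound
grows to roughly 0.28 because the deepest-stained pixels fall to single-
digit gray levels. The round-trip tests assert the 0.01 level on
mid-range constant fields and the 0.02 level across the default range.

**Channel quantization for histograms.** FOS features presuppose discrete
gray levels, so each concentration map is quantized to 8 bits over a
*fixed global* range of [0, 3] OD units. Per-patch min–max scaling would
make histogram features incomparable across patches (a flat patch would
be stretched to full range); a fixed range keeps features commensurate.
Features can also be computed on raw concentration maps via
`extractDualChannelFeatures(quantized = FALSE)`.

# First-order features

For a channel patch with $N$ pixels $x_j$ and normalized histogram $p(i)$
over 256 bins:

* energy $\sum_j x_j^2$, variance $m_2 = \tfrac1N\sum_j (x_j-\mu)^2$
  (population),
* skewness $m_3/m_2^{3/2}$ and kurtosis $m_4/m_2^{2}$ (non-excess,
  Pearson),
* entropy $-\sum_i p(i)\log_2 p(i)$ in bits, uniformity $\sum_i p(i)^2$.

Zero-variance patches return skewness and kurtosis 0 by convention
(entropy 0, uniformity 1 follow from the definitions). Every feature is
checked against an explicit-loop implementation to 1e-9 relative error,
and the features are invariant to any spatial rearrangement of pixels —
they are distribution statistics, nothing more. Per-column z-scores are
fitted on the training partition only and applied everywhere
(zero-variance columns are left at 0); standardization lives in the
feature module so every classifier sees identical inputs. Whether the
original study standardized before classical training is not documented;
standardization-on is the default here, switchable via
`buildFeatureTable(standardize = FALSE)`.

# Feature selection

RFE iteratively fits a gradient-boosting baseline (100 trees, depth 3,
learning rate 0.1, single thread — fixed for reproducibility) and removes
the weakest feature until `k = 5` remain, ties broken by removing the
lexicographically last name so the elimination order is deterministic.

A design question with no documented answer is whether selection operates
on 6 features or on 12 dual-channel columns. StainFOS ranks the six
feature *families* by pooling (summing) the importances of each family's
H and E columns and eliminates families as units, keeping 5 families = 10
columns. This reconciles "five of six features" with dual-channel
learning and guarantees the H and E branches of the DC-BiLSTM always see
the same feature families. Which family is eliminated is data-dependent
and deliberately not hard-coded.

The kept families are then validated by one-way ANOVA on the training
partition. The test runs per channel column and each family is judged by
its stronger channel (larger effect size): pooling the H and E values
into one vector looks natural but lets a family whose channels shift in
opposite directions cancel to a null pooled effect despite being highly
discriminative, which is exactly the dual-channel signal the pipeline
exists to exploit. Effect size is
$\eta^2 = SS_{between}/SS_{total}$ categorized at the conventional
0.01/0.06/0.14 thresholds. Families with $p \ge \alpha$ (default 0.05)
are dropped; if nothing survives, the selection fails loudly with a
diagnostic table rather than guessing.

# Classifiers

The four classical models are standard library fits behind one
interface: RBF-SVM (cost 1, probability outputs), logistic regression,
bagging (100 unpruned trees with `mtry = p`, i.e. bootstrap aggregation
without feature subsampling), and gradient boosting (100 trees, depth 3,
rate 0.1). Hyperparameters are fixed defaults, not tuned. The positive
class is always malignant (or grade5); hard labels use threshold 0.5, no
calibration.

The DC-BiLSTM is implemented in the package (batched forward pass,
backpropagation through time, Adam, early stopping on validation loss
with best-weight restoration). Architecture: one branch per stain
channel, each branch two stacked bidirectional LSTM layers of 64 cells
whose forward and backward passes are concatenated; the terminal states
of both branches are concatenated into a single vector and passed to a
fully connected 2-way softmax. With the zero-initialized output layer the
untrained network scores exactly 0.5, a property the tests use.

Two input interpretations are supported because the architecture's
description is ambiguous between them:

* `"feature"` (default): each branch consumes its channel's k selected
  FOS features as a length-k sequence, one scalar per time step, ordered
  by decreasing RFE rank — this matches the pipeline framing where
  selection precedes learning;
* `"patch_rows"`: each branch consumes the raw 64×64 channel patch as 64
  time steps of 64 values — this matches a "time steps = 64" reading.

Neither is asserted to be the original intent; both run through the same
engine.

Training defaults are 100 epochs maximum, batch 64, Adam at 1e-3,
patience 10. At the full problem size (5120 training patches) the
package's reference runs use 15 epochs with patience 5: the selected
features are low-dimensional and strongly separable, so the network
converges within a few epochs, and the shorter budget keeps a complete
five-model comparison on a single CPU in the minutes range.

# The synthetic generator

No public substitute exists for the private slide dataset, so the
package ships a seeded generator that emulates H&E tissue through the
same Beer–Lambert forward model the deconvolution inverts: per-pixel H
and E concentration fields are drawn (smooth eosin-rich stroma,
elliptical glands with hematoxylin-dense epithelium and optional
near-white lumina, nucleus-like hematoxylin specks), recorded as ground
truth, perturbed with Gaussian noise *in OD space*, and rendered to 8-bit
RGB. Noise in OD space rather than RGB space is deliberate: it keeps the
noise-free render an exact oracle for the deconvolution.

Class recipes follow the qualitative morphology of prostate histology:
benign — small uniform glands (radius 8±1.2 px), low density, open
lumina, minimal clutter; malignant — larger irregular glands (13±5 px),
2–3× density, frequent lumen loss, heavy nuclear clutter (25% of stroma);
grade3 and grade5 interpolate/extremize the same axes (grade5
approaching lumen-free cell sheets with 35% clutter). Concentration
ranges are held in [0, 1.2] OD — realistic for H&E and inside the region
where 8-bit recovery stays near 0.01 OD (see the error budget above).
These defaults were fixed once, from the morphology descriptions, before
any classifier results were inspected.

What the generator does *not* emulate: real optical blur and chromatic
aberration, stain variation between labs, tissue folds and artifacts,
nucleus-level spatial structure, or second-order texture. Consequently,
passing classification tests on synthetic data demonstrate that the
pipeline machinery is correct and that FOS features separate
distribution-level class differences — they do not certify performance
on real slides, where the reported headline numbers came from data that
is not publicly available.

# Numerical and procedural conventions

* Coordinates are 0-based, row-major, top-left origin; patch offsets are
  multiples of 64; remainder rows/columns are discarded (study images
  divide evenly).
* Gamma correction applies `round(255 * (v/255)^gamma)` per channel with
  round-half-up; the gamma value itself is not documented in the source
  study, so the default is 1.0 (a no-op) — data are never silently
  altered by an invented constant. Resizing is bilinear.
* Background filtering scores patches by mean OD over all three
  channels (white = 0), drops those below 0.15 by default, and orders
  survivors by descending score with lexicographic patch-id tie-breaks;
  `keepTopK` then takes an exact count.
* ROI splitting is stratified by class and grouped by ROI
  (`round(fraction * n)` per class, remainders to train), so patches
  never leak across partitions; 250+250 ROIs at 0.64/0.16/0.20 give
  exactly 320/80/100 ROIs = 5120/1280/1600 patches.
* Metric reporting rounds half-up to one decimal only at report time.
  Precision/recall/F1 are positive-class metrics; undefined denominators
  yield NA with a warning, never 0.
* One master seed derives per-stage seeds (`seed + 7919 * stage_index`,
  kept under 2^31), so a full rerun is byte-identical; every run
  directory embeds its config and an md5 of it.

# Known limitations

* The ≤ 0.01 OD round-trip bound is physically attainable only where
  stained pixels stay above ~25 gray levels; the package documents and
  tests the honest bound instead of pretending 8-bit images carry more
  information.
* The published per-table precision/recall values cannot all be
  reproduced from the published confusion matrices under any single
  positive-class convention (e.g. one matrix gives recall 792/800 =
  99.0 vs. a printed 98.9); accuracy is convention-free, so the package
  asserts accuracies from those matrices and treats the printed
  precision/recall rounding as unresolved.
* The DC-BiLSTM is a faithful but compact implementation (no dropout, no
  gradient clipping, no learning-rate schedule); it is adequate for the
  low-dimensional feature sequences it consumes by default, not a
  general-purpose deep-learning engine.
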