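---
title: "Methods: texture, fusion classification and uncertainty for intestinal ischemia-reperfusion images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: texture, fusion classification and uncertainty for intestinal ischemia-reperfusion images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irimage)
```

## The problem

Acute intestinal ischemia requires the surgeon to decide, intra-operatively,
which bowel segments will recover after reperfusion and which must be
resected. Visual inspection is unreliable in the borderline zone, and a
second-look operation 24-48 h later is often needed. A promising alternative
is to photograph the serosal surface with a digital microscope and classify
the images by injury state. `irimage` implements that analysis end to end:
tissue images are assigned to one of 18 classes indexed by hours of ischemia
and reperfusion (class 0 = healthy control; 1-8 = 1-8 h ischemia; 9-13 = 3 h
ischemia + 1-5 h reperfusion; 14-17 = 4 h ischemia + 1-4 h reperfusion), and
the package provides the texture statistics, classifiers, uncertainty
quantification and attribution maps used to study them.

Because the porcine image dataset this design comes from is not publicly
deposited, the package ships a synthetic generator that emulates the
dataset's statistical structure; every stage is developed and tested against
it.

## The synthetic tissue generator

`generate_dataset()` draws, per image: a pink-red base field; a low-frequency
"mottle" texture (a coarse Gaussian grid bilinearly upsampled); 3-6 dark
curvilinear vessels (random-walk polylines with a Gaussian cross-section,
strongest in the red channel); and i.i.d. Gaussian pixel noise (sd 2
intensity units). The class state drives three signals:

* **Mottle amplitude** (texture): `amplitude_control * (1 + gain * i)`,
  where `i` is hours of ischemia, with `amplitude_control = 4` and
  `gain = 0.35` per hour. For reperfusion classes the whole amplitude is
  scaled by `1 - recovery * min(r, i) / i`, with `recovery = 0.5` after 3 h
  of ischemia and `0.25` after 4 h. This encodes the study's qualitative
  findings: image entropy and red-channel contrast rise with ischemia
  duration, are partially reversed by reperfusion, and the reversal is
  stronger when ischemia lasted 3 h than 4 h (3 h of warm ischemia is
  regarded as the viability limit in this model).
* **Red-channel mean** (colour): decreases by 6 intensity units per ischemia
  hour and recovers with reperfusion by the same factor — ischemic tissue
  darkens, reperfused tissue regains colour.
* **Green-channel drift**: decreases by 3 units per hour of *total elapsed
  time* (`i + r`) and is not reversed; it emulates the slow serosal change
  of exposed bowel over the 8 h protocol. Methodologically it also makes the
  18 `(phase, hours)` states jointly identifiable — amplitude and red level
  alone would leave some reperfusion states indistinguishable from
  intermediate ischemia states, which the hour-resolved labels of the real
  acquisition do distinguish.

The defaults (64 x 64 px, 40 images per class) are the desk-scale working
point used by the tests and the acceptance script: large enough for the
texture statistics to separate classes, small enough that the full pipeline
trains on one CPU in minutes. Full-size 224 x 224 rendering is supported.
The generator is **not** anatomically realistic: it makes no claim about
vessel topology, specular highlights, peristalsis or inter-animal variation.
Consequently, passing tests demonstrate that the pipeline recovers the
statistical structure the generator encodes — not that the classifiers would
reach any particular accuracy on real intestinal images, whose headline
accuracies cannot be reproduced without the original data.

An imbalance mode (`control_multiplier`) inflates the control class, as in
the real acquisition where the control segment is imaged over the whole time
course; the class-weight formula below then compensates.

## Texture statistics

`shannon_entropy()` computes `H = -sum p_i log2 p_i` over a 256-bin intensity
histogram, skipping empty bins. The intensity variable is open to choice;
the package defaults to gray luminance (ITU-R BT.601,
`0.299 R + 0.587 G + 0.114 B`) on the grounds that entropy is discussed as a
whole-image texture property; any single channel can be passed instead.

`cooccurrence_matrix()` counts ordered pairs of values `(pixel, pixel at
offset)` — asymmetric, skimage-compatible — with the study's offset of one
pixel at zero radians, on the red channel (red dominates intestinal tissue).
`glcm_contrast()` is `sum_ij G_ij (i - j)^2` on the normalized matrix;
dissimilarity, homogeneity, energy and correlation are also available.
`class_summary()` reports per-class boxplot statistics (Tukey 1.5 IQR
whiskers — the usual convention).

## Handcrafted descriptors

`hog_descriptor()` is a from-scratch histogram of oriented gradients:
centered-difference gradients (edge replication at borders), 9 unsigned
orientation bins over [0, 180) with magnitude-weighted linear interpolation
between bin centres at (k - 0.5) x 20 degrees, 8 x 8-pixel cells, 2 x 2-cell
blocks at one-cell stride, L2 block normalization with an epsilon guard
(zero-gradient blocks map to zero vectors, so a constant image yields a zero
descriptor rather than NaNs). A 224 x 224 image yields 27 x 27 x 36 = 26,244
features; 64 x 64 yields 1,764. The unsigned convention and centered
differences are the common defaults for 9-bin HOG; the reference design fixes only the
bin count, cell and block sizes. For the CNN branch the descriptor is
rendered as an image (per-cell oriented lines weighted by the cell
histogram), since a convolutional branch needs a spatial input and the
descriptor itself is a flat vector.

`lbp_map()` is the classic local binary pattern: 8 neighbours at radius 1
compared with the centre, bit set on `neighbour >= centre` (the tie must be
assigned somewhere; `>=` is the original convention). The defining property
of LBP is exact invariance under monotone intensity transforms, which holds
only if sampling points coincide with pixels; bilinear interpolation at
off-grid circle points does not commute with nonlinear monotone maps and
breaks the invariance. The package therefore snaps the radius-1 circle to
the 8 grid neighbours by default — the original LBP operator — and offers
`interpolate = TRUE` for the circular-sampling variant. Both are validated
against naive per-pixel implementations in the tests.

## The convolutional classifier

The classifier is the core of the method, so rather than delegating to an
external deep-learning framework the package implements the network engine
natively in R: convolution as im2col gather plus BLAS matrix
multiplication, exact backpropagation (validated against finite differences
to ~1e-7 relative error in the tests), and Adam. The architecture follows
the reference design: four stages of `conv(3x3, 'same', L2 penalty, ReLU) ->
maxpool(2) -> dropout`, with widths `base_units x (1, 2, 3, 4)`, then a ReLU
dense layer (width 128 by default — the reference design leaves it open), dropout, and
an 18-unit softmax. Training minimizes class-weighted cross-entropy, with
weights `n / (n_classes * n_c)`, and optional augmentation (rotation up to
20 degrees, zoom 90-110%, horizontal/vertical flips at probability 0.5 each
— the flip probability is the package's choice) applied to training batches
only. The reference hyperparameter grid (base units 16/32/64/128,
L2 1e-3/1e-4/1e-5, dropout 0.1/0.2/0.3, batch 32/64/128, learning rate
1e-3/1e-4, 100 epochs) is expressible through `cnn_config()`; the desk-scale
defaults are base 16, dropout 0.2, L2 1e-4, batch 32, learning rate 1e-3, 15
epochs. The softmax layer starts at zero weights, so training begins at
exactly the uniform-prediction loss `log(n_classes)` — a convenient, widely
used initialization that also anchors the loss scale in tests.

Numerical conventions worth recording: pooling ties route the gradient to
the first maximal child; dropout uses inverted scaling; all training
randomness (shuffling, dropout, augmentation, weight draws) derives from the
config seed, so identical calls give identical histories.

## Decision-level fusion

Three branches — RGB images, HOG renderings, LBP code maps, each
standardized per channel with parameters fitted on its own training fold —
are trained as independent CNNs. Their per-image class-probability vectors
are concatenated (3 x 18 = 54 features) and classified by a random forest
(100 or 300 trees; `randomForest`). The meta-classifier is trained on the
branches' *validation-fold* predictions, not on the branches' own training
data: branch outputs on training images are overconfident and would teach
the forest the wrong feature distribution (the reference design leaves open which
fold it used). The RGB branch doubles as the traditional-CNN baseline in the
model comparison.

## Bayesian network and uncertainty

`build_bayesian_cnn()` replaces every kernel weight by an independent
Gaussian with learnable mean and standard deviation (softplus
parameterization), sampled per forward pass by the reparameterization trick;
kernel parameter count is exactly twice the deterministic twin's. Biases
remain point estimates, matching the reference implementation's layers in
which only the kernels carry posteriors. Training minimizes the negative
log-likelihood of sampled-weight predictions; because the weights are
variational, the KL divergence of the posteriors from a standard-normal
prior is added, scaled by `1/n_train` (standard minibatch ELBO scaling), and
can be disabled (`kl_weight = 0`) for a pure-likelihood comparison. The
posterior standard deviations are initialized at 5% of the He weight scale:
a fixed absolute initial sd would be as large as the deeper layers' weights
themselves, making an untrained network wildly overconfident instead of
near-uniform.

`mc_predict()` runs `T` (default 300) independent stochastic passes;
`uncertainty_intervals()` restricts to correctly predicted images (majority
vote over the per-pass argmax — correctness must be decided somehow at MC
level, and majority vote is the natural choice), takes each image's `T`
true-class probabilities, computes the per-image mean and 2.5th/97.5th
percentiles (linear interpolation), and averages within each class. Classes
with no correctly predicted image are reported as missing rather than
fabricated. Harder, overlapping classes — in the synthetic data the
mid-reperfusion states, in the porcine experiment the mid-reperfusion classes — show lower
mean certainty and wider intervals.

## Shapley patch attribution

The original analysis used a packaged SHAP explainer without recording the
variant, so its pixel values are not numerically reproducible; the package
implements model-agnostic Shapley attribution over image patches instead,
which is exactly testable. The image is tiled by a patch grid (8 x 8 patches
at 64 x 64 by default); hidden patches are replaced by a baseline image (the
training-set mean; zeros or a blurred image are reasonable alternatives).
`shapley_attribution()` estimates each patch's Shapley value by permutation
sampling — marginal contribution of each patch along random reveal orders —
whose per-permutation contributions telescope, so the estimate satisfies the
efficiency axiom exactly: the values sum to `f(image) - f(baseline)`.
`exact_shapley_oracle()` enumerates all `2^n` coalitions (n <= 12) with the
combinatorial weights and anchors the tests: efficiency, symmetry and
null-player hold to 1e-9, and the 2000-permutation estimator stays within
0.02 of the oracle on an 8-patch fixture. `render_attribution()` draws the
diverging red (positive) / blue (negative) overlay per target class.

## Evaluation

`accuracy_score()`, `macro_precision_recall()` (unweighted per-class
averages; a class never predicted contributes precision 0, with a warning)
and `confusion_counts()` feed `evaluation_report()`. The 60/20/20
train/validation/test split shuffles the whole dataset first (as in the
source — images of the same animal may fall on both sides, a known leakage
caveat of that design); validation/test sizes are floor-rounded with the
remainder going to training. Stratified or subject-grouped splitting can be
composed from `subset_dataset()` if leakage-free evaluation is wanted.

## The pipeline and problem sizes

`run_experiment()` chains simulate -> stats -> features -> branch training
-> fusion -> Bayesian uncertainty -> attribution, with every stage seed
derived deterministically from one global seed, and writes CSV/JSON
artifacts stamped with a config hash. The package's standard problem sizes,
chosen once as its desk-scale study conditions: 18 x 40 images at 64 x 64,
15 training epochs with base 16 units for the branches, 10 epochs for the
Bayesian model, 300 Monte-Carlo passes over up to 72 test images, and 50
sampled permutations on an 8 x 8 patch grid for attribution maps. The unit
tests use smaller fixtures (fewer classes, 32 x 32 images) for everything
except the acceptance checks.

## Known limitations

* The generator's realism is statistical, not anatomical; transfer of any
  accuracy figure to real tissue images is out of scope.
* A pretrained-backbone branch (e.g. ResNet50) is deliberately not shipped:
  it would require downloading external weights. The training functions
  accept any `ir_cnn`, so a custom backbone can be slotted in.
* The network engine is CPU-only and sized for desk-scale experiments;
  full-scale settings (224 x 224, 100 epochs, tens of thousands of images) are expressible
  but slow in pure R.
* Gradient-based explainers (GradCAM, LIME) are out of scope; the Shapley
  module is the package's single attribution method.
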