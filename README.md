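# irimage

Texture statistics, deep classification and uncertainty quantification for
intestinal ischemia–reperfusion surface images.

## The problem

Acute intestinal ischemia forces a hard intra-operative decision: which bowel
segments will recover once blood flow is restored, and which must be
resected. Visual inspection is unreliable in the borderline zone, so a
second-look operation 24–48 h later is often required. One proposed
alternative is to photograph the serosal surface with a digital microscope
and classify the images by injury state on an hourly scale: class 0 is the
healthy control, classes 1–8 are 1–8 h of ischemia, classes 9–13 are 3 h of
ischemia followed by 1–5 h of reperfusion, and classes 14–17 are 4 h of
ischemia followed by 1–4 h of reperfusion.

`irimage` implements that analysis as a reusable R pipeline, for researchers
studying tissue-viability classification from surface images:

* a **seeded synthetic tissue-image generator** (the animal dataset behind
  this design is not publicly deposited) whose class-dependent statistics
  reproduce the documented trends: Shannon entropy and red-channel GLCM
  contrast rise with ischemia duration, are partially reversed by
  reperfusion, and reverse more strongly after 3 h of ischemia than after
  4 h;
* **texture statistics**: Shannon entropy `H(X) = -Σᵢ P(xᵢ) log₂ P(xᵢ)`
  over the 256-bin intensity histogram, and red-channel co-occurrence
  properties, `contrast = Σᵢⱼ G_ij (i − j)²` for the normalized GLCM `G` at
  a one-pixel, zero-radian offset (plus dissimilarity, homogeneity, energy,
  correlation);
* **from-scratch HOG and LBP descriptors** (9 unsigned orientation bins,
  8×8-px cells, 2×2-cell L2-normalized blocks; 8-neighbour radius-1 binary
  codes) and their image-shaped renderings;
* a compact **convolutional network** — four stages of conv(3×3, same, L2,
  ReLU) → maxpool(2) → dropout with widths `base × (1,2,3,4)`, a dense ReLU
  layer and an 18-unit softmax — trained with class-weighted cross-entropy
  (weights `n/(k·n_c)`) and Adam, implemented in pure R (im2col + BLAS) with
  backpropagation verified against finite differences;
* **decision-level fusion**: the RGB, HOG and LBP branches' 18-class
  probability vectors are concatenated into 54 features and classified by a
  random forest trained on held-out validation predictions;
* a **Bayesian CNN** whose kernel weights carry independent Gaussian
  posteriors (mean + softplus standard deviation, reparameterized sampling;
  exactly 2× the kernel parameters of its deterministic twin), trained on
  negative log-likelihood + KL/n, with Monte-Carlo prediction distributions
  (default 300 passes) summarized as per-class mean certainty and averaged
  2.5th/97.5th percentile intervals over correctly predicted images;
* **macro-averaged evaluation** (accuracy, macro precision/recall, confusion
  matrices) with a shuffled 60/20/20 split;
* **Shapley patch attribution** by permutation sampling, with an exact
  coalition-enumeration oracle (≤ 12 patches) and red/blue overlay
  rendering.

## Worked example

```r
library(irimage)

cfg <- generator_config()                       # 64x64, 40 images/class
control  <- render_tissue_image(class_label(0), cfg, seed = 7)
ischemic <- render_tissue_image(class_label(8), cfg, seed = 7)  # 8 h ischemia

round(unlist(red_channel_stats(control))[c("entropy_bits", "contrast")], 2)
#> entropy_bits     contrast
#>         3.76        12.20
round(unlist(red_channel_stats(ischemic))[c("entropy_bits", "contrast")], 2)
#> entropy_bits     contrast
#>         4.90        17.21
```

Eight hours of ischemia raise the image entropy (3.76 → 4.90 bits) and the
red-channel contrast (12.2 → 17.2): the ischemic surface is mottled and
granular where the control is smooth. `class_summary()` tabulates these
statistics for all 18 classes and `plot_class_summary()` draws the boxplots.

A full experiment — generate, split 60/20/20, train the three branches, fuse,
train the Bayesian model, summarize uncertainty, explain predictions — is one
call:

```r
cfg <- experiment_config(bayes_epochs = 10, mc_passes = 300, mc_max_images = 72,
                         n_permutations = 50, n_attribution_images = 1, seed = 1)
bundle <- run_experiment(cfg)
bundle$comparison
```

At the package's desk-scale study conditions (18 × 40 images, 64×64 px, 15
epochs, base 16 units; seed 1) this prints

```
   model  accuracy macro_precision macro_recall
1    cnn 0.9444444       0.9583333    0.9398148
2 fusion 1.0000000       1.0000000    1.0000000
3  bayes 0.9444444       0.9395944    0.9407407
```

reproducing, on synthetic data, the qualitative model ordering reported for
the original porcine dataset: decision-level fusion improves on the
single-branch CNN (the cnn and fusion rows use the 144 test images; the
bayes row is scored on the 72 Monte-Carlo test images). `bundle$uncertainty`
holds the per-class Monte-Carlo certainty means and 95% intervals, e.g.

```
  class_index n_correct mean_certainty lower upper
1           0         5          0.509 0.197 0.779
2           1         8          0.490 0.211 0.740
3           2         5          0.380 0.199 0.611
4           3         3          0.585 0.337 0.780
```

and `bundle$attributions` the Shapley patch maps (`render_attribution()`
draws the red/blue overlays). All numbers
above come from the synthetic generator — the package makes no claim that
they transfer to real tissue images (see the methods vignette,
`vignettes/irimage-methods.Rmd`).

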