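---
title: "Weakly supervised multiple-instance learning for breast ultrasound: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised multiple-instance learning for breast ultrasound: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

sonomil implements breast-level malignancy prediction from variable-size
breast-ultrasound image sets using weakly supervised multiple-instance
learning (MIL), together with the clinical evaluation machinery such a model
needs: cohort eligibility rules, matched operating points, hybrid reader-AI
fusion, bootstrap confidence intervals and permutation tests. Because the
clinical archives such models are trained on are private, the package ships a
seeded synthetic phantom generator that reproduces the *structure* of the
problem — bags of images, a lesion visible in only some of them, labels only
at the breast level — so that every component is testable end to end on any
machine.

## The model

A breast exam is an image set $X = \{x_1, \dots, x_K\}$ with $K$ varying
freely (4-12 for phantoms; real exams reach 70). Only two binary labels are
available per breast: $y^b$ (a benign lesion is present) and $y^m$ (a
malignant lesion is present). Both can be 1 at once. No image-level or
pixel-level annotation exists; the model must learn *where* lesions are from
*whether* the breast has one.

For each image $x_k$ a convolutional backbone $f_g$ produces a feature map
$h_k \in \mathbb{R}^{h \times w \times C}$. Three heads share it:

* **Saliency maps.** A $1\times1$ convolution with 2 output channels and a
  sigmoid yields $A_k^b, A_k^m \in [0,1]^{h\times w}$, interpreted as
  approximate benign/malignant lesion locations.
* **Image-level predictions.** Each map is aggregated by *top-$t$ pooling*:
  the mean of its $n = \lceil t\,h w\rceil$ largest entries,
  $\hat y_k^c = f_{\mathrm{agg}}(A_k^c)$. Small $t$ focuses on the hottest
  cells, $t = 1$ is global average pooling. $t$ is a fraction throughout
  (the searched range is $[0.1, 0.5]$).
* **Gated attention.** Global max pooling gives a vector
  $v_k \in \mathbb{R}^C$ per image, and attention logits
  $e_k = W^\top\!\big(\tanh(V v_k) \odot \sigma(U v_k)\big)$ with
  $W \in \mathbb{R}^{L\times 2}$, $V, U \in \mathbb{R}^{L \times M}$,
  $M = C$. The benign and malignant logit columns are softmax-normalized
  independently across the $K$ images, so $\sum_k \alpha_k^c = 1$ per class.

The breast-level prediction is the attention-weighted convex combination
$\hat y^c = \sum_k \alpha_k^c\, \hat y_k^c$, which makes the forward pass
exactly invariant to permuting the image set and invariant to duplicating
every image (softmax weights halve, the weighted mean is unchanged). Both
invariances are tested at tolerance $10^{-5}$.

Training minimizes, per breast,

$$L(y, \hat y) = \sum_{c \in \{b,m\}} \mathrm{BCE}(y^c, \hat y^c)
  + \beta \sum_{k=1}^K L_{\mathrm{reg}}(A_k^c), \qquad
  L_{\mathrm{reg}}(A) = \sum_{i,j} |A[i,j]|,$$

the $L_1$ penalty discouraging saliency outside lesions. The regularizer is
summed (not averaged) over the $K$ images, as the loss is written; $\beta$
absorbs the scale. Predicted probabilities are clipped to
$[10^{-7}, 1-10^{-7}]$ so the loss is finite. The benign label participates
only through this loss (multi-task regularization); model selection and all
evaluation use the malignant head.

### Implementation

No deep-learning framework exists for R in this package's dependency set, so
the network and its training are implemented directly: im2col convolutions
on plain arrays (verified against a brute-force convolution loop), manual
backpropagation through the attention/pooling graph (verified against
central finite differences at $10^{-4}$ relative tolerance), and a
hand-written Adam optimizer ($\beta_1 = 0.9$, $\beta_2 = 0.999$) with
*decoupled* weight decay. Coupled L2 regularization would be the one-line
alternative; decoupled decay keeps the penalty independent of the adaptive
step size.

Three backbones are registered, all emitting $h \times w \times C$:

| name | structure | intended use |
|---|---|---|
| `tiny` | one stride-2 3x3 conv per halving, widths 16/32/64/... | fast experiments |
| `tiny2` | `tiny` plus a stride-1 refinement conv per level | desk-scale default (64 px, $h=w=4$, $C=32$, $L=16$) |
| `deep` | wide `tiny2` | full-scale profile (256 px, $h=w=8$, $C=512$, $L=128$) |

The full-scale parameterization in the literature is a ResNet-18; under
hand-written backpropagation a plain strided CNN is the honest equivalent we
can maintain. At phantom scale the `tiny2` refinement convs — particularly
the deep-level ones, where the lesion has been reduced to a few cells but
its margin context is integrated — are what carry the benign/malignant
shape discrimination; without them the model plateaus as a mere lesion
detector. A saliency cell's receptive field then exceeds the image, so
spatial alignment of the saliency maps is enforced by the L1 penalty
rather than by locality of the architecture.

Two further initialization choices matter and are deliberate:

* The saliency-head bias starts at $\mathrm{logit}(0.3)$, a realistic
  positive-class prevalence, instead of 0. With a zero bias the first
  epochs are spent learning the base rate through a saturating sigmoid.
* Gradients are clipped to a global L2 norm of 5 per step. Batches are one
  breast, so a single hard bag can otherwise produce a step that scrambles
  the weights.

## What the phantom generator emulates

Each phantom breast is a bag of $K \sim U\{4,\dots,12\}$ speckled grayscale
images (64 px default, 8-bit quantized). The background is a smooth tissue
field multiplied by spatially correlated Rayleigh-like speckle
(`speckle_scale` 0.35). A positive breast carries one lesion, planted in
$\max(2, \lceil 0.4K \rceil)$ of its images with small view-to-view jitter —
the remaining images are indistinguishable from negatives, which is what
makes attention necessary. Lesions are hypoechoic (interior at 0.45 of
background brightness), radius 6-11 px (at most about a tenth of the image
area). Benign lesions are smooth-margin ovals (axis ratio 0.55-0.9, soft
1.6 px edge); malignant lesions carry 5-12 angular spiculations with
irregularity amplitude 0.25-0.45 and a sharper 0.6 px margin, mirroring the
margin/shape criteria radiologists actually use. Class mix is 40/30/30
negative/benign/malignant, and 8% of malignant breasts also carry a benign
lesion to exercise the multi-label case. Grayscale is replicated to three
channels to honor the RGB input contract; color Doppler is not simulated.

The generator reproduces *compositional* difficulty (bags, partial
visibility, shape-vs-texture discrimination) but not acoustic physics:
no posterior shadowing or enhancement, no depth-dependent attenuation, no
probe-pressure deformation, no burnt-in annotations. Passing the phantom
acceptance bar therefore demonstrates that the weak-supervision mechanism
works — attention finds the lesion-bearing images and the saliency maps find
the lesions — not that any particular clinical accuracy would be attained on
hospital data.

Ground-truth lesion masks exist for evaluation only. The training-facing
accessors (`training_view()`, the bundle loader) never expose them, and a
contract test enforces that.

## The desk-scale training profile

The full-scale regime (50 epochs, 30 random-search trials over
$\eta \in 10^{[-5.5,-4]}$, $\beta \in 10^{[-3,0.5]}$,
$\lambda_{wd} \in 10^{[-6,-3.5]}$, $t \in [0.1, 0.5]$, top-3 ensembling) is
implemented and its sampler is tested against those bounds. Those learning
rates are calibrated for a large model seeing hundreds of thousands of
exams; a fresh tiny model given 200 phantom breasts and 15 epochs cannot
move at $10^{-4}$. The desk profile therefore fixes

* learning rate $10^{-3}$, weight decay $10^{-5}$, a global gradient-norm
  clip of 5,
* a two-phase schedule, exposed as `warmup_epochs` and `t_final` in
  `train_config()`: epochs 1-11 train with $\beta = 0$ and dense pooling
  $t = 0.5$, epochs 12-15 with $\beta = 3\times10^{-3}$ and sharp pooling
  $t = 0.125$. Both halves are forced by measurement: with sparse pooling
  from the start only the few pooled cells receive gradient and the lesion
  cells never enter the top-$n$, so features cannot bootstrap; and a
  nonzero regularizer before features form pushes the sigmoid saliency
  into saturation and training dies. Once the representation exists, the
  sharp-pooling/L1 phase concentrates the saliency maps without costing
  discrimination,
* no geometric augmentation: at 64 px, $\pm45°$ rotation and 0.7-1.5
  scaling routinely destroy or evict the 6-11 px lesion, and the black
  warp borders mimic hypoechoic regions. The augmentation policy itself
  (flip/rotate/translate/scale/shear with the standard ranges) is
  implemented, tested, and remains the default of `augment_config()` for
  full-scale use.
* Since random search is pointless with a fixed configuration, the tiny
  pipeline's "ensemble" trains its members from different seeds and keeps
  the top-k by validation AUROC, reusing the same selection machinery.

Model selection is by per-epoch validation AUROC of the malignant head (the
benign head is auxiliary), and the returned checkpoint is the best epoch's.

## Evaluation machinery

* **AUROC** uses the rank (Mann-Whitney) formula — the probability a random
  positive outscores a random negative, ties counting one half — and is
  checked exactly against an exhaustive pairwise oracle and against pROC.
* **AUPRC** is step-wise average precision without interpolation (ties
  grouped), matching a threshold-sweep oracle; with constant scores it
  equals prevalence.
* **BI-RADS** scores form a 6-point suspicion index (1-2 collapse to 0;
  3, 4A, 4B, 4C, 5 ascend); 0 and 6 are rejected. AUROC is invariant to any
  order-preserving recoding, which is tested.
* **Operating points** are matched to a target sensitivity or specificity by
  sweeping all achievable thresholds and taking the smallest matched rate at
  or above the target; exact ties prefer the better complementary rate. No
  interpolation between thresholds. PPV is PPV2 (cancers recommended for
  biopsy over biopsies recommended); triage points find the highest
  threshold meeting an NPV target (dismissal) or the lowest meeting a PPV
  target (escalation).
* **Hybrid fusion** standardizes reader and AI scores to zero mean and unit
  variance and averages with weight $\lambda = 0.5$; $\lambda \in \{0, 1\}$
  reproduces the single-source ranking exactly. Readers are ordinalized
  before fusion (for AUROC this choice is invisible; for AUPRC it is the
  stated convention).
* **Bootstrap CIs** resample breasts (rows) with replacement, 1000
  iterations, percentile 2.5/97.5. Patient-level clustering is ignored —
  the resampling unit is flagged as a limitation. Single-class resamples are
  redrawn; if the metric fails on more than half the draws, the computation
  aborts rather than report a hollow interval.
* **The permutation test** is one-tailed ("model a exceeds model b"): each
  trial swaps the two models' scores per case with probability one half, and
  the p-value is $(1 + \#\{\text{null} \ge \text{observed}\})/(1 + n)$ —
  add-one smoothed, hence never exactly zero. Its size is verified by
  simulation under an exchangeable null, and bootstrap coverage by a
  binormal simulation with known true AUROC.

## Cohort rules

Breast-level labels come from pathology events dated within 30 days before
to 120 days after the exam (both ends inclusive); malignant and benign
findings are matched against controlled vocabularies and a breast may carry
both labels. Test-set eligibility mirrors clinical truthing practice:
non-biopsied BI-RADS 1-2 exams need a clean follow-up at 6-24 months and no
malignancy within 15 months; BI-RADS 3 exams need either all follow-ups in
4-36 months to be BI-RADS 1-2 (at least one — the vacuous reading is
rejected) or a BI-RADS 1-3 follow-up at 24-36 months; discordant benign
biopsies must be resolved by a non-discordant biopsy or surgery within 6
months; pathology-proven cancers are excluded when assessed BI-RADS 1-2 or
diagnosed without any US-guided biopsy, and manually reviewed when BI-RADS
0/3/6 or under multi-modal guidance. `manual_review` is a first-class
verdict here because no image review is possible in code.

"Months" are 30.44-day multiples rounded to whole days, all window
endpoints inclusive; every boundary day (-30, +120 days; 4, 6, 15, 24, 36
months; 183 days after a discordant biopsy) has an explicit test on both
sides. The rule router is total: any record outside the rules' domain is
excluded with rule id `unroutable` and an audit note.

## Numerical choices and degenerate inputs

* Top-$n$ cardinality is $\lceil t\,hw \rceil$, floored at 1; value ties at
  the cutoff cannot change the mean of the selected values, so no tie-break
  is needed.
* The softmax is computed per class column with max subtraction; the
  two-vector exponential in the attention definition is read elementwise.
* The $1\times1$ saliency head is a single convolution with two output
  channels (shared pre-activation weights would be the alternative; two
  separate heads differ only in initialization symmetry).
* Zero-variance inputs to hybrid fusion standardize to all zeros with a
  warning; empty image sets, single-class AUROC inputs, unreachable
  operating-point targets and unknown finding categories raise errors that
  name the offending field.
* All randomness flows through explicit integer seeds; derived streams are
  labeled (`derive_seed(seed, "train")`), and the RNG state of the caller is
  always restored.

## Problem sizes

The shipped checks run, by choice, at desk scale: 200 training and 100
held-out phantom breasts, 15 epochs, 64 px images with a 4x4 saliency grid
(the package's acceptance bar there is held-out malignant AUROC at least
0.90 and a saliency pointing-game hit rate of at least 60% against planted
lesion masks, against a chance level of roughly the lesion area fraction,
under 10%); statistical checks use 200 simulations of 500 permutation
trials and 200 bootstrap-coverage simulations at n = 200; the reproducibility
check runs the 60/30/30 tiny pipeline twice. The `paper` profile (256 px,
`deep` backbone, 50 epochs, 30 trials) is configured but is a multi-day CPU
run; nothing in the package depends on executing it.

A subtlety worth recording: saliency upsampling respects the conv-grid
anchoring. With $3\times3$ kernels, padding 1 and stride-2 stacks, feature
cell $i$ is centered on input pixel $(i-1)\,s + 1$ (where $s$ is the total
stride), not on the center of the $i$-th tile; a uniform tile-based resize
shifts every upsampled saliency map by about half a cell, which at this
grid size is enough to push most argmax points off the lesions.

## Known limitations

* Phantom realism ends at texture and shape; no acoustic artifact modeling.
* The bootstrap ignores patient-level clustering of breasts.
* The backbone registry does not reproduce ResNet-18; at full scale this is
  a parameterization difference with unquantified effect.
* Saliency maps are $4\times4$ at the desk scale, so localization is coarse
  by construction: an oracle placing the saliency peak at the grid cell
  nearest the true lesion center scores only about 0.65 on the pointing
  game, because 6-11 px lesions are small relative to 16 px cells. The
  trained models reach about half that ceiling (roughly 3 times the ~10%
  chance level): with the backbone depth needed for benign/malignant shape
  discrimination the saliency cells' receptive field exceeds the image,
  and a detector firing at a fixed offset from the lesion is exactly as
  cheap under the loss as an aligned one. Weak-supervision localization at
  this desk scale is therefore real but far from perfect; nothing about
  the phantom scale transfers this limit to full-scale data, where the
  same architecture family is known to localize well.
* Training batches are single breasts; gradient noise is correspondingly
  high and mitigated by clipping rather than batching.
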