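---
title: "Unsupervised tissue and WMH segmentation by constrained autoencoding: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised tissue and WMH segmentation by constrained autoencoding: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Multi-sequence MRI intensities are modelled as a linear mixture of the
materials present in the brain. For channels $c = 1..C$ (e.g. FLAIR, T1-w,
T2-w) and materials $i = 1..M$ (WMH, WM, GM, CSF, optionally meninges),

$$\hat Y_c = \sum_{i=1}^{M} w_{i,c}\, S_i, \qquad
  w_{i,c} \ge 0,\; S_i \ge 0,\; \textstyle\sum_i S_i = B,$$

where $B$ is the binary brain mask and $S_i$ are soft segmentations. A
three-scale fully convolutional encoder–decoder produces $S$ through a
Softmax (so the non-negativity and sum-to-one constraints hold by
construction), the mask is applied after the Softmax, and a final 1×1×1
convolution with non-negative weights and zero bias realises the mixture.
The network is an autoencoder: it is trained, with no labels, to
reconstruct its own input sequences. Because a lesion voxel cannot be
expressed as a non-negative mixture of the pure-tissue signatures, the
optimisation is driven to dedicate a material to it; after training, the
Softmax channel whose mixing-weight signature is FLAIR-dominant *is* the
WMH segmentation.

Each convolution block is conv(3³) → leaky ReLU (slope 0.1) → batch
normalisation, in that order. Downsampling is a 2×2×2 strided convolution;
upsampling is 2×2×2 nearest-neighbour followed by a 3³ convolution
(avoiding checkerboard artifacts); encoder activations are concatenated
into the decoder at matching resolution. Filters double per scale
(`base_filters`, default 16; tests and the desk-scale protocol use 8).
Weights are Glorot-uniform, biases zero.

## Loss

The reconstruction objective is the scale-invariant cosine proximity
$f(y, \hat y) = y\cdot\hat y / (\lVert y\rVert\,\lVert\hat y\rVert)$,
applied per channel to the intensities and to their discrete Laplacian
($K$, the 27-point stencil with $-6$ centre):

$$L(Y, \hat Y) = -\frac 1 C \sum_c
  \big[ f(\mathrm{vec}\,Y_c, \mathrm{vec}\,\hat Y_c)
      + f(\mathrm{vec}\,K\!*\!Y_c, \mathrm{vec}\,K\!*\!\hat Y_c) \big].$$

Scale invariance lets the mixing weights absorb the arbitrary intensity
scale of each sequence; the Laplacian term emphasises edges and improves
robustness to slowly varying inhomogeneity. Because the problem is
ill-posed ($C < M$), an activity regulariser penalises overlap between
materials:

$$\Omega(S) = \frac{\alpha}{M} \sum_{i=1}^M \sum_{j=1}^M
  f(\mathrm{vec}\,S_i, \mathrm{vec}\,S_j).$$

The double sum is implemented exactly as written, diagonal included; the
diagonal terms are constants with zero gradient, so they affect reported
loss values but not training. $\alpha$ defaults to 0.0075 (the
four-sequence setting; 0.02 is the documented two-sequence setting).
A norm floor $\varepsilon = 10^{-8}$ in $f$ guards all-zero vectors
(empty materials, all-background patches). Note the floor makes an
identically zero map contribute $\approx 0$ rather than 1 to its own
diagonal, so the regulariser mildly favours *empty* maps over overlapping
ones — a property worth knowing when a material genuinely absent from the
data (e.g. meninges without a T2/PD channel) silently disappears.

## Optimisation

Adam with Nesterov momentum ("Nadam") with $\beta_1 = 0.9$,
$\beta_2 = 0.999$, learning rate $10^{-3}$, batch size 1, and a momentum
schedule $\mu_t = \beta_1\,(1 - 0.5\cdot 0.96^{\,t\,\psi})$ with schedule
decay $\psi = 0.004$. The update, per step $t$ (products
$\Pi_t = \prod_{s\le t}\mu_s$):

$$m \leftarrow \beta_1 m + (1-\beta_1) g,\quad
  v \leftarrow \beta_2 v + (1-\beta_2) g^2,$$
$$\bar m = (1-\mu_t)\,\frac{g}{1-\Pi_t} + \mu_{t+1}\,\frac{m}{1-\Pi_{t+1}},\quad
  \theta \leftarrow \theta - \eta\,\frac{\bar m}{\sqrt{v/(1-\beta_2^t)}+\epsilon}.$$

After every step the mixing weights are clipped at zero (projected
gradient); the mixing bias is fixed at zero and never trained. Training
augments each input patch with i.i.d. Gaussian noise (sd 0.05) followed by
per-channel scaling by $\mathcal N(1, 0.5^2)$ scalars (not truncated at
zero); the reconstruction target stays clean, and the brain mask is taken
from the clean input patch — binarising the noise-augmented input would
make the mask all-ones.

Batch normalisation with batch size 1 uses per-patch statistics during
training. At prediction time, `predict_volume` also uses per-patch
statistics by default rather than frozen running averages: with few
batch-size-one training patches the learned features are conditioned on
per-patch normalisation, and the frozen averages misnormalize
background-heavy windows (on the same trained network, matched-material
mean Dice was 0.53 with whole-volume/running-average inference, 0.63
sliding-window/running, 0.74 sliding-window/per-patch). Prediction should
use the training patch size and stride; running averages remain available
via `bn_mode = "running"`.

## The phantom

All tests run against a synthetic phantom: nested ellipsoidal compartments
(an off-centre ventricle-like CSF core, WM interior, GM shell, and for
$M = 5$ a thin meninges rim) plus lesions inside the WM at a configurable
fraction of the WM volume (default 5%). The lesion geometry follows the
clinical WMH phenotype: large confluent periventricular caps adjacent to
the ventricle surface carry most of the load, with punctate deep-WM blobs
for the remainder — chosen because a cohort in which no region is ever
lesion-dominant would under-represent exactly the signal the unsupervised
factorisation relies on. Hard maps are blurred (Gaussian, $\sigma = 1$
voxel — partial volume) and renormalised so that the maps sum to exactly
1 inside the mask. Channels are synthesised generatively from the mixture
equation with a fixed non-negative weight matrix whose rows mimic
FLAIR/T1/T2 contrast (CSF T2-bright and FLAIR-dark, WM T1-bright, GM
FLAIR-brighter than WM, WMH FLAIR-dominant and T1-dark), optionally
multiplied by a smooth positive bias field $\exp(g)$ (smoothed white
noise, rescaled to a maximum log-amplitude, mean one over the mask) and
degraded with additive Gaussian noise before clipping at zero.

**Identifiability of the mixing matrix.** Full rank is not enough for the
ground truth to be recoverable: if any material row is a non-negative
combination of the other rows, exact alternative factorisations of the
data exist and no optimiser can be expected to prefer the generating one
(an early version of the default weights had the GM row *exactly* inside
the cone of CSF/WM/WMH, and training reproduced the data perfectly while
mixing the maps). The default matrix therefore makes each of the four
principal rows an extreme ray of their joint non-negative cone (minimum
relative NNLS residual 0.26; condition number 2.9), a property asserted
by a unit test. The meninges row is interior — matching that class's
tendency to vanish from trained models.

What the phantom does *not* emulate: MRI acquisition physics, Rician
noise, anatomy (gyri, sulcal CSF), motion or registration error. Passing
the phantom recovery tests therefore demonstrates that the estimator and
its optimisation behave as designed on data that satisfy the model's
assumptions — not that any particular clinical accuracy is attained.

## Desk-scale training protocol

The reference protocol trains on 80×80×80 patches with stride 40 from 30
subjects — tens of thousands of gradient steps. The test suite scales
this to a single 48³ phantom: `base_filters` 8, 16³ patches extracted
with stride 8 (50 selected patches per epoch), 50% patch selection, and
80 epochs (20-epoch rounds inside the refinement loop). Patch size and
stride are the two knobs that control the number of gradient steps per
epoch; with a single training volume, a small stride substitutes for the
missing subject diversity. Convergence of the matched-material Dice is
monotone in total gradient steps (≈0.6 at 1000 steps, ≈0.7 at 2000,
≈0.9 at 4000).

The loss landscape has observable stages: channel-scale matching (cosine
> 0.98 within a few epochs), separation of the dominant tissues, and
last, the small-volume materials (CSF core, lesions). The final stage is
*bistable* at this scale: the activity regulariser is indifferent between
the true factorisation and a configuration where two Softmax channels
split one tissue spatially (their overlap is zero either way), and it
erects a barrier between the two (merging requires transient overlap).
The only force pulling toward the lesion material is its reconstruction
gain, a few thousandths of the loss at a 5% lesion load. Some runs
therefore finish with the lesion channel active (mean matched Dice
0.90–0.95) and others with it folded into a duplicate tissue map (mean
≈0.74); which basin a run lands in is sensitive to initialisation at the
level of floating-point rounding. At full scale the gain is
integrated over vastly more steps and subjects, which makes escape
reliable for the lesion class, though the mild form of the phenomenon —
a minor material such as the meninges failing to appear when few
sequences constrain it — persists even there. The mixing-layer
initialisation rejects clipped Glorot draws that would start an entire
channel column or material row at zero — a dead-channel trap the
projection cannot cleanly escape.

## Bias-field estimation

The inhomogeneity loop alternates segmentation and correction: predict
soft maps, form the pure-tissue probability mask (CSF+GM+WM, i.e.
$1 - S_{\rm WMH} - S_{\rm MENINGES}$ under sum-to-one), estimate a smooth
multiplicative field per channel, divide it out of the *targets*, and
retrain from scratch with the original inputs — so the final network
segments uncorrected images directly.

The estimator is deliberately lightweight (the classical N4 algorithm is
treated as a replaceable external tool, not reimplemented). Inside the
refinement loop the network's own reconstruction provides a clean
reference and the field is fitted to
$\log(\text{volume}/\text{reference})$. Stand-alone (no reference), the
estimator first flattens tissue contrast: cluster the residual
log-intensities (k-means with deterministic quantile initialisation),
subtract class means, down-weight partial-volume voxels far from their
class centre. Either way the smooth field is estimated by *backfitting* —
repeatedly adding a weighted Gaussian smoothing of the residual to the
running log-field (default 4 iterations, kernel 6 voxels) — because a
single kernel pass shrinks the field amplitude substantially (a σ=12
single pass recovered only ~20% of a synthetic field that backfitting at
σ=6 recovers to ~75% with an oracle reference). Fields are normalised to
weighted mean 1 — the overall gain is not identifiable and is absorbed by
the scale-invariant loss.

A measurement caveat discovered with an oracle experiment (dividing by the
*true* field): WM coefficient-of-variation is only a meaningful
bias-correction metric on the channel where WM carries its principal
contrast (T1-like). On T2-like channels, partial-volume mixing with bright
CSF leaves a CoV floor larger than half the biased CoV, so no correction —
not even with the exact field — can halve it. The tests therefore measure
WM CoV on the T1-like channel.

## Inference and post-processing

Whole volumes are predicted with a sliding window on the same clamped
grid as patch extraction, averaging Softmax outputs over overlapping
voxels; averaged maps are renormalised inside the mask to restore
sum-to-one exactly. The WMH map is binarised with a *strict* threshold
(default 0.5; 0.87 is the documented two-sequence setting) and connected
components smaller than 3 voxels are removed (26-neighbourhood by
default, shared with the lesion-wise metrics so component counting is
internally coherent).

## Numerical conventions

* Percentiles (the p99 normaliser, the H95 quantile): linear
  interpolation between order statistics (`quantile` type 7).
* Binarisation: strictly greater than the threshold.
* Patch grids: origins at stride multiples, the last origin clamped to
  touch the boundary; volumes smaller than the patch are zero-padded
  symmetrically.
* Background (for patch selection and the brain mask): a voxel where
  every channel is exactly zero.
* H95 is computed on full voxel sets, not extracted surfaces, and is
  undefined (NA) when either mask is empty.
* AVD is reported both as a fraction and ×100.
* Components/permutations: material-to-truth matching maximises mean
  Dice by exhaustive permutation search (M ≤ 8).
* All stochastic steps (phantom, initialisation, shuffling, augmentation)
  run under explicit seeds; reruns are bit-identical on a fixed platform.

## Known limitations

* The convolution stack is implemented in R/C++ for CPU; it is adequate
  for desk-scale volumes but not for production-size cohorts.
* With fewer channels than materials the factorisation is only as
  identifiable as the regulariser makes it; a material can converge to an
  empty map (see the loss section) — on real data the recommended check
  is the mixing-weight signature of every Softmax channel.
* The maskless bias estimator assumes the weight mask covers tissues
  whose log-intensities form separable clusters; heavy pathology breaks
  this, which is exactly why the refinement loop feeds it the model
  reconstruction as a reference instead.
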