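---
title: "Micro-expression recognition from onset/apex optical flow: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-expression recognition from onset/apex optical flow: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Micro-expressions are involuntary facial movements lasting well under half
a second, with displacements of at most a few pixels on a cropped face.
flowMER implements a complete recognition pipeline for such clips: apex
spotting, dense motion extraction, a three-branch attention network, an
imbalance-aware loss, and leave-one-subject-out (LOSO) evaluation. This
vignette explains the models, the tunable parameters, and the design
choices that were genuinely open, and records what the bundled synthetic
benchmark does and does not establish.

## From frames to flow triplets

A sample is represented by two frames only — the onset (neutral) frame and
the apex (maximal-intensity) frame. When the apex index is not annotated,
`locateApex()` spots it: the face is divided into three fixed fractional
regions (mouth, left eye+brow, right eye+brow), each frame's uniform LBP
histogram (8 neighbors, radius 1, "neighbor >= center", 58 uniform bins +
1 pooled bin) is compared with the first frame by the chi-squared distance
with an additive guard of 1e-10, and the region with the largest peak
difference is searched by halving: the index range is split, recursion
follows the half with larger mean difference, and the argmax of the final
window (at most 3 frames) is returned, ties toward the lower index. Fixed
fractional boxes stand in for facial landmarks, which are out of scope;
`RoiSpec`-style overrides are accepted by every entry point. A completely
static sequence returns the second frame with a degeneracy flag rather
than an error, so batch preprocessing never stalls.

A sensitivity point worth knowing: the radius-1 LBP code responds to
sub-pixel texture shifts roughly linearly only up to about half a pixel;
beyond that the histogram difference saturates, the tent-shaped intensity
ramp maps to a plateau, and the argmax wanders within it (we measured hit
rates dropping from ~95% at 0.4 px peak displacement to ~50% at 2 px on
the synthetic sequences). The apex-spotting oracle therefore exercises the
spotting algorithm at 0.4 px peak deformation — the regime the descriptor
is designed for; real spotting pipelines equally rely on the apex search
being driven by the *relative* difference curve rather than its absolute
scale. Even in-regime, adjacent near-apex frames differ by only a few
hundredths of a pixel, so a one-frame tolerance is inherent.

Dense motion between onset and apex is computed with a duality-based TV-L1
solver written for this package: a coarse-to-fine pyramid (factor 0.5,
Gaussian pre-smoothing, coarsest level at least 16 px), five warps per
level, and an inner loop alternating a pointwise shrinkage of the
linearized brightness-constancy residual with a Chambolle-style dual
ascent on the total-variation term. Defaults `lambda = 0.15`,
`theta = 0.3`, `tau = 0.25` assume intensities rescaled to [0, 255], which
the solver does internally. The solver sits behind `computeOpticalFlow()`
so any dense method meeting the translation-recovery contract (median
error at most 0.25 px on a shifted texture) could be substituted. Frames
are resized to the working face resolution 170 x 140 before flow.

Optical strain is the magnitude of the symmetrized displacement Jacobian,
`os = sqrt(exx^2 + eyy^2 + 2 exy^2)`, computed by central differences
(one-sided at borders). Both off-diagonal terms are counted, the standard
reduction in the optical-strain literature. Strain is exactly zero under
rigid translation, which is why it isolates muscle deformation from
residual head motion.

The network input is a 3 x 28 x 28 triplet (u, v, os). Each channel is
min-max normalized to [0, 1] per sample — no dataset-level statistics
exist for arbitrary user data, so nothing needs calibration — and
bilinearly resized. A constant channel maps to 0.5, placing "no signal"
at the channel midpoint; the same rule makes a zero-motion sample an
all-0.5 triplet rather than noise.

## The three-branch attention network

Each channel enters its own branch: two inception blocks (parallel 1x1,
1x1-reduce + 3x3, 1x1-reduce + 5x5, and 3x3-maxpool + 1x1 paths, ReLU,
concatenated; 6 kernels per scale in block one, 16 in block two, each
block followed by 2x2 max pooling), giving 24-channel 14x14 and 64-channel
7x7 maps. The multi-scale fusion module (MSFF) joins them: the shallow map
is 2x2-pooled, aligned to 64 channels by a 1x1 convolution, summed with
the deep map and passed through a spatial attention module (SAM:
channel-mean and channel-max maps, a 7x7 convolution, a sigmoid gate
multiplying the input); the deep map passes through its own SAM; the two
gated maps are concatenated to 128 channels. Where the fusion wiring was
ambiguous we sum the aligned shallow map with the deep map *before* its
SAM; the alternative (gating first, summing after) was noted and not
taken, since gating the sum lets the attention see both scales at once.

The three 128-channel maps are then reweighted against each other
(MOFRW): one squeeze-excitation channel-attention module (reduction 4),
with a single shared set of weights, scores each branch; the three score
vectors compete through a softmax across branches (not across channels),
so the per-channel weights of u, v and os always form a 3-way probability
simplex; each map is scaled by its weights and added back to the
concatenated maps as a residual. Sharing one CAM is what the single CAM
function in the module's formulation implies, and it yields a clean
testable symmetry: identical branch inputs receive weights of exactly 1/3.

The head is a global average pool over the 384-channel map and one fully
connected layer — the minimal head for datasets of a few hundred samples.
Weights are He-normal, biases zero, all seeded; the 1x1-reduce widths
equal the per-scale kernel count. These head/width choices are ours; the
architecture source fixes only the per-scale kernel counts.

There is no deep-learning runtime in the package's dependency set: the
forward and backward passes are written out by hand over (H, W, C, B)
arrays, with convolution/pooling kernels in compiled code. Every gradient
is verified against central finite differences (relative tolerance 1e-3)
in the test suite, for parameters and for input pixels.

## Logit-adjusted loss for class imbalance

Micro-expression corpora are heavily skewed. Training uses logit-adjusted
softmax cross-entropy (LASCE): class priors `p_y` are the label
frequencies of the current training split (never of test subjects),
correction factors are `a_y = log(p_y^tau + eps)` with `tau = 0.5` and
`eps = 1e-12`, and the loss is standard cross-entropy on `logits + a`,
in log-sum-exp stable form. At `tau = 0` all factors are equal and the
loss is ordinary cross-entropy, a property the tests assert. The printed
form of the loss in the source material weights the log-softmax by
`(p_ij + a_j)` summed over all classes, which is not a proper
cross-entropy and contradicts its own `tau = 0` equivalence claim; we
implement the standard label-indexed form, which satisfies it. Plain
cross-entropy, focal loss (`gamma = 2` default) and logit-adjusted focal
loss are provided for ablation, with the analytic gradients of all four
checked against finite differences.

## Training and evaluation protocol

Defaults follow the published recipe: Adam, learning rate 1e-4, weight
decay 1e-4 (added to the gradient), batch size 8, 70 epochs, no schedule
and no early stopping. Augmentation applies horizontal flips — on a
normalized triplet the u channel flips as `1 - mirror(u)`, v and os
mirror unchanged — and per-channel affine dithering (scale 0.9-1.1,
shift ±0.05, clipped). One seed drives initialization, shuffling and
augmentation; per-fold seeds are derived from the run seed, so an entire
LOSO report reproduces bit-for-bit on CPU.

Evaluation is leave-one-subject-out: one fold per subject, ordered by
subject id. Predictions are pooled over folds into a single confusion
matrix; per-class recall and F1, their unweighted means (UAR, UF1), and
pooled accuracy are computed from it. Mean per-fold accuracy is reported
alongside, since "accuracy" is ambiguous in the literature; the headline
is the pooled value. Classes absent from every test fold are dropped from
the macro averages with a warning rather than silently scored zero.

## The synthetic benchmark

Licensed micro-expression corpora cannot be redistributed, so the package
ships a generator instead. A sample's ground-truth flow is a sum of
Gaussian displacement bumps at class-specific facial loci (amplitude 2 px,
radii 8-12% of the frame), plus a subject-level random affine flow (SD
0.2 px, 10% of the amplitude, shared by all samples of a subject so LOSO
generalization is non-trivial) and i.i.d. Gaussian flow noise (SD 0.1 px,
a twentieth of the amplitude). Sequences for apex spotting warp a smooth
random texture (Gaussian-filtered white noise, sigma 2 px, the texture
every flow solver needs) by the class flow scaled with a tent ramp peaking
at `round(apexFrac * (seqLen - 1)) + 1`; warping is inverse bilinear with
replicated borders. Ten subjects and 30 samples per class form the default
3-class benchmark; the 5-class imbalance testbed uses counts
[60, 32, 27, 25, 102], the skew shape of a well-known corpus.

The class definitions went through genuine design iterations worth
recording. Classes must be invariant under horizontal mirroring, because
flip augmentation presumes the bilateral symmetry of facial actions — an
early draft with left/right-lateralized classes was unlearnable *by
construction* (flipping turned one class into another). Classes must also
differ in motion-direction composition, not merely in bump position: the
global-average-pool head makes the classifier largely translation
invariant, so position-only classes are indistinguishable to it, exactly
as two action units with identical direction fields at different sites
would be. The final patterns (jawDrop, browRaise, noseWrinkle, smilePull,
lipPress) differ in vertical-motion sign composition and lateral
structure.

What the benchmark does not emulate: photometric noise, illumination
flicker, head pose drift, landmark jitter, or the rich texture statistics
of real faces. Passing the end-to-end tests shows the pipeline is wired
correctly and that the loss behaves as designed under imbalance; it does
not certify recognition rates on real corpora.

## Problem sizes and numerical choices

The shipped evaluations are sized for a single CPU: the end-to-end LOSO
benchmark trains 10 folds x 30 epochs on 90 samples (about four minutes),
and the imbalance comparison trains five seeds x two losses for 15 epochs
on a fixed two-subject hold-out of the 246-sample skewed set, scoring the
mean recall of the minority classes (those with below-average counts:
32, 27 and 25 of 246); each seed redraws the dataset's subject effects
and the training randomness, so the comparison averages over both
sources of variation. Thirty
epochs is a smoke-test budget: the same run converges to 100% at the full
70-epoch recipe, and the reduced budget already clears 0.95 pooled
accuracy. Tolerances: solver stopping 1e-2 on the mean flow update;
min-max degeneracy guard 1e-12; chi-squared guard 1e-10; softmax
computations in subtracted (log-sum-exp) form throughout. Argmax
predictions break ties toward the lower class index; the divide-and-
conquer apex search breaks ties toward the lower frame index.

## Grad-CAM and a known limitation

`gradCam()` explains a class logit at the post-MOFRW feature map: channel
weights are spatially averaged gradients, the weighted sum is rectified,
upsampled to 28 x 28 and min-max normalized (an all-constant map returns
zeros). With a GAP + linear head the channel weights are proportional to
the head's weights, which makes the heatmap an exact spatial read-out of
class evidence — and exposes a real property of the synthetic benchmark:
because per-sample min-max normalization maps the zero-motion background
to a class-dependent level (class flows have signed direction
compositions), a spatially *uniform* background statistic is itself
discriminative, the network uses it, and the heatmap argmax is then
decided by padding-driven border fluctuations rather than by the motion
locus. On noise-free data (no background to amplify) the peaks return to
the motion loci. Class designs that remove the global cue restore
localized evidence in principle but are not learnable within the
30-epoch smoke budget, so locus-level Grad-CAM localization and fast
smoke-test learnability are jointly unattainable on this benchmark; the
localization check is reported as failing rather than redefined. On real
faces, where background flow is not an i.i.d.-noise artifact of
normalization, this shortcut is far weaker.

## Known limitations

- The flow solver is tuned for small displacements (a few pixels);
  large-motion clips would need a deeper pyramid.
- Apex spotting assumes a single activity peak; multi-peak sequences
  return the dominant half's maximum.
- Face detection, landmarking and cropping are out of scope; inputs are
  pre-cropped faces, and a cropping hook can be layered in front of the
  manifest reader.
- The hand-written network is sized for 28 x 28 inputs and this
  architecture; it is not a general-purpose training framework.
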