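---
title: "Resolution-invariant MRI denoising: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolution-invariant MRI denoising: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Magnitude MR images are reconstructed from two quadrature channels, each
carrying zero-mean Gaussian noise. The magnitude operation makes the noise
Rician: a noise-free intensity $A$ is observed as
$M = \sqrt{(A+n_1)^2 + n_2^2}$ with $n_1, n_2 \sim \mathcal N(0, \sigma^2)$,
whose density is

$$p(M) = \frac{M}{\sigma^2}
  \exp\!\Big(-\frac{M^2 + A^2}{2\sigma^2}\Big)
  I_0\!\Big(\frac{AM}{\sigma^2}\Big).$$

In signal-free background ($A=0$) this is Rayleigh (mean
$\sigma\sqrt{\pi/2}$); at high SNR ($A/\sigma > 3$) it is approximately
Gaussian centred near $\sqrt{A^2+\sigma^2}$. `rice_pdf()` evaluates the
density through the exponentially scaled Bessel function so that large
$AM/\sigma^2$ does not overflow; `rice_cdf()` integrates it numerically
(trapezoid on 8192 points, error around $10^{-7}$), which is accurate
enough to drive Kolmogorov–Smirnov goodness-of-fit tests against simulated
noise.

High-resolution acquisitions trade voxel size against noise floor, and a
denoiser trained at one voxel size usually degrades at another. The model
here addresses that with a *latent resolution normalization*: feature maps
are bilinearly rescaled by $F = R_o / R_i$ between the native in-plane
resolution $R_o$ and a fixed internal resolution $R_i$ (1.0 mm by
default), so almost all of the network operates at a normalized anatomical
scale regardless of the input grid.

## Conforming

All volumes pass through a canonicalization ("conforming") stage:

1. reorient to RAS (pure axis permutation/flips);
2. resample every axis to `max(dim)` samples by linear interpolation with
   the half-pixel-centre convention (no corner alignment, no recomputation
   of scale factors); the recorded isotropic voxel size is
   `min(voxel_size)`;
3. rescale intensities to 8-bit through a clipped histogram: 1000 bins,
   ceiling at the smallest bin edge above which at most 1/1000 of the
   voxels lie, values rounded to integer gray levels, then mapped linearly
   to $[0,1]$.

Two numerical choices deserve a note. First, when the data contain an
extreme outlier (orders of magnitude above the bulk), the whole bulk falls
into the first histogram bin and a single pass would collapse the dynamic
range; the histogram is therefore rebuilt on the clipped range whenever
the ceiling halves the range (a standard robust-range iteration, at most
10 passes). Second, conforming is exactly idempotent by construction: a
volume that is already cubic, isotropic, RAS, and quantized on the 8-bit
$[0,1]$ lattice passes through unchanged, because re-clipping an already
normalized histogram can only shift values by quantization artifacts.
A constant-valued volume maps to all zeros (documented degenerate case).

## Network

The denoiser is residual: it predicts the *noise* of the middle slice of a
7-slice slab (2.5D input), and the prediction is subtracted from that
slice. The architecture is a nested (UNet++-style) encoder–decoder with
seven resolution rows:

* row 0 works at the native resolution; its first block (`CBU_0,0`) is the
  only part of the network that sees native-scale features;
* row 1 works at the internal resolution, reached by bilinear rescaling
  with $F = R_o/R_i$;
* rows 2–6 are reached by 2×2 max pooling (stride 2) with argmax indices
  passed to the matching unpooling stage.

Each convolutional block unit (CBU) runs three 3×3 convolutions (padding
1, so spatial shape is preserved) with PReLU non-linearities (one
learnable slope per channel), one internal maxout, and optional batch
normalization. Merges between blocks use *maxout* — the elementwise
maximum across inputs — so the filter count stays constant (`n_filt`,
default 64) everywhere; a nested block at row $i$, column $j$ merges the
unpooled block $(i{+}1, j{-}1)$ with all same-row predecessors
$(i, 0..j{-}1)$. Row 0's six columns merge the up-rescaled row-1 block
with all row-0 predecessors and end in a 1×1 output head, yielding six
residual noise candidates $Y_1..Y_6$. The final residual is their weighted
average with six trainable scalars $\lambda_N$ (initialized to 1):
$Y = \sum_N \lambda_N Y_N / \sum_N \lambda_N$; the combination degenerates
(and raises an error) only if $\sum\lambda_N$ reaches zero.

Implementation notes, where the design was genuinely open:

* The nested blocks exist for rows $i = 1..5$ and columns $j = 1..6-i$;
  this is the index range required for the six row-0 heads to be
  computable.
* Spatial dims that are not divisible by $2^5$ after the latent rescale
  are zero-padded to the next multiple of 32 and the result is cropped
  back, so any slab of side ≥ 16 passes through.
* Batch normalization is off by default: image-regression work
  consistently reports train/eval statistic gaps and output artifacts at
  small batch sizes, and the retained long-training configuration of this
  family of models drops it. When enabled, statistics are per-stack at
  train time (the engine processes batch items singly) with running
  moments used in eval mode.
* With filter doubling (the UNet++-like growth used by the heavier
  variant and by the plain encoder–decoder comparator), the stack being
  unpooled has twice the channels of the stored pooling indices; index
  channels are recycled, and a learned 1×1 projection channel-matches
  inputs at maxout merges.
* $\lambda_N$ are unconstrained reals, trained jointly, and excluded from
  weight decay (they are normalizers, not features).

Two comparator architectures ship with the package: a 17-layer
multi-channel DnCNN (64 filters, 3×3, batch-norm + ReLU on the hidden
layers, residual output) and a five-level plain encoder–decoder with the
same latent rescaling and CBUs but concatenating skips and filter doubling
from 32 to a 512-filter bottleneck.

All forward and backward passes run on compiled (RcppArmadillo) kernels —
im2col convolution, pooling/unpooling with indices, bilinear resizing and
its adjoint — under a small reverse-mode tape. Every kernel's gradient is
exercised against finite differences in the test suite indirectly through
the training tests; the tape makes training deterministic given the seed.

## Noise simulation and training regimes

Training noise is Rician with a base sigma expressed as a fraction of the
unit intensity range (noise is added after conforming). Three regimes are
provided: `standard` draws sigma uniformly in [0, 0.09] and pairs it with
a *spatially variable* field; `refine_low` ([0, 0.04]) and `refine_high`
([0.04, 0.09]) use stationary fields and are meant for second-stage
refinement on top of a frozen first-stage model.

The variable field is specified only by its endpoints — ×3 in the volume
centre, ×1 at the outermost voxels, cubic interpolation in between — so a
concrete geometry had to be chosen: a 3×3×3 control lattice (centre 3,
boundary 1) expanded by separable natural-spline (tricubic) interpolation
and clamped at ≥ 1. This makes every boundary voxel exactly ×1, the centre
of an odd grid exactly ×3 (27% of the range at base sigma 9%), and the
field mirror-symmetric about each midplane.

A uniform sampler almost surely never draws sigma exactly 0, yet seeing
noise-free inputs during training is what keeps the trained model close to
the identity on clean data. `train_config(zero_noise_frac = 0.125)`
therefore trains that fraction of samples at sigma = 0 while the sampler
itself stays purely uniform.

During training, noise is realized lazily on the extracted (and possibly
cropped) slab rather than the full volume; since the noise is i.i.d. per
voxel this is identical in law and an order of magnitude cheaper per step.
Noise is re-drawn fresh at every step from a seed derived from
(global seed, step, batch index), so epochs never reuse realizations.

## Augmentation

Horizontal flips (probability 0.5), in-plane rotations uniform on
[−5°, +5°] (bilinear, zero fill — background is air after conforming),
and inner-scale augmentation: a zero-mean Gaussian offset
$\mu \sim \mathcal N(0, 0.1)$ added to the latent rescale factor $F$ per
training sample, redrawn from a derived sub-stream in the rare event
$F + \mu \le 0$. The same flip decision and angle are applied to the input
slab and the clean target, which the tests verify with a fiducial-voxel
check.

## Losses and metrics

MAE, MSE and PSNR ($10\log_{10}(\mathrm{MAXI}^2/\mathrm{MSE})$, with an
infinity sentinel at zero MSE) follow their closed forms. SSIM uses the
standard 11×11 Gaussian window (σ = 1.5), $k_1 = 0.01$, $k_2 = 0.03$, and
$c_3 = c_2/2$ so the contrast and structure terms collapse into the usual
two-factor index. MS-SSIM uses the printed five-scale exponents
(0.0448, 0.2856, 0.3001, 0.2363, 0.1333) renormalized to the first $M$
scales ($M = 2$ by default), contrast–structure means at scales
$1..M{-}1$, and the full SSIM mean at the coarsest scale — the combination
under which $M = 1$ reduces exactly to single-scale SSIM. Negative
per-scale terms are clamped at zero before exponentiation so the index
stays real.

The perceptual losses compare feature maps $\Phi_l$ of a small
convolutional extractor: mean absolute feature difference (the
feature loss) or mean squared difference (the LPIPS-style distance), on
the first layer by default, with grayscale slices channel-replicated to 3.
Pretrained classifier weights are deliberately not bundled; the default
extractor uses fixed seeded random convolutions, which is fully
deterministic, self-contained, and a recognized test double for deep
perceptual metrics — but it is *not* the published human-calibrated
metric, and absolute values are not comparable to published LPIPS numbers.
Requesting `origin = "pretrained_classifier"` raises an instructive error.

`paired_compare()` wraps paired t-tests against a reference method with
Benjamini–Hochberg FDR correction and labels methods better/worse/ns at
q < 0.05; a method identical to the reference is reported as ns with
p = 1 rather than an undefined t statistic.

## Training settings

AdamW ($\beta_1 = 0.9$, $\beta_2 = 0.99$, decoupled weight decay 0.01)
under a one-cycle schedule: cosine ramp from `max_lr/div_factor` (0.001)
to `max_lr` (0.01) over the first 7.5% of steps, cosine annealing to
`0.001/100 = 1e-5` over the remainder. Momentum cycling is mapped onto
$\beta_1$, moving 0.95 → 0.85 → 0.95 opposite the learning rate. The
refinement stages use a fixed learning rate of 1e-6. `mixed_precision`
emulates reduced-precision training by rounding forward activations to
IEEE single precision (R has no native half-precision arithmetic); it
changes no shape contract and moves the toy-run loss by well under 10%.

Training uses axial slabs only; the three-plane view aggregation — running
the same weights once per anatomical plane and averaging the three
denoised volumes voxelwise — is inference-only, and removes the
plane-specific streaking that single-plane 2.5D denoising produces.
Edge slices use replication padding. Outputs are clamped to [0, 1] before
export and stay in conformed space unless a native-grid resample is
requested.

## Synthetic phantoms

The phantom generator emulates a multi-tissue head: nested ellipsoids
(CSF/head 0.30, a thin bright shell 0.95 standing in for cortex, gray
matter 0.75, white matter 0.55, a ventricle 0.15) over zero background,
plus smooth low-frequency texture (amplitude 0.02) and a smooth
multiplicative bias field (amplitude 0.05, deliberately retained — the
pipeline performs no bias-field correction). The bright thin shell gives
the denoiser a high-frequency structure to destroy, so over-smoothing is
visible in SSIM and the feature losses. Deterministic given the seed.

What the phantoms do *not* emulate: k-space acquisition, point-spread
functions, motion/ghosting, spatially correlated or coil-map noise,
anatomical variability. Passing tests on phantoms therefore demonstrates
that the pipeline's mechanics (geometry, noise law, optimization, shape
contracts) are correct — not that the trained toy models match
state-of-the-art denoising quality on real brains, which requires the
full training corpus and schedule.

## Problem sizes used by the test suite

The suite trains a 16-filter, 7-row model for 400 optimization steps
(batch 2, 32×32 crops) on ten 64-cube phantoms — the scale a reviewer can
re-run on one CPU core in minutes — and checks a ≥ 3 dB PSNR gain over the
noisy input at sigma = 5% on a held-out phantom, together with
identity preservation on clean input: the clean-input reconstruction
error, added in quadrature to the denoising error, must cost less than
0.5 dB, and the absolute drift must stay below 1% MAE. Smaller
configurations (4 filters, 4 rows, 16×16 crops) cover convergence,
determinism, refinement wiring, and mixed-precision contracts.

## Known limitations

* The engine is CPU-only and single-threaded; full-scale training (tens
  of epochs over real MRI corpora) is out of reach by design.
* The LPIPS-style distance uses seeded random features, not the published
  calibrated network.
* Batch statistics are per-stack when batch normalization is enabled.
* Checkpoints are an R serialization with a version stamp
  (`mridenoise-ckpt-1`); compatibility with other implementations' weight
  files is not attempted.
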