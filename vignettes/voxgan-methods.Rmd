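---
title: "Reconstructing anatomical volumes with a conditional 3D GAN: models, losses and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing anatomical volumes with a conditional 3D GAN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Tomographic modalities (CT, MRI) deliver a 3D anatomical structure as an
ordered stack of 2D slices. Reconstructing a dense volumetric model from
such a slice set -- and doing so in a way that preserves not just the outer
surface but the interior density structure and the vertical correlation
between neighboring slices -- is the task this package addresses. The core
object is a **volume**: a dense grid of voxel intensities, shape
$(l, w, h)$ for the x, y, z resolutions, normalized to $[0, 1]$. Voxels
enumerate in raster order (x fastest, then y, then z), which in R is simply
the column-major order of a `dim = c(l, w, h)` array; slice $k$ (1-based in
this API) is the $xy$-plane at $z = k$.

The reconstruction model is a **conditional GAN**: a generator $G$ maps a
conditioning image set $I_G$ (the slice stack, possibly sparse or noisy) to
a candidate volume $\hat V$, and a discriminator $D$ scores (condition,
volume) pairs for authenticity. Training minimizes least-squares
adversarial objectives

$$L_G = \mathbb{E}\big[(D(x,\hat v)-\tfrac12)^2\big] + \alpha\, L_{recon},
\qquad
L_D = \mathbb{E}\big[(D(x,v)-\tfrac12)^2 + D(x,\hat v)^2\big],$$

with the real target $\tfrac12$, the fake target $0$, and the generator
driving fake scores toward $\tfrac12$. These targets are implemented
exactly as stated, not silently corrected to the more conventional LSGAN
$1/0/1$ targets; the conventional variant stays available through
`loss_config(lsgan_targets = "standard")`.

## The composite reconstruction loss

The adversarial signal alone does not pull a high-dimensional volume onto
an anatomical shape, so the generator objective adds a reconstruction loss
with weight $\alpha$ (default 33):

$$L_{recon} = L_{dist} + L_f + L_{sim}.$$

**Distance.** $L_{dist}$ is the mean absolute voxel difference (L1). With
an anatomical model occupying a minority of the grid, L1 alone averages
intensities down and washes out the high-density structures.

**Feature.** $L_f$ counters that by scoring the overlap of *high-value
voxel sets*. For thresholds $t_s$, $s = 1..N_r$,

$$L_f = 1 - \frac{1}{N_r}\sum_s
 \frac{|\{m : v[m] \ge t_s \wedge \hat v[m] \ge t_s\}|}
      {|\{m : v[m] \ge t_s \vee \hat v[m] \ge t_s\}|},$$

i.e. one minus the threshold-averaged Jaccard index of the supra-threshold
sets. Two conventions deserve a note. First, the sum over thresholds is
normalized by $N_r$ by default (`normalize_feature_by_nr = TRUE`) so that
$L_f$ stays on the unit scale of the other two terms; the raw sum is
available by flag. Second, a threshold at which *neither* volume has any
voxel above $t_s$ contributes overlap 1: two volumes agreeing that nothing
exceeds $t$ should not be penalized, and this convention avoids 0/0. The
default threshold set $\{0.2, 0.4, 0.6, 0.8\}$ spreads evenly over the
intensity range; it is a package default (the grid is configurable), chosen
because no canonical set exists for normalized CT.

Hard indicator functions have zero gradient almost everywhere, so a loss
built from them cannot steer an optimizer. Training therefore substitutes
the soft surrogate $\sigma((x - t)\tau)$ for $I(x \ge t)$, with
intersection and union realized by the product t-norm/conorm and sharpness
$\tau = 50$ by default. The surrogate's value converges to the hard loss as
$\tau \to \infty$ (checked numerically in the test suite), and every
*reported* value -- logs, evaluations -- is always the hard-indicator
loss.

**Similarity.** $L_{sim} = 1 - \frac1h \sum_k
\mathrm{SSIM}(S(v,k), S(\hat v,k))$ compares corresponding axial slices
with the structural similarity index and averages over all $z$. SSIM uses
the canonical constants of its original formulation: Gaussian window 11,
window sd 1.5, $C_1 = 0.01^2$, $C_2 = 0.03^2$ at dynamic range 1, local
statistics over the valid filtering region. None of these constants are
prescribed by the method itself, which cites SSIM without parameters; the
canonical choices are the defensible default. Windows larger than a slice
shrink to the largest odd size that fits. Inside training, the slice-wise
SSIM is expressed as a single 3D convolution with a $w \times w \times 1$
Gaussian kernel, which filters every slice at once and backpropagates
exactly (it is not a surrogate).

## Networks

The generator is assembled from four stages, all 3D:

1. **Local feature fusion block (LFFB).** A $3^3$ stem conv lifts the
   1-channel conditioning tensor to `base_channels`; parallel convs with
   kernels $1^3 / 3^3 / 5^3$ (configurable) extract features at several
   receptive fields; their concatenation is fused by a $1^3$ conv and added
   back onto the stem output as a local residual. The stem exists because a
   residual between a 1-channel input and a multi-channel fusion is not
   well-typed; lifting first makes the residual exact.
2. **Encoder.** `depth_down` convolutions, kernel $4^3$, stride 2, each
   halving resolution and growing channels geometrically (capped).
3. **Refiner.** `depth_mid` ResNet-style blocks at the bottleneck: two
   $4^3$ stride-1 convs (asymmetric padding 1/2 keeps even extents exact)
   with instance normalization, ReLU and dropout (default 0.2) between.
4. **Decoder and output.** `depth_up = depth_down` transposed convs
   (kernel $4^3$, stride 2, exact adjoints of the encoder convs) with
   U-Net skip concatenations from the matching encoder level (the last
   skip comes from the LFFB output), then a stride-1 $4^3$ output conv to
   one channel through a sigmoid.

Two deliberate deviations from the method's prose: the source text assigns
stride 2 to the output layer, which would halve the resolution and
contradict the requirement that the generated volume match the ground
truth grid voxel-for-voxel -- the output conv is stride 1 here. And no
bounded output activation is named there; the sigmoid enforces the
stated $[0,1]$ normalization.

The discriminator stacks $4^3$ stride-2 convs over the channel-wise
concatenation of the conditioning tensor and the candidate volume
(condition as one channel, candidate as another), instance norm on all but
the first layer, LeakyReLU(0.2), then a fully connected layer with sigmoid.
Sparse image sets are embedded on the output grid with zeros at missing
z positions, so one architecture serves full, sparse and noisy
conditioning. How the original network ingested its condition, its layer
counts and widths are not recoverable from the source; these are the
package's choices, recorded here and in `generator_config()` /
`discriminator_config()` defaults (depth 3 + 3 refiner blocks,
base 16 channels at test scale).

All networks, the reverse-mode tape behind them, and Adam are implemented
in this package on plain R arrays: convolutions are cached im2col gathers
feeding BLAS matrix multiplies, transposed convolutions reuse the same
index sets as scatter-adds (exact adjoints), and stride-1 input gradients
are computed as gather convolutions with 180°-flipped kernels. Gradient
correctness is pinned by finite-difference tests through the entire
generator and composite loss.

## Training procedure

Per iteration: one discriminator Adam step on $(x, v)$ vs the *detached*
$(x, \hat v)$, then one generator Adam step against the updated
discriminator. Defaults follow the stated experimental settings --
learning rate $2 \times 10^{-4}$ for both networks, $\alpha = 33.0$,
dropout 0.2 -- with Adam $\beta = (0.5, 0.999)$ (the GAN-stable
convention), batch size 1, items consumed in cycling order, and a fixed
step budget (no stopping criterion is given in the source). Runs are
deterministic given the config seed; checkpoints (RDS plus a JSON sidecar)
round-trip bit-exactly on the same machine, and the per-step CSV log
reports `step, l_dist, l_feat, l_sim, l_recon, l_adv_g, l_g_total, l_d`,
with the feature term logged at its hard value.

## Synthetic phantoms

The CT corpora behind the original experiments (a national spine CT
archive and an external liver CT collection) are not distributable, so the
package generates phantom volumes reproducing the intensity structure the
method relies on: a low-value background majority (the "undefined" region
outside the anatomy), a mid-value interior, and -- for skeletal phantoms --
a thin high-value cortical shell that dominates the upper quartile of the
intensity histogram.

* `vertebra`: an ellipsoidal body with a ~2-voxel cortical shell at
  intensity 0.9, interior 0.55 with a faint radial gradient, plus a
  posterior rectangular process; background 0.08. Proportions are chosen so
  that Q3 of the voxel distribution lands between interior and shell
  intensity -- the regime in which Q3-thresholding isolates rigid
  structure.
* `liver`: a smooth-edged union of two overlapping ellipsoids at interior
  intensity with no shell -- the soft-tissue regime evaluated at Q1
  thresholds.
* `sphere`: the minimal bone-like case (solid ball, thin shell).

Additive Gaussian noise (default sd 0.02, a mild CT-like texture) is
applied before clipping to $[0,1]$, so the volume contract survives.
Random affine jitter (default magnitude 0.05) varies items. Per-item seeds
derive from the master seed by a counter-based split, making item $i$
independent of how many items are generated. Conditioning sets are the
truth's own slices (`full_stack`), every $n$-th slice (`sparse_slices`),
or noise-corrupted slices (`noisy_stack`) -- the composition of the
original conditioning input is unspecified in the source, so it is a
parameter here rather than a fixed choice.

What the phantoms do *not* emulate: projection physics, beam hardening,
anatomical population variability, or real HU marginals. Passing tests on
phantoms therefore demonstrate that the machinery -- losses, gradients,
training dynamics, evaluation -- behaves as specified on data with the
assumed intensity structure, not that the method reaches any particular
quality on clinical CT.

## Evaluation protocol

Volumes are compared after binarization at thresholds derived from the
*ground-truth* volume's intensity quantiles (the protocol analyzes the
truth's distribution, never the generated one): Q3 emphasizes rigid
skeletal structure, Q1 soft tissue. At a threshold $t$ the voxel confusion
fractions use strict `>` comparisons; note the deliberate asymmetry with
the feature loss, which uses `>=` -- both appear that way in the source
and are kept as printed, the difference mattering only for voxels exactly
at threshold. The printed FN formula in the source counts
$v \le t \wedge \hat v \le t$, which is the TN cell; the standard
convention is the default here (precision/recall/F1/Dice require it) and
the literal formula ships behind `convention = "as_printed"` for
transparency, with derived metrics refusing such counts. From standard
counts: IoU, Dice, F1, precision, recall, with any 0/0 defined as 1 when
`fp = fn = 0` and 0 otherwise; Dice $= 2\,\mathrm{IoU}/(1+\mathrm{IoU})$
holds identically and is asserted on random inputs.

Whole-volume similarity uses L1, PSNR (peak 1, `Inf` sentinel for
identical volumes), and three slice-averaged indices: UQI (Wang-Bovik
universal index, sliding uniform 8×8 window -- SSIM with both constants
zero), SSIM (shared with the loss), and VSI, a visual-saliency-weighted
index computed per grayscale slice from a band-pass (log-Gabor) frequency
prior with a center prior and Scharr gradient similarity, using the
published constants on a 0-255 intensity scale. VSI's full original
definition includes chrominance terms that do not exist for grayscale CT;
this grayscale variant is the package's documented adaptation, it equals 1
for identical volumes, and it can be disabled (`include_vsi = FALSE`) as
it is the heaviest metric. The exact UQI window of the original evaluation
is unstated; 8 is the index's canonical default.

`threshold_sweep()` reproduces the protocol's threshold study: five
evenly spaced quantiles from Q1 to Q3 (25%, 37.5%, 50%, 62.5%, 75%) with
truth-derived thresholds, reporting IoU/F1/Dice per row. Quantiles use
linear interpolation between order statistics (R type 7), the common
default; the estimator is not specified in the source.

## Numerical choices and problem sizes

The test suite and the acceptance script exercise training at desk scale:
volumes of $16^3$, generator/discriminator width 8 base channels (the
`base_channels = 16` package default remains the documented test-scale
preset; width 8 is the smoke-run configuration so that a 500-step
adversarial run completes in minutes on one CPU core), 20-phantom
datasets, 300-500 steps, batch 1. These sizes are the package's choices
for routine verification; nothing in the implementation is specific to
them, and `generator_config(depth_down = 4, base_channels = 64,
out_resolution = 128)` expresses the full-scale preset if one has the
hardware and data.

Other numerics worth knowing: instance-norm epsilon $10^{-5}$; Adam
epsilon $10^{-8}$; parameter init $N(0, 0.02)$ (the DCGAN convention)
under a per-network seed; NIfTI I/O stores doubles (value-exact
round-trips), slice stacks store 16-bit TIFF (error $\le 1/65535$);
HU-window normalization defaults to $(-1000, 2000)$, spanning air to dense
bone, because the original normalization of CT intensities to $[0,1]$ is
unspecified -- it is configurable.

## Known limitations

* A volumetric GAN at clinical resolution wants GPU-scale compute; the
  pure-R engine here is exact but desk-scale. The published headline
  metrics of the original study are out of reach without its non-public
  data and hardware, and this package does not attempt them.
* **Quantile thresholds inside a noise mode are degenerate.** When the
  Q1 threshold of a ground-truth volume falls inside its noisy background
  mode (as it does for any phantom whose background majority carries
  additive noise), the binarized truth labels background voxels positive
  or negative by their noise sign. Two consequences follow. First, an
  *untrained* generator -- whose near-zero-initialized output layer and
  sigmoid emit ≈0.5 everywhere -- predicts all-positive at such a
  threshold and scores IoU $= 1 - q$ (0.75 at Q1) by construction, an
  inflated baseline. Second, a well-trained reconstruction converges to
  the *denoising* solution, placing the background uniformly on one side
  of the threshold; its Q1 IoU is then bounded near the anatomy fraction
  divided by the positive fraction (≈0.6 for the default vertebra), and
  exceeding the degenerate baseline would require voxel-exact
  reproduction of the conditioning noise. Q1 overlap on noisy-background
  volumes therefore measures noise reproduction, not anatomy
  reconstruction -- the Q3 rows of `threshold_sweep()` are the
  informative ones for bone-like structure. This is a property of the
  evaluation protocol, not of any particular network.
* The feature loss optimizes a soft surrogate; at low sharpness the
  surrogate's optimum can differ slightly from the hard loss's.
* Phantoms are structural stand-ins, not physical CT simulations.
* DICOM series handling (orientation matrices, gantry tilt), resampling
  and registration are out of scope; imports are NIfTI or slice stacks.
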