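# voxgan

Conditional 3D GAN reconstruction of volumetric anatomical models from
tomographic slice sets, with a composite reconstruction loss and a full
volumetric evaluation protocol — implemented end-to-end in R, exercisable
on synthetic CT-like phantoms.

## What it does, for whom

Given an ordered stack of 2D grayscale slices (the conditioning image set
*I<sub>G</sub>*), a volume generator *G* produces a dense voxel grid
*V̂* ∈ [0,1]<sup>l×w×h</sup> approximating the ground-truth anatomy *V*,
trained adversarially against a volumetric discriminator *D* that scores
(condition, volume) pairs. The intended audience is researchers in medical
image synthesis who want a transparent, fully inspectable reference of
this reconstruction approach — every layer, gradient and metric is plain R
backed by BLAS, pinned by brute-force oracles in the test suite.

Training minimizes least-squares adversarial objectives

```
L_G = E[(D(x, V̂) − ½)²] + α·L_recon          (α = 33 by default)
L_D = E[(D(x, V) − ½)² + D(x, V̂)²]
```

with the composite reconstruction loss

```
L_recon = L_dist + L_f + L_sim
L_dist  = mean |V − V̂|                        (L1)
L_f     = 1 − mean_s J_s,  J_s = |V≥t_s ∧ V̂≥t_s| / |V≥t_s ∨ V̂≥t_s|
L_sim   = 1 − (1/h) Σ_k SSIM(V[,,k], V̂[,,k])
```

i.e. an L1 term, one minus the threshold-averaged Jaccard overlap of
high-value voxel sets, and one minus the mean slice-wise structural
similarity. The generator is a 3D U-Net encoder–decoder with a ResNet
refiner and a multi-scale local-feature-fusion front block; the
discriminator is a stack of strided 4³ convolutions with a sigmoid head.
Evaluation binarizes volumes at quantile thresholds of the *ground-truth*
intensity distribution (Q1 for soft tissue, Q3 for bone) and reports IoU,
Dice, F1, precision, recall, L1, PSNR, UQI, VSI and volume SSIM, plus a
five-point Q1→Q3 threshold sweep.

Because the original CT corpora are not distributable, the package ships a
phantom generator (`vertebra`, `liver`, `sphere`) reproducing the
intensity structure the method assumes: low-value background majority,
mid-value interior, and a thin high-value cortical shell for bone-like
shapes. See `vignettes/voxgan-methods.Rmd` for the full model account.

## Worked example

```r
library(voxgan)

# one synthetic vertebra with its conditioning slice stack
pair <- make_phantom(phantom_spec(kind = "vertebra", resolution = 16L,
                                  seed = 1L))

# desk-scale networks; alpha = 33, lr = 2e-4, dropout = 0.2 defaults
st <- train(list(pair),
            generator_config(base_channels = 8L, out_resolution = 16L),
            discriminator_config(base_channels = 8L, in_resolution = 16L),
            loss_config(),
            train_config(steps = 300L, seed = 3L, adversarial = FALSE))

vhat <- generate(st, pair$condition)
evaluate_pair(pair$truth, vhat, include_vsi = FALSE)
#> <voxgan_metric_report>
#>   overlap at t = 0.0714 (q = 0.25): iou 0.6726 dice 0.8042 f1 0.8042
#>   l1 0.0244  psnr 28.423 dB  uqi 0.9105  vsi NA  ssim 0.9900

threshold_sweep(pair$truth, vhat)
#>   quantile  threshold       iou        f1      dice
#> 1    0.250 0.07135349 0.6725689 0.8042346 0.8042346
#> 2    0.375 0.07976914 0.6282009 0.7716503 0.7716503
#> 3    0.500 0.08874575 0.6096491 0.7574932 0.7574932
#> 4    0.625 0.09979879 0.6444330 0.7837754 0.7837754
#> 5    0.750 0.55408567 0.9853659 0.9926290 0.9926290
```

After 300 generator-only steps on one phantom, the mean absolute voxel
error is 0.024, slice-wise structural similarity averages 0.99, and the
Q3-threshold overlap -- the quantile that isolates the rigid cortical
shell and interior -- is nearly perfect (IoU 0.985). The lower sweep rows
sit in the phantom's noisy background mode (thresholds 0.07-0.10 against
a background of 0.08 with noise sd 0.02), where binarized overlap is
limited by voxel noise rather than reconstruction quality; the vignette
discusses this property of quantile thresholds that fall inside a noise
mode.

The same pipeline is scriptable from a shell via the bundled entry point:

```sh
inst/cli/voxgan simulate --kind vertebra --n 20 --resolution 16 --seed 7 --out data/
inst/cli/voxgan train --data data/ --out runs/r1/ --steps 500
inst/cli/voxgan generate --checkpoint runs/r1/checkpoint.rds \
                         --condition data/cond_0001 --out gen.nii.gz
inst/cli/voxgan evaluate --truth data/truth_0001.nii.gz --pred gen.nii.gz \
                         --out report.json --sweep 5
```

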