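# wiafseg

Lightweight 3D brain-tumor segmentation in R: wavelet-gated downsampling,
iterative axial factorized attention, and a multi-scale fusion decoder,
implemented from the numerics up (forward pass, analytic backward pass,
AdamW training) on BLAS-backed matrix operations — no deep-learning
framework required.

## What it is for

Voxel-wise segmentation of gliomas from multimodal MRI (T1, T1ce, T2,
FLAIR) into the nested BraTS regions — enhancing tumor (ET), tumor core
(TC), whole tumor (WT) — with a deliberately small budget: the reference
network holds **5.23 M** trainable parameters and costs **9.75 G**
multiply-accumulates for one forward pass at a 4×128×128×128 input. The
package is aimed at people who want to study or extend the architecture
itself: every component is exposed, tested against brute-force oracles, and
trainable at desk scale on synthetic phantoms with no dataset download.

## The model in brief

* **Wavelet front end (AWD-FD).** Stage 1 downsamples by a fixed
  single-level 3D Haar transform: each channel becomes eight half-resolution
  sub-bands `X_LLL … X_HHH`. A squeeze-excitation gate
  `w = sigmoid(W2 ReLU(W1 GAP(X_sub)))` rescales the 8C sub-band channels,
  and a 1×1×1 projection maps them into the stage-1 width. Orthonormal
  filters make Parseval energy conservation and perfect reconstruction
  exact.
* **Iterative axial factorized attention (IAFT).** Instead of full 3D
  self-attention (`O(N^2)` in the token count), each block attends along
  one spatial axis at a time with the other two folded into the batch,
  sweeping H, W, D sequentially through SiLU-gated residuals:
  `Z <- Z + silu(Attn_axis(Z))`. Score/value cost scales as `O(N^{4/3})`
  on cubic grids.
* **Multi-scale fusion decoder (MSFFD).** Per-level channel gates, alignment
  of the four pyramid levels to the stride-2 grid (transposed convolution +
  trilinear interpolation), a lightweight axial-attention pass per level,
  1×1×1 fusion, progressive upsampling, and a pointwise classifier —
  167,940 parameters in total.
* **Objectives and metrics.** `L = lambda1 * L_Dice + lambda2 * L_CE`;
  evaluation reports per-region Dice and 95th-percentile Hausdorff distance
  (pooled symmetric surface distances, mm), means with Student-t 95%
  confidence intervals, and paired t-tests between models.

## Worked example

Train the committed desk-scale preset (32³ phantoms, reduced widths, 20
epochs — a few minutes on one CPU) and evaluate on held-out phantoms:

```r
library(wiafseg)

spec <- phantom_spec(grid = 32)
ds   <- generate_dataset(20, spec, seed = 0, split = c(8, 1, 1))
fit  <- train(wiaf_desk_config(), ds, train_config("desk", seed = 0))

tail(fit$log, 3)
#>    epoch          lr      loss  val_dice
#> 18    18 0.003087446 0.4085417 0.7568808
#> 19    19 0.002895304 0.4269172 0.7888684
#> 20    20 0.002700755 0.3883604 0.7635989

ph   <- generate_phantom(spec, 101)
pred <- predict_labels(fit$model, normalize_volume(ph$volume))
rs   <- brats_regions(ph$labels)
dice_score(brats_regions(pred)$WT, rs$WT)
#> [1] 0.8911495
```

The training loss falls from 1.83 (first epoch) to 0.39 over 20 epochs and
the validation mean region Dice reaches ~0.76; whole-tumor Dice on unseen
phantoms is typically around 0.9 (the desk-scale acceptance threshold is a
mean of at least 0.70 over five held-out phantoms). Edema (bright on FLAIR)
drives WT; the tiny enhancing core is the hard class at this scale,
mirroring the behaviour reported on real data.

Architectural budgets are analytic and instant:

```r
summarize_model(wiaf_reference_config())
#>   component  params       macs params_M macs_G
#> 1      stem   43131  134259904     0.04   0.13
#> 2    stage1    1176 1073741824     0.00   1.07
#> 3    stage2   40928 1702887424     0.04   1.70
#> 4    stage3  232320  981467136     0.23   0.98
#> 5    stage4 4744512 2441871360     4.74   2.44
#> 6   decoder  167940 3415093824     0.17   3.42
#> 7     total 5230007 9749321472     5.23   9.75
```

A thin command-line wrapper is installed as `exec/wiaf` with subcommands
`generate`, `train`, `predict`, `evaluate`, `summarize`, and
`calibrate-config`.

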