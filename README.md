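# tatha

Thyroid nodule segmentation for B-mode ultrasound, implemented end to end
in R: the TATHA pipeline with its T-Net architecture, Banerjee compound
loss, DTSF ensemble, preprocessing operators, a synthetic phantom
generator, and the cross-validation statistics harness.

## Who this is for

Researchers working on ultrasound lesion segmentation who want a fully
inspectable, CPU-reproducible implementation of this pipeline — every
layer, gradient and statistic is open R/C++ code with oracle-backed tests —
and anyone who needs the individual pieces: speckle-reducing diffusion,
CLAHE, Canny-style edge refinement, Tversky/Dice/focal compound losses,
convex probability-map ensembling, or fold statistics.

## What is inside

- **Preprocessing** (`anisotropic_diffusion`, `clahe`,
  `sobel_gradients` + `hysteresis_edges`, `extract_roi`,
  `preprocess_pipeline`): the explicit 4-neighbour Perona–Malik scheme
  `I <- I + λ Σ c_i ∇I_i` with `c = exp(-(|∇I|/κ)²)`; contrast-limited
  adaptive histogram equalization with clip `T_clip = clip × MN/L`;
  Sobel magnitude/orientation with NMS and dual-threshold hysteresis;
  tight half-open bounding boxes.
- **T-Net** (`tnet_config`, `build_tnet`, `enumerate_layers`,
  `verify_table4`, `attention_map`): five encoder T-blocks (parallel
  dilation-1/dilation-2 convolutions, concatenation, BN, ReLU; filters
  64…1024), a CBAM-style channel-attention bottleneck, two decoder blocks
  with encoder skips, and two heads (the strict tabulated terminus at
  quarter resolution, or a full-resolution sigmoid head for training).
  Forward, backward and Adam are implemented in the package
  (RcppArmadillo kernels); gradients are verified against numerical
  differentiation in the tests.
- **Loss and metrics** (`banerjee_loss`, `tversky_index`,
  `dice_coefficient`, `evaluate`):
  `L = 0.23(1−TI) + 0.65(1−Dice) + 0.12(1−TI)^γ` on soft cardinalities,
  with analytic gradients; accuracy / Dice / IoU / sensitivity /
  specificity / trapezoidal AUC / average precision.
- **DTSF ensemble** (`thyrofen_extract`, `fit_ensemble_weights`,
  `dtsf_combine`): convex combination `Σ w_i · map_i` with weights
  softmax-fitted from validation Dice.
- **Phantoms** (`phantom_spec`, `generate_phantom`, `generate_dataset`,
  `make_folds`): speckled low-contrast elliptical-nodule phantoms with
  paired masks; 450/95/92 splits and the 15-fold layout.
- **Statistics** (`fold_summary`, `one_sample_t_test`, `shapiro_wilk`,
  `stat_report`, `tatha_reference_folds`): fold summaries, two-sided
  one-sample t-tests against the peer baseline (mean peer accuracy
  0.9124), Shapiro–Wilk normality.
- **I/O and CLI** (`load_image`, `render_overlay`, `render_boxes`,
  `inst/cli/tatha`): PNG/TIFF readers/writers, overlay and bounding-box
  figures, YAML run configs, and a thin command-line front end
  (`tatha synth | preprocess | build --verify-table4 | eval | stats |
  ensemble | visualize`).

## Worked example

Verify the architecture against its published layer table, then reproduce
the published fold statistics:

```r
library(tatha)

net <- build_tnet(tnet_config(output_mode = "table4_strict"))
print(net)
#> T-Net (table4_strict head), input 256x256x1
#>   51 layers, 55,639,040 parameters
head(enumerate_layers(net), 4)
#>    name          output_shape params  connections
#>   Input   (None, 256, 256, 1)      0            -
#>   Conv1  (None, 256, 256, 64)    640        Input
#>   Conv2  (None, 256, 256, 64)    640        Input
#> Concat1 (None, 256, 256, 128)      0 Conv1, Conv2
nrow(verify_table4(net))   # mismatching rows vs. the published counts
#> [1] 0

stat_report(tatha_reference_folds())
#>   metric   mean       sd      t         p     verdict shapiro_w shapiro_p    mu0
#> accuracy 0.9493 0.002599 54.990 9.265e-18 Significant    0.9530    0.5733 0.9124
#>     dice 0.9161 0.004075  3.527 3.348e-03 Significant    0.9450    0.4488 0.9124
#>      auc 0.9391 0.003030 34.159 6.933e-15 Significant    0.9328    0.3005 0.9124
```

Every printed parameter count of the tabulated T-Net reproduces exactly
(640 for the first encoder convolution through 1,769,728 for the last
decoder pair), and the fold summaries match the published mean/SD pairs at
4 decimals with "Significant" t-verdicts against the 0.9124 peer baseline.
The Shapiro–Wilk column is the value Royston's algorithm actually yields
on the printed fold accuracies.

Train a desk-scale network on synthetic phantoms and segment one:

```r
ds  <- generate_dataset(n_train = 32, n_val = 8, n_test = 8,
                        spec = phantom_spec(size = 64), seed = 11)
cfg <- tnet_config(input_size = 64, filters = c(8, 16, 32, 64, 128),
                   output_mode = "full_resolution", seed = 1)
fit <- train_tnet(build_tnet(cfg), ds, learning_rate = 3e-3,
                  batch_size = 8, max_epochs = 100, patience = 15, seed = 1)
print(fit)
#> trained T-Net: 55 epochs (best 40), val loss 0.0634, val Dice 0.9435

ph   <- generate_phantom(phantom_spec(size = 64), seed = 99)
prob <- predict(fit, ph$image)
evaluate(prob, ph$mask)$dice
#> [1] 0.9379462
```

(A few minutes on one CPU core; the best-epoch validation Dice of ~0.94
means predicted and true nodule masks overlap almost completely at this
scale.)

## Layout

```
R/                  implementation (preprocessing, T-Net + autodiff, loss,
                    DTSF, phantoms, training, statistics, I/O)
src/                RcppArmadillo convolution / pooling kernels
inst/extdata/       published fold metrics and peer baselines (CSV)
inst/cli/tatha      command-line front end
tests/testthat/     oracle-backed unit, property and end-to-end tests
vignettes/          methods vignette: models, parameter choices, limits
scripts/acceptance.R
```
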