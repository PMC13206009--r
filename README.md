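# hsiband

Reconstruction-assisted, attention-guided spectral band selection for
non-destructive prediction of fruit soluble solids content (SSC, in
degrees Brix) from visible/near-infrared hyperspectral cubes.

Full-band VNIR hyperspectral imaging (here 176 bands over 404.7-1010.8
nm) carries far more spectral channels than a deployable fruit-grading
sensor can afford, and adjacent bands are strongly collinear. `hsiband`
is for researchers in postharvest quality sensing and chemometrics who
want to learn a compact wavelength subset that is chosen *for* the
regression task while still retaining enough information to restore the
full spectrum — a candidate filter set for a cheap multispectral device.

## The method

Given a calibrated, normalized reflectance cube `X ∈ [0,1]^{C×H×W}`,
the pipeline is select–reconstruct–predict:

- **Attention.** A spatial mask `M_S = σ(f_S([Avg_C(X); Max_C(X)]))` and
  band importances `a = σ(MLP(GAP_{h,w}(X)))`.
- **Differentiable selection.** Probabilities
  `p_i = σ((a_i − τ)/T) / Σ_j σ((a_j − τ)/T)` with adaptive threshold τ
  and annealed temperature T; a soft pass count
  `K~ = Σ_i σ((a_i − τ)/T_pass)` and the budget penalty
  `L_pass = ½(K~ − K)²` hold the effective band count at the target K.
  The gated cube `X_soft = X · M_S · g` feeds both heads.
- **Two coupled heads.** A small U-Net-style encoder–decoder
  reconstructs all C bands (`L_rec` = MSE); a compact head (depthwise
  separable conv → efficient channel attention → generalized-mean
  pooling → affine) predicts SSC (`L_reg` = Huber, δ = 1 °Brix).
- **Progressive training.** `L = α_t L_rec + β_t L_reg + λ L_pass` with
  α falling and β rising across Stage 0 (all modules trained) and
  Stage 1 (attention frozen); between Stages 1 and 2 the top-K most
  frequently selected bands are fixed, and Stage 2 fine-tunes the
  regression branch only. Evaluation reports RMSE/R²/RPD for prediction
  and PSNR/SSIM/SCC/SAM for reconstruction.

Because the instrument dataset is not distributable, the package ships a
phantom generator that plants an SSC-linked absorption on a known set of
informative bands, so selection, reconstruction and regression are all
testable against ground truth. See the methods vignette
(`vignettes/band-selection-methods.Rmd`) for the full model description
and design rationale.

## Worked example

Train the full pipeline on 48 synthetic 32-band phantoms with 8 planted
informative bands and a band budget of K = 8:

```r
library(hsiband)
cfg <- phantom_config(n_bands = 32, height = 16, width = 16,
                      informative_bands = c(3, 7, 12, 16, 20, 24, 27, 30),
                      noise_sd = 0.005, n_samples = 48, seed = 11)
plan <- stage_plan(total_epochs = 50, stage_epochs = c(30, 10, 10),
                   batch_size = 8, lr = 0.02, lr_att = 0.1,
                   input_decay = 0.02, alpha_range = c(1, 0.1),
                   beta_range = c(0.5, 1), augment = FALSE)
run <- phantom_run(cfg, K = 8, plan = plan, patch_size = 12, seed = 4,
                   base_width = 8, hidden = 8)
run$selected_bands
run$test$reg
```

which prints

```
selected bands (0-based): 3 4 5 7 16 20 22 24
planted bands           : 3 7 12 16 20 24 27 30
test RMSE 0.546 Brix, R2 0.790, RPD 2.44
reconstruction PSNR 14.60 dB, SSIM 0.703, SAM 9.80 deg
```

Five of the eight fixed bands are planted informative bands; held-out
prediction explains 79% of the label variance at an error of about half
a degree Brix (an RPD near 2.4 sits in the "approximate quantitative
prediction" range of common spectroscopy heuristics). The band table
maps each selected index to its wavelength and accumulated selection
frequency:

```r
selected_band_table(run$selected_bands, 32,
                    frequency = run$model$state$sel$freq)
```

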