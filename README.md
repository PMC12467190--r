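# ctdenoise

Convolutional denoising and quality evaluation for paired low-dose CT
studies, in R.

Low-dose CT trades radiation exposure for noise. When paired acquisitions
of the same subject at high and low dose exist, a network can be trained to
map the noisy low-dose (LQ) slice to its high-dose (HQ) reference, and the
result can be judged three ways: global paired image-quality metrics,
organ-level noise statistics in Hounsfield units (HU), and an observer
(reader) study. `ctdenoise` implements all three layers plus the model
itself, and ships a synthetic phantom generator so every stage runs without
access to clinical data.

The pieces:

* **Network** — an encoder–decoder with skip connections and a DnCNN-style
  refinement head: two conv/ReLU/pool encoder stages (64, 96 filters), a
  112-channel bottleneck with dropout, two transposed-convolution decoder
  stages (96 filters) concatenated with the matching encoder features, *n*
  refinement blocks (conv → batch norm → ReLU → dropout), and a 1-filter
  reconstruction conv. Forward pass, exact analytic backward pass and Adam
  are implemented in vectorized R and verified against finite differences.
* **Training** — patient-level train/validation/test splitting, paired
  augmentation (common rotation/flips applied identically to HQ and LQ),
  MSE loss, best-on-validation checkpointing, and a seeded hyperparameter
  search over the documented tuning spaces.
* **Metrics** — MSE, PSNR `10·log₁₀(L²/MSE)`, SSIM (global single-statistic
  and windowed Gaussian forms), pixel-domain multi-scale VIF, edge
  preservation index (literal gradient quotient and gradient-correlation
  forms), and noise variance.
* **ROI analysis** — circular ROIs of physical radius (default 8 mm) on HU
  slices; mean, sample SD, and percent SD reduction
  `100·(SD_LQ − SD_out)/SD_LQ`.
* **Reader statistics** — exact reconstruction of integer 1–5 Likert score
  sets from printed summaries (mean/SD/median/IQR/n) by exhaustive search,
  one-sample t-tests against the neutral midpoint 3, Holm adjustment
  (standard and tie-averaged variants), Cohen's d, and 95% CIs.
* **I/O** — minimal single-frame DICOM read/write with HU rescale, PNG
  export, CSV/JSON reports, and a command-line front end
  (`exec/ctdenoise`).

## Worked example

Simulate a paired study, train a small model, and evaluate it:

```r
library(ctdenoise)

pairs <- make_paired_dataset(n_patients = 23, slices_per_patient = 10,
                             size_px = c(64, 64), seed = 101)
sp <- split_by_patient(pairs, c(15, 4, 4), seed = 101)

cfg <- denoiser_config(enc_channels = c(6, 8), mid_channels = 10,
                       dec_channels = 8, n_dncnn_blocks = 2,
                       dropout_rate = 0.1)
model <- build_denoiser(cfg, seed = 102)
fit <- train_denoiser(model, sp$train, sp$val,
                      train_config(epochs = 10, seed = 103))

report <- evaluate_dataset(sp$test, model = fit$model)
subset(report$aggregate, metric %in% c("psnr", "ssim"))
#>      arm metric    mean      sd  median     min     max n_missing
#> 2     LQ   psnr 27.0482 1.72693 27.5134 24.2151 28.9870         0
#> 3     LQ   ssim  0.6265 0.06434  0.6412  0.5226  0.7051         0
#> 8 output   psnr 27.8365 0.37858 27.9862 27.0438 28.2820         0
#> 9 output   ssim  0.7908 0.02505  0.7991  0.7412  0.8166         0
```

The denoised arm beats the low-dose arm by ~0.8 dB mean PSNR and ~0.16
SSIM on the held-out patients of this small synthetic study, and with a
visibly tighter spread. Dataset generation and training are deterministic
given the seeds, so the run above reproduces exactly.

Reader-study analysis from a printed summary table:

```r
res <- analyze_reader_study(load_reader_summaries())
res[res$question_id == "Q9", c("t", "p_raw", "p_holm", "cohens_d", "ci_width")]
#>   t        p_raw       p_holm cohens_d  ci_width
#>  11 0.0001080522 0.0009724698 4.490731 0.4284303
```

Q9's six reconstructed scores (4,5,5,5,5,5) give t = 11.00 against the
neutral midpoint 3 (df = 5), a raw two-sided p of 0.000108, a Holm-adjusted
p of 0.000972 across the nine questions, Cohen's d = 4.49, and a 95% CI
half-width of 0.43 — i.e. the observers scored the denoised images far
above neutral.

ROI noise arithmetic:

```r
sd_reduction_pct(17.60, 16.20)   # vitreous body, % SD reduction
#> [1] 7.954545
sd_reduction_pct(18.85, 15.40)   # brain parenchyma
#> [1] 18.30239
```

## Documentation

The methods vignette (`vignettes/lowdose-ct-denoising.Rmd`) describes the
model, the noise model and its assumptions, the metric variants and why
both EPI conventions are provided, the Holm tie-handling conventions, the
numerical choices, and what the synthetic phantom does and does not
demonstrate.
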