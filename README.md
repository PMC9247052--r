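# organspectra

Analysis toolkit for intraoperative hyperspectral imaging (HSI) of porcine
organs. An HSI camera assigns every pixel a reflectance spectrum (100 bands,
500–995 nm in 5 nm steps); the scientific question is whether those spectra
are *organ fingerprints* — different between organs, stable across animals
and acquisition conditions — and whether they support automatic tissue
classification. The package is written for researchers who have
annotation-level spectra (or datacubes plus organ masks) with pig / organ /
image / angle / repetition metadata, and for anyone who wants to study the
estimators themselves on fully synthetic data.

It provides, end to end:

* **Preprocessing** — pixel-level ℓ1 normalization of datacubes and
  per-annotation median spectra, with QC for dead pixels
  (`l1_normalize_pixels()`, `extract_median_spectrum()`,
  `preprocess_dataset()`).
* **Fingerprint atlas** — per-organ mean ± SD spectra with per-pig curves
  and A/n counts (`compute_atlas()`, `export_atlas()`, `autoplot()`).
* **Variance decomposition** — for each wavelength λ the linear mixed model

  `y_ijk = α + organᵀβ + angleᵀθ + δ_i + γ_ij + ε_ijk`,
  `δ_i ~ N(0, σ²_pig)`, `γ_ij ~ N(0, σ²_image)`, `ε_ijk ~ N(0, σ²_rep)`

  is fitted by REML (`lme4`) and reflectance variance is split into organ,
  angle, pig, image and repetition shares, with parametric-bootstrap
  confidence bands and an organ-stratified variant
  (`decompose_variance()`, `decompose_variance_stratified()`).
* **Embedding** — seeded t-SNE of annotation spectra with the three-stage
  hyperparameter search protocol and a quantitative neighbour-purity score
  (`embed_spectra()`, `staged_search()`).
* **Classification** — a from-scratch 1-D CNN (conv 64/32/16, kernel 5,
  average pooling; FC 100/50; batch norm + ELU throughout; ~34k
  parameters) trained with Adam and per-epoch learning-rate decay,
  leave-one-pig-out cross-validation, mean-logit ensembling and a per-pig
  evaluation suite (`train_lopo()`, `ensemble_predict()`,
  `evaluate_predictions()`).
* **Synthetic data** — a generator that draws spectra exactly from the
  mixed model above under the standardized acquisition protocol
  (3 repetitions × 3 angles × 4 positions per organ per pig), so every
  stage is testable without the non-public porcine dataset
  (`make_fingerprint_library()`, `make_standardized_design()`,
  `simulate_spectra()`, `calibrate_components()`).
* **Pipeline** — a config-driven runner covering
  simulate → preprocess → atlas → variance → embed → train → evaluate with
  per-stage seeds and an MD5-hashed manifest (`run_pipeline()`).

## Worked example

Simulate the standardized study at a reduced size, decompose the variance,
and train the classifier:

```r
library(organspectra)
library(dplyr)

design <- make_standardized_design(n_pigs = 10, porcine_organs(),
                                   n_positions = 2)
lib    <- make_fingerprint_library(porcine_organs(), seed = 11)
comps  <- calibrate_components(lib, design, organ_share = 0.8)

# raw table for variance work, normalized table for the classifier
raw  <- simulate_spectra(design, lib, comps, seed = 12)
spec <- simulate_spectra(design, lib, comps, seed = 12, normalize = TRUE)

decomp <- decompose_variance(raw, wavelengths = spectra_wavelengths(raw)[1:10])
median_across_wavelengths(decomp)
#> # A tibble: 5 × 2
#>   factor          median
#>   <chr>            <dbl>
#> 1 angle      0.000000708
#> 2 image      0.219
#> 3 organ      0.742
#> 4 pig        0.0294
#> 5 repetition 0.00293

split  <- split_train_test(unique(spec$pig_id), unique(spec$pig_id),
                           distinct(spec, pig_id, organ),
                           n_test = 3, seed = 13)
bundle <- train_lopo(filter(spec, pig_id %in% split$train_pigs),
                     cnn_architecture(),
                     training_config(epochs = 3, samples_per_epoch = 8192,
                                     batch_size = 128, seed = 14))
test   <- filter(spec, pig_id %in% split$test_pigs)
report <- evaluate_predictions(test$organ,
                               ensemble_predict(bundle, test)$pred,
                               test$pig_id)
report
#> <evaluation_report> micro accuracy 0.981 (21/1080 misclassified);
#>   macro sensitivity 0.981, specificity 0.999, F1 0.980
```

The decomposition medians recover the generative shares — organ ≈ 0.8 on
average across the spectrum (the first ten wavelengths shown sit slightly
below it because the between-organ spread varies by band), with
image ≫ pig ≫ repetition in the calibrated noise split — and the
ensemble classifies annotations of pigs never seen in training with high
accuracy. `autoplot()` works on the atlas, the decomposition, the embedding
and the evaluation report; `tidy()`/`glance()` return tibbles.

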