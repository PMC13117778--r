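# mswanet

Frequency-aware classification of histopathology images with a residual
convolutional network carrying **multi-scale wavelet attention (MSWA)**,
evaluated under a strict **patient-level protocol**.

Malignant tissue in H&E-stained breast biopsies shows up as textural
irregularity across spatial scales — the kind of signal plain spatial
convolutions represent only implicitly. The MSWA block makes it explicit:
after each residual stage the feature map `X` is decomposed by a separable
2-D discrete wavelet transform into the sub-bands `LL, LH, HL, HH`; each
band is scored by its energy

    eps_s = (1 / HW) * sum_ij X_s(i, j),      s in {LL, LH, HL, HH},

the dominant band is selected recursively over `L` levels, bilinearly
upsampled back to `H x W`, aligned by a 1x1 convolution, and fused
residually:

    Y = X + Conv1x1(Upsample(MSWA(X))).

Around the model, the package implements the full evaluation protocol that
patient-level claims require: overlap tiling of whole images into 224-pixel
patches (stride `round(224 x 0.8) = 179`), leakage-free patient-wise 70/30
splits and stratified 5-fold cross-validation with an explicit leakage
audit, augmentation-based class balancing, fold-ensemble probability
averaging, hierarchical patch → image → patient aggregation with a 0.5
decision threshold, confusion-matrix metrics with percentile bootstrap
confidence intervals, paired fold comparisons, and Grad-CAM attribution
maps. A synthetic histology-texture cohort generator (classes separable by
multi-scale frequency content, patient-correlated intensity effects) makes
every stage runnable end-to-end without downloading data.

Everything is self-contained R: the 2-D DWT, and a compact neural-network
engine (im2col convolution on BLAS with a C++ gather/scatter core, batch
normalization, max/average pooling, bilinear resize, AdamW, cross-entropy)
with a finite-difference-verified backward pass.

## Worked example

```r
library(mswanet)

# 1. a synthetic cohort: 24 patients, 4 images each, 700 x 460 px
coh <- generate_cohort(synthetic_cohort_spec(seed = 101))

# 2. tiling arithmetic for the native image size
plan_grid(700, 460, patch_size = 224, overlap = 0.20)
#> stride 179, nh 3, nw 2 -> 6 patches per image

# 3. train a reduced-width MSWA model on a patient-level split and
#    aggregate test predictions patch -> image -> patient
res <- run_patient_eval(coh$index, coh$images, seed = 101,
                        mswa = wavelet_spec("haar"), epochs = 5,
                        width_multiplier = 0.25, input_size = 48)
res$patient_acc
#> [1] 1
print(res$metrics)
#> metrics: acc 1.0000 | prec 1 | rec 1 | spec 1 | f1 1 (tp 4 fp 0 fn 0 tn 4)
```

The run above held out 8 of 24 patients by a stratified patient-level
split, trained on ~380 balanced patches from the remaining 16, and
classified every held-out patient correctly from the averaged patch
probabilities — the synthetic classes differ only in high-frequency
texture, which is exactly the signal the wavelet attention selects.

The matched plain backbone (`mswa = NULL`) under the same seed reached
patch-level accuracy 0.995 versus 1.0 for the MSWA model in this run; the
test suite repeats this comparison over five seeds.

Other entry points: `dwt2_single()` / `subband_energy()` /
`dominant_subband()` (the wavelet core), `mswa_forward()` (one attention
block), `build_model()` / `train_fold()` / `predict_probs()`,
`patient_split()` / `stratified_kfold()` / `leakage_audit()`,
`ensemble_average()` / `aggregate_image()` / `aggregate_patient()` /
`bootstrap_ci()`, `gradcam()`, and `run_study()` for the full
cross-validated protocol. A thin command-line front end lives at
`inst/cli/mswa.R` (`generate`, `split`, `study`, `gradcam`).

## Tests

```sh
Rscript -e 'devtools::test()'
```

The suite covers closed-form and brute-force oracles for the wavelet
engine, finite-difference gradient checks, tiling and balancing rules,
leakage fuzzing, aggregation laws, bootstrap enumeration, Grad-CAM
properties, and an end-to-end learnability experiment on the synthetic
cohort. Everything runs on one CPU.

## Vignette

`vignettes/mswa-methods.Rmd` documents the model and protocol in detail:
energy conventions and tie-breaking, boundary handling, the
straight-through treatment of the discrete sub-band selection,
zero-initialized residual fusion, the split/rounding rules, what the
synthetic cohort does and does not emulate, and the problem sizes the test
suite uses.
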