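---
title: "Normative deviation mapping of brain morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative deviation mapping of brain morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normdae)
```

## The model

Case-control classifiers ask which features separate patients from controls.
A *normative* model asks a different question: how far does an individual sit
from the healthy-population range? `normdae` implements this with a
semi-supervised denoising deep autoencoder trained exclusively on healthy
subjects' regional morphometry — 68 Desikan-Killiany cortical thicknesses
(34 per hemisphere, mm) and 36 segmentation volumes (mm^3), 104 regional
features per subject.

The network is

```
x (104) --> h1 (SELU) --> z (SELU)          [latent code]
                     \--> y_age (softmax, 16 classes, ages 22..37)
                     \--> y_sex (softmax, M/F)
[z, y_age, y_sex] --> h2 (SELU) --> x_hat (linear, 104)
```

with the default 104-100-75-100-104 layout. Training minimizes

Loss = ||x - x_hat||^2 / (n p) + CE(y_age, y_hat_age) + CE(y_sex, y_hat_sex) + XCov + L2,

where the reconstruction error is averaged over batch and features so the
four terms live on comparable scales, CE is the categorical cross-entropy of
the covariate heads, and

XCov = 1/2 * sum_ij C_ij^2,  C = batch cross-covariance(z, [y_hat_age, y_hat_sex]).

Age and sex are *deliberately kept inside* the model rather than regressed
out: the heads learn to predict them, the decoder is allowed to use the
predictions, and the XCov penalty pushes covariate information out of `z`.
A subject is then reconstructed *conditional on* (predicted) age and sex, so
that ordinary covariate variation is not mistaken for deviation.

Inputs are corrupted during training with additive Gaussian noise (SD 0.1 on
standardized features) while the loss targets the clean input — the
denoising principle: the model must learn the structure of healthy
variation, not memorize individual subjects.

After training, each test subject gets a **deviation metric**

D = 1/104 * sum_i (x_i - x_hat_i)^2,

computed on features standardized with the *training* cohort's mean and
population SD (never refit on test data), plus a **regional deviation map**,
the 104 per-region squared errors. Groups from the same dataset are compared
with two-tailed Mann-Whitney U tests; regional magnitudes are summarized by
|Cliff's delta| and flagged at an uncorrected p < .01 (an expected 1% false
positive rate; correlated neighbouring regions make Bonferroni-style
corrections inappropriate here).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `h1_units, z_units, h2_units` | 100, 75, 100 | layer widths; `z < h1` constrains the code |
| `l2_coefficient` | 1e-3 | L2 on weight matrices (not biases) |
| `corruption_sd` | 0.1 | SD of denoising corruption, standardized units |
| `epochs` | 2000 | Adam epochs |
| `batch_size` | 64 | mini-batch size (remainder batch kept) |
| `lr_initial, lr_final` | 0.05, 0.0005 | per-epoch exponential decay endpoints |
| `loss_weights` | 1,1,1,1 | reconstruction, age CE, sex CE, XCov |
| age range | 22-37 | inclusion filter and the 16 age classes |

The learning rate decays by a constant per-epoch factor
`(lr_final/lr_initial)^(1/(epochs-1))`, so the final epoch runs at exactly
`lr_final`. Grid search over layer widths (`select_architecture()`)
evaluates symmetric `h1 = h2` candidates with `z < h1` from
{10, 25, 50, 75, 100} by k-fold cross-validated validation reconstruction
error.

## Design choices where the design was open

* **Heads branch from `h1`, not from `z`.** The covariate heads and the
  latent code are siblings: both are computed from the first hidden layer.
  This makes the XCov penalty meaningful — `z` and the head outputs are
  separate channels whose cross-covariance can be driven to zero.
* **The decoder consumes predicted probabilities, not true labels,** during
  both training and inference. One consistent computation graph, and
  inference never needs demographic truth.
* **XCov operands** are the latent code and the concatenated softmax outputs
  of both heads, with the 1/2 sum-of-squares form given above (batch
  covariance, 1/n). The penalty's exact normalization is a convention; this
  one makes the term's gradient scale like the batch covariance itself.
* **Cross-entropy treats age as unordered classes.** No ordinal penalty;
  a prediction two years off costs the same as one twenty years off. This
  keeps the head a plain classifier; the reported age MAE is computed from
  the argmax class.
* **Normalization uses the population SD** (divide by n) with a floor of
  1e-8 against degenerate constant features.
* **Mann-Whitney branch rule:** the exact U null distribution is used when
  `n_a * n_b <= 400` and there are no ties, otherwise the normal
  approximation with tie and continuity corrections; the output labels the
  branch. Exact where cheap, honest everywhere.
* **SVM test scores default to the decision margin.** AUC depends only on
  the ranking, so the margin and Platt-calibrated probabilities give the
  same AUC up to monotone transformation; the margin is exactly
  reproducible run-to-run, whereas libsvm's internal Platt calibration
  draws from a process-global random stream that breaks byte-identical
  reproducibility. `score = "probability"` restores calibrated
  probabilities.
* **C grid:** odd powers of two from 2^-15 to 2^15 (16 values), ties broken
  toward the smaller C (stronger regularization).
* **Seeding:** every stochastic stage derives independent sub-seeds from a
  single master seed (`derive_seeds()`), so bootstrap repetitions are
  individually reproducible and the CLI's `--seed` controls everything.

## What the synthetic cohorts emulate

Real reference cohorts (and the clinical datasets the method was designed
for) are access-controlled, so the package ships a generative cohort module
used by every test. Healthy features are jointly Gaussian given covariates:

x = baseline + age_slope * (age - 29.5) + sex_offset * 1[male] + L f + noise,

with integer ages uniform on 22-37, latent factors `f ~ N(0, I)` inducing
inter-regional correlation through the loading matrix `L`, and independent
per-region noise. Defaults emulate adult morphometry: thickness ~2.5 mm
(total SD ~0.14 mm), volumes ~5000 mm^3 (total SD ~540 mm^3), ~60% of
variance shared through 12 factors, mild cortical thinning with age, larger
volumes in males. Patients differ by mean shifts on selected regions,
expressed in units of each feature's *marginal SD* (the features mix mm and
mm^3, so effect sizes must be scale-free), and/or by a replaced loading
matrix — `decorrelate_loadings()` changes a region's correlation pattern
while preserving its marginal variance, the "covariance-only" alteration
that univariate analysis cannot see.

The generator does **not** emulate site/scanner batch effects, head-motion
artefacts, segmentation failures, non-Gaussian tails, or clinical
heterogeneity (every patient gets the same shift). Passing tests therefore
show that the implementation recovers what this generative family plants —
they do not certify performance on real scanners or real disorders.

## Numerical choices and degenerate inputs

* SELU constants lambda = 1.0507..., alpha = 1.6733...; SELU layers are
  initialized LeCun-normal, the softmax heads and linear output
  Glorot-uniform; biases start at zero.
* Adam uses beta1 = 0.9, beta2 = 0.999, eps = 1e-8; data are reshuffled
  every epoch from the run seed; the short remainder batch is kept.
* A non-finite loss aborts training with the epoch and per-term values.
* Zero-variance features get their SD floored (with a warning) rather than
  producing NaNs; identical group samples give p in the no-evidence region
  (p ~= 1) rather than an error.
* Grid-search and cost-selection ties resolve deterministically (first /
  smaller candidate).

## Simulation sizes used by the checks

The verification suite runs at sizes chosen to make each property
measurable at desk scale: parameter recovery uses a reference cohort of
1000 with 100 controls / 100 patients, 0.8-SD shifts in 8 of 104 regions,
and 500-epoch trainings over ten seeds; null calibration uses one 600-subject
reference model and 100 simulated null cohorts; the linear-bottleneck bound
compares a 1500-epoch fit on 75-factor data (n = 1000) against the rank-75
PCA train-set oracle; bootstrap checks run 50-100 repetitions with 40-epoch
retrainings on a 300-subject reference. For the bound experiment the
corruption and L2 regularizers are disabled and the Adam schedule is
lowered to 0.005 -> 5e-5: the default 0.05 schedule — appropriate for the
strongly structured data the default configuration targets — does not settle
into the many weak directions of a spectrally flat 75-factor model, and the
experiment is designed to measure representational capacity, not the
regularized training compromise.

## Known limitations

* The deviation metric is a *total* score; the model cannot report the
  direction of an alteration (increase vs decrease), only its magnitude.
* Regional deviation maps inherit the model's multivariate nature: a region
  can deviate because its own value shifted *or* because its relation to
  other regions changed. That is a feature for detection and a caveat for
  interpretation.
* Training is CPU-bound base R; at the default 2000 epochs on 1000 subjects
  expect minutes, not seconds. There is no GPU path.
* The heads assume the 16-class age coding; cohorts outside 22-37 need a
  different `label_coding` and retraining.

## A minimal run

```{r example, eval = FALSE}
co <- generate_cohort(cohort_spec(
  n_reference = 1000, n_controls = 100, n_patients = 100,
  affected_regions = c(3, 17, 40, 60, 75, 88, 95, 101), shift_sizes = 0.8,
  seed = 1))

fit <- train_normative(co$reference, model_config(epochs = 500, seed = 1))

dev <- compute_deviations(fit, co$clinical)
pat <- dev[dev$group == "PAT", ]
hc  <- dev[dev$group == "HC", ]

compare_groups(pat, hc)          # U, p, Cliff's delta, group summaries
regional_comparison(pat, hc)     # per-region map, sorted by |delta|
```
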