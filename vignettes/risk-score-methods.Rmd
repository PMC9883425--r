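---
title: "Building and validating a deep-feature pathological risk score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating a deep-feature pathological risk score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pathRS)
```

## The problem and the model

Early-stage cervical cancer treated by radical surgery has a generally
favorable prognosis, but a minority of patients progress, and the routine
clinicopathological factors (FIGO stage, histology, margins, parametrial
invasion, nodal status, LVSI, stromal invasion depth, tumor size) leave
substantial prognostic information on the table. Digitized H&E whole-slide
images (WSIs) of the resected tumor carry that information implicitly.
pathRS implements a pipeline that turns one annotated WSI per patient into
a scalar **pathological risk score (RS)** for overall survival (OS) and
disease-free survival (DFS):

1. **Tiling.** The pathologist-annotated tumor region of interest (ROI) is
   cut into non-overlapping 512×512 patches (`tileROI()`); a patch is kept
   when at least half of its pixels fall in the ROI. Coordinates are
   0-based, half-open, enumerated row-major, so every downstream feature
   matrix has a reproducible row order.
2. **Stain normalization.** Staining, scanners and lighting shift slide
   colors between patients. Each patch is decomposed into two stain
   components by Macenko-style optical-density factorization
   (`fitStainReference()`): pixels are mapped to optical density
   (Beer–Lambert, base 10), stained pixels are projected onto the best-fit
   plane, and the robust angular extremes (1st/99th percentile) of the
   projected cloud are taken as the stain vectors. Concentrations are
   rescaled so their 99th percentiles match a fixed reference patch, and
   the image is rebuilt with the reference basis (`normalizePatch()`). The
   reference patch is the first tissue patch of a configurable reference
   patient, recorded in the run manifest.
3. **Patch features.** A pluggable backbone maps every patch to a
   2048-dimensional nonnegative vector (`extractFeatures()`). The default
   in all tests is a deterministic **surrogate backbone** — block-mean
   pixel statistics under a fixed random rectified projection — which
   needs no weight files and is bit-reproducible from its seed. A
   pretrained-CNN path (global-average-pool head, inputs resized to 224)
   is declared but requires externally supplied weights and is never
   needed for validation.
4. **Deep-encode (DE) features.** A dense autoencoder
   2048→512→128→512→2048 with rectified-linear hidden layers, mean-squared
   reconstruction loss, batch size 32 and 150 epochs (`trainAutoencoder()`)
   compresses each patch vector to the 128-wide bottleneck activation
   (`encodeFeatures()`). The training pool samples 10% of each patient's
   patch rows (at least one per patient), split 80/20 into train and
   validation.
5. **Patient aggregation.** A patient's DE rows are averaged per dimension
   into one 128-d PDE vector (`aggregatePatient()`); the cohort is split
   3:1 into training and testing, stratified on the endpoint's event flag
   (`splitCohort()`).
6. **Stability selection.** 1000 times (configurable 50–1500), half of the
   training patients are drawn without replacement and an elastic-net Cox
   model (mixing 0.5, penalty by 5-fold cross-validated partial
   likelihood) is fitted; features with nonzero coefficients are counted.
   The top 15% of the 128 dimensions by frequency (19 features; an exact
   count such as 18 can be forced) are the salient PDE features
   (`stabilitySelect()`).
7. **Risk score.** A multivariable Cox model (Efron ties) on the selected
   features yields the signature `Sig_i`; the **RS** is
   `Score_i = Sig_i / sqrt(sum_k Sig_k^2 / n)` (`rmsNormalize()`), so the
   mean squared score is exactly 1 on the normalizing cohort. The
   root-mean-square divisor is frozen on the training cohort and reused on
   test patients to avoid leakage.
8. **Stratification.** The RS threshold is found by an X-tile-style scan
   (`findCutpoint()`): all midpoints of consecutive unique training scores
   are candidate cutpoints, each group must keep ≥10% of patients and ≥1
   event, and the candidate maximizing the two-group log-rank chi-square
   wins. High risk is `score >= cutpoint`. The same threshold stratifies
   the testing cohort and all clinical subgroups.

Evaluation (`survival-eval`) covers Harrell's C (with seeded percentile
bootstrap CIs), IPCW cumulative/dynamic time-dependent AUC at 36 and 60
months, Kaplan–Meier curves and log-rank tests, univariate and
multivariable Cox hazard-ratio tables with likelihood-ratio p-values, a
clinical baseline Cox model for comparison, subgroup analyses by FIGO
stage, clinicopathological risk status (high = any of LN metastasis,
parametrial invasion, positive margin, or ≥2 of LVSI / deep stromal
invasion / tumor >4 cm) and positive-LN count, and the
cohort-characteristics association tests (Fisher exact or Yates-corrected
chi-square).

## The synthetic cohort: what it emulates and what it does not

No patient data ship with the package; every claim is validated on
synthetic cohorts with known ground truth (`simulateCohort()`):

* Each patient has a latent factor vector (10 factors by default, 3 of
  them prognostic with log-hazards (1, 1, −1)). Patches observe the
  latent vector plus per-patch jitter (sd 0.3) through a nonnegative
  2048×10 loading matrix, plus feature noise (sd 0.1), clipped at zero so
  features resemble post-activation CNN outputs.
* Survival follows a Weibull proportional-hazards model (shape 1.5) on
  the prognostic factors; censoring is an independent uniform 60–100
  month follow-up window. The baseline scale is calibrated by
  root-finding so the realized OS censored fraction matches the target
  (default 0.90, i.e. ~10% deaths); a coupled relapse process is
  calibrated the same way to a ~19% DFS event fraction, and
  `dfs_time = min(death, relapse, censoring)` so DFS never exceeds OS.
  These targets mirror the event fractions of a 251-patient early-stage
  cervical-cancer cohort followed 5–8 years, which is also the default
  cohort size (189 training / 62 testing at the 3:1 split).
* Clinical covariates are drawn independently of survival, with category
  frequencies typical of such a cohort. They are genuinely
  noise — which is exactly what makes them the right null baseline for
  the model-comparison claim (the RS should beat a clinical model when
  only the image features carry signal).
* `simulateToySlides()` draws small two-stain textured "tissue" images
  with per-patient channel gains and ROI masks. They exercise tiling and
  normalization code paths only; no histomorphology is attempted.
* `simulateDECohort()` plants hazards directly in 128-d patient-level
  features, the natural ground truth for the selection and Cox stages.

Passing tests on these cohorts show that every stage does what it claims
under a correct proportional-hazards generative model with linear latent
structure. They cannot show that real WSIs satisfy those assumptions, that
a CNN backbone extracts prognostic texture, or how the pipeline behaves
under non-proportional hazards, informative censoring, or site batch
effects beyond global color shifts.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `patchSize`, `stride` | 512, 512 | px | native tiling size; non-overlapping grid keeps patches independent |
| `minRoiFraction` | 0.5 | — | a patch is "tumor" when at least half its pixels are annotated |
| autoencoder widths | 2048-512-128-512-2048 | units | fixed architecture; 128 is the DE dimension |
| `batchSize`, `epochs` | 32, 150 | — | training schedule of the compression stage |
| `learningRate` | 1e-3 | — | Adam step size |
| `trainFractionPerPatient` | 0.10 | — | per-patient sampling keeps slow patients from dominating the pool |
| `nRepeats` | 1000 | — | subsample screenings; 50–1500 supported, compared by `compareRepeatCounts()` |
| `subsampleFraction` | 0.5 | — | half-sampling is the standard stability-selection regime |
| `alpha` | 0.5 | — | elastic-net mixing: sparsity with grouping of correlated dimensions |
| `topFraction` | 0.15 | — | top 15% of 128 = 19 features; `exactCount` forces e.g. 18 |
| `minGroupFraction` | 0.10 | — | cutpoint scan keeps both risk groups viable (≥10% and ≥1 event) |
| `horizons` | 36, 60 | months | the 3- and 5-year AUC operating points |
| `nBoot` | 200 (pipeline), 1000 (reporting) | draws | percentile bootstrap for C/AUC CIs |

## Numerical and design choices

* **Autoencoder initialization.** Weights are Glorot-uniform with zero
  biases. With strictly nonnegative inputs, larger symmetric
  initializations let early adaptive-gradient steps silence most of the
  rectified bottleneck, and training stalls at the reconstruction error
  of the surviving units; the smaller Glorot scale keeps enough bottleneck
  units active and training then reliably explains >99% of the variance
  of low-rank data. Inputs are min-max scaled to [0,1] per dimension with
  the scaler fitted on the training pool and stored with the model.
* **Reconstruction "accuracy".** A mean-squared-error regressor has no
  canonical accuracy; the history reports the fraction of reconstructed
  entries within 0.05 of the scaled input as a descriptive surrogate,
  never used for selection or acceptance.
* **Elastic-net path.** Per-repeat penalties come from 5-fold
  cross-validated partial likelihood on a 50-point path truncated at 5%
  of the maximal penalty; subsamples with fewer than two events are
  redrawn (at most 100 attempts).
* **Tie handling.** Efron's approximation everywhere (month-resolution
  times tie often); Breslow available by configuration.
* **Cox convergence.** A signature fit is rejected when any standardized
  effect `|beta|·sd(x)` exceeds 50 (monotone-likelihood guard); the raw
  coefficient scale is meaningless for tiny-variance DE dimensions. In
  hazard-ratio tables, a non-converging or constant covariate is flagged
  per row rather than failing the table.
* **Two-sided Fisher p.** Probability-ordering convention (sum of
  hypergeometric probabilities of tables no more probable than observed);
  stated because two-sided conventions differ. The
  cohort-characteristics rule uses Fisher when any expected cell is
  below 5, otherwise the Yates-corrected chi-square; this single rule
  reproduces all printed reference p-values simultaneously.
* **IPCW AUC.** Cases up to the horizon are weighted by the inverse
  left-limit Kaplan–Meier censoring survival at their event times;
  control weights cancel. With no censoring the estimator reduces exactly
  to the rank-sum AUC, which is property-tested.
* **Cutpoint scan.** No multiplicity correction is applied across scan
  candidates: a single chosen threshold is applied unchanged to the test
  cohort, and the scan table is returned for audit. Whether the X-tile
  program's internal criterion is exactly the log-rank maximum is
  unknown; this is an emulation.
* **One shared split.** OS and DFS pipelines share one 3:1 split
  (stratified on a configurable event flag) by default; per-endpoint
  selection, signature, normalization and threshold are always separate.
* **Degenerate inputs.** Empty masks tile to zero patches; blank patches
  fail stain fitting with a "degenerate stain" error, and normalization
  passes such patches through flagged; constant feature columns are
  dropped before selection and can never be selected; zero margins give
  Fisher p = 1 with a flag.
* **Seed fan-out.** Every pipeline stage derives its seed from the global
  seed (`deriveSeed()`), so a stage can be rerun in isolation and two
  runs of one config are byte-identical under the surrogate backbone.

## Validation problem sizes

The shipped validation suite runs cohorts of 40–300 patients with 2–8
patches each, the autoencoder's low-rank reconstruction check on 200×2048
matrices of intrinsic rank 10 (120 epochs), stability selection at 8–200
repeats (100 repeats for the planted-recovery checks), and ten end-to-end
251-patient cohorts at 40 autoencoder epochs and 100 screening repeats.
These sizes were chosen so the full suite exercises every stage at
realistic cohort scale while remaining comfortable on a single CPU;
configurations up to the full 150-epoch / 1000-repeat defaults behave
identically, only slower.

## Known limitations

* The CNN backbone is declared but not bundled; all validation uses the
  surrogate. Conclusions about real pretrained features require supplying
  that path.
* The synthetic generator is linear-Gaussian in its latent structure;
  selection consistency under heavy-tailed or nonlinear feature–hazard
  links is untested.
* The cutpoint scan emulates, but cannot be verified against, the
  proprietary X-tile behavior.
* Competing risks and proportional-hazards diagnostics are out of scope.
* With ~10% event rates, test cohorts of ~60 patients yield wide C-index
  and AUC intervals; the bootstrap CIs make that visible rather than
  fixing it.
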