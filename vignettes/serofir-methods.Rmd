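---
title: "Methods: serum FTIR fingerprinting from quality control to CNN classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum FTIR fingerprinting from quality control to CNN classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

serofir implements a complete chemometric and machine-learning workflow for
stratifying dried-film serum mid-infrared spectra into healthy (non-allergic),
allergic, and immunotherapy-treated (tolerized/SIT) groups. Because no
public serum FTIR cohort with this design exists, the package ships a
synthetic-spectrum generator with the statistical structure the analysis
assumes, and every downstream stage is exercised and tested against it.
This vignette explains each stage's model, the tunable parameters and their
defaults, the design decisions taken where the protocol left choices open,
and what the synthetic benchmark does and does not establish about real
data.

## The synthetic serum cohort

A clean spectrum is a sum of Gaussian absorbance bands on a wavenumber grid,

$$x(w) \;=\; \sum_b A_b \, c_b(\text{class}) \, s_b(\text{subject})\,
  g\!\left(\frac{w - \mu_b}{\sigma_b}\right),$$

with eleven default bands placed in the canonical assignment ranges of the
1800–900 cm⁻¹ fingerprint window: ester carbonyl (1740), amide I/II
(1655/1545), CH₂ (1455), collagen/amide III (1310/1240), phosphate diester
(1235), and four carbohydrate bands (1165/1120/1080/1030 cm⁻¹). The profile
$g$ is a Gaussian truncated at $\pm 4\sigma$ (rescaled so its peak is
exactly 1), which makes class effects *exactly* local to their bands — a
property the test suite asserts.

Class structure: the allergic class scales the ester band by +10% and the
amide I/II bands by −8%; the tolerized class scales the carbohydrate bands
by +8%. These magnitudes are benchmark choices, not estimates of serum
biology (the `separation` knob halves or doubles them on the log scale).
Subject-level biology is a log-normal factor per band with log-sd
`subject_sd` (0.03 for the human preset, 0.015 for the inbred mouse
preset); log-normality keeps amplitudes positive.

Each replicate film adds, in order: multiplicative scatter
$x \mapsto b\,x + a$ with $b$ log-normal (log-sd 0.05) and $a$ normal
(sd 0.01 AU); a random degree-2 polynomial baseline (coefficient sd
0.005 AU on a grid rescaled to $[-1, 1]$); a comb of 12 fixed narrow
(σ = 2 cm⁻¹) residual water-vapor lines between 1900 and 1400 cm⁻¹ scaled
by a N(0, 1) multiplier times 5·10⁻⁴ AU (over- and under-compensation);
per-batch grid shift (one 1.5 cm⁻¹ step) and gain (1.05) for batches beyond
the first; and white noise (sd 0.002 AU). A configurable fraction of
spectra (2% in the shipped presets) is replaced by gross outliers — 10×
amplitude scaling, a saturated 4 AU flat top across 1700–1600 cm⁻¹, or a
+3 AU sloped baseline — with the truth table recording which.

The default grid runs 499.5–4000.5 cm⁻¹ in 1.5 cm⁻¹ steps. The half-step
anchoring is deliberate: it places 900 and 1800 cm⁻¹ exactly on the grid,
so the closed truncation window contains 601 points; instrument grids are
anchored by the laser wavenumber and are never round numbers. Reproducibility
is structural: subject-level draws come from per-subject seeded streams, so
growing the replicate count never changes existing subjects' spectra, and
equal configurations give byte-identical datasets.

What the generator does **not** emulate: interferogram-level physics
(apodization, zero-filling), Mie or resonant scattering distortions,
correlated biochemical covariation between bands, age/sex covariates, or
instrument drift within a batch. Consequences for interpretation are
discussed at the end.

## Quality control

The two-stage QC mirrors common spectrometer-software practice. Stage one
is a three-criterion quality test with explicit windows: maximum
fingerprint-window (1800–900) absorbance inside
[`absorbance_min`, `absorbance_max`] = [0.05, 1.5] AU; a signal-to-noise
ratio — amide-I maximum above the chord through the 1700–1600 cm⁻¹ window
edges, divided by the sd of the linearly detrended 2200–1900 cm⁻¹ residual —
of at least 50; and a water-vapor score, the peak-to-peak of the
Savitzky–Golay second derivative inside 1847–1837 cm⁻¹, of at most
3·10⁻⁴ AU/(cm⁻¹)². The water threshold was calibrated once against the
generator's default artifact levels (≈2.4× the clean-data 99th percentile);
at the default noise level the smoothed second derivative only rises
clearly above its noise floor for strong contamination, so this criterion
is a gross-contamination guard rather than a sensitive detector.

Stage two fits a PCA outlier model to the mean-centered raw spectra,
retaining the smallest component count whose cumulative explained variance
reaches `variance_fraction` (default 0.95). Hotelling's
$T^2_i = \sum_{j \le k} t_{ij}^2/\lambda_j$ is charted against the
$F$-based limit $k(n-1)/(n-k)\,F_{1-\alpha}(k, n-k)$, and the residual
$Q_i = \lVert x_i - \hat x_i \rVert^2$ against the Jackson–Mudholkar
limit computed from the residual eigenvalues. On this generator's data the
residual eigenvalue spectrum is heavy-tailed and the Jackson–Mudholkar
exponent $h_0$ can turn negative, where the normal-power approximation
degenerates; the implementation then falls back to the matched-moment
$g\chi^2_h$ limit ($g = \theta_2/\theta_1$, $h = \theta_1^2/\theta_2$).
A spectrum passes QC iff all three quality booleans hold and both chart
statistics sit below their limits.

Two honest calibration facts, both computed by the tests and analysis
scripts: the $F$-based $T^2$ limit holds its nominal 5% level on
multivariate-normal scores, but on the generator's clustered, log-normal
cohorts the combined exclusion rate of the two α = 0.05 charts plus the
quality test sits near (sometimes marginally above) 9–10%, i.e. a clean-data
pass fraction near 90% rather than 95%. This is the expected behavior of
normal-theory control limits on non-normal data — the same non-normality
the Mardia screen below reports — and we report it rather than widening the
default limits.

## Preprocessing

The five-step chain runs in fixed order:

1. **Truncation** to the closed 1800–900 cm⁻¹ fingerprint window
   (601 points on the default grid).
2. **Savitzky–Golay second derivative**, 15-point window, fitting
   polynomial order 3, computed with the physical 1.5 cm⁻¹ step. The
   protocol fixes the window (15 points) and the derivative order (2) but
   not the fitting order; 3 is the common chemometrics choice compatible
   with a second derivative. Edge policy: the 7 points at each end, where
   no full window exists, are dropped — no padded values enter later stages
   — leaving 587 points. Smoothing bias scales as (window/band width)²:
   the tests show exact reproduction of polynomial curvature, <2% error on
   a broad (σ = 45 cm⁻¹) Gaussian and <8% on a narrow amide-like
   (σ = 18 cm⁻¹) band.
3. **Multiplicative scatter correction**: per-spectrum OLS of
   $x = a + b\cdot\mathrm{ref}$, corrected spectrum $(x - a)/b$. The
   reference is the mean of the data being corrected — except inside
   cross-validated classification, where it is the training-split mean,
   stored and reused (no test-set leakage). MSC is applied after the
   derivative, following the printed step order.
4. **Unit-vector normalization** to Euclidean norm 1 (film-thickness
   scale removal).
5. **Scaling**: mean-centering for PCA; per-wavenumber standardization,
   train-fitted, for the CNN. The protocol's "scaling" step is not further
   specified; both interpretations are implemented and configurable.

The tests assert the chain's key invariance: a per-spectrum affine
distortion $x \mapsto b x + a$ changes the preprocessed output by less
than 1% RMS.

## Calibration transfer (piecewise direct standardization)

Two acquisition batches differ by a one-grid-step shift and a 5% gain in
the mouse preset. PDS regresses, for every target wavenumber $j$, the
master value at $j$ on the slave window $[j-h, j+h]$ plus intercept
(default half-width 7 points ≈ 21 cm⁻¹, about one band width), solving
each local problem by truncated SVD (relative cutoff 10⁻⁶ guards
collinearity) and assembling a banded operator. PDS is fit on truncated
raw absorbance, before derivative and MSC: standardization corrects the
instrument response, which precedes chemometric correction.

Transfer standards: the simulator renders the same clean spectra under
both batches' conditions. The default standardization set is 60 paired
replicate films (three sera × 20 replicates, the acquisition protocol's
replicate design). This matters: with only 12 noisy pairs the 15-coefficient
local regressions overfit and transfer *amplifies* batch differences; with
60 pairs the between-batch PCA centroid distance collapses to well under a
quarter of its raw value (computed in `analysis/03_transfer.R` and the
acceptance suite). All-constant windows (zero-absorbance regions of
artifact-free data) get intercept-only maps with a single aggregated
warning.

## Unsupervised stratification and the normality screen

PCA uses the SVD of mean-centered rows; explained-variance fractions use
*all* eigenvalues in the denominator, matching the "PC-1 x%" reporting
convention. Scores of new data subtract the model mean, never the new
data's own mean. Sign convention: each loading row's largest-magnitude
element is made positive, so loadings and scores are bit-reproducible.
Group 95% confidence ellipses come from the eigen-decomposition of the 2×2
score covariance scaled by the χ²(2) quantile; Monte-Carlo coverage is
asserted at 0.95 ± 0.02.

Mardia's multivariate skewness ($n b_1/6$ against
χ² with $d(d+1)(d+2)/6$ df) and kurtosis ($z$ against $d(d+2)$ with
variance $8d(d+2)/n$) screen the preprocessed scores for multivariate
normality; on spectra with more variables than observations the test runs
on leading PCA scores and flags that it did so. Royston's test is omitted:
it only corroborated the nonparametric framing, and Mardia alone decides
the screen here (a recorded deviation).

## Supervised classification

**Splits.** A 65/20/15 train/validation/test design and 10-fold
cross-validation are mutually inconsistent prescriptions (a 15% test set is
not a 1/10 fold), so the cross-validation here is repeated hold-out: 10
independent stratified 65/20/15 splits, with all repeats' test predictions
pooled into one confusion matrix. Stratification is by class with
largest-remainder rounding, deterministic under (seed, repeat).

Two grouping modes exist because replicate spectra of one subject can
legitimately be split together or apart, and the choice changes what the
metrics mean. `"spectrum"`
assigns individual spectra (the literal "65% of the spectra" reading — the
protocol under which the reference metrics were printed); `"subject"`
keeps all replicates of a subject in one subset, preventing replicate
leakage. The shipped benchmark (`run_human_benchmark()`) uses spectrum
mode to reproduce the reference operating point; the analysis scripts also
run the subject-grouped variant, the scientifically honest generalization
estimate — expect it lower (and with per-subject error blocks of ~20
replicate spectra), since there the classifier must generalize to unseen
subjects rather than to unseen replicate films of known subjects, from a
training sample of only 39 subjects. `analysis/05_classify.R` and
`analysis/06_evaluate.R` compute and report both.

**Network.** The 1D CNN is implemented from scratch in RcppArmadillo
(valid convolutions via im2col + GEMM): `section_depth` conv blocks
(conv + ReLU + max-pool, filters doubling from `n_filters`, capped at 64),
two further conv + max-pool blocks, one dense hidden layer (64 units) with
dropout 0.3, and a softmax output of size 3. With zero biases an all-zero
input produces exactly uniform probabilities, a symmetry the tests use.
Ties at the argmax resolve to the lowest class index, with the fixed class
order (non-allergic, allergic, tolerized).

**Training.** Plain SGD with momentum and L2 weight penalty (adaptive
optimizers deliberately excluded — the tuned variables are the classical
four: depth, initial learning rate, momentum, L2), batch size 32, at most
150 epochs, early stopping when validation classification error fails to
improve for 15 epochs, restoring the best-validation weights. Per-epoch
training metrics are running minibatch statistics; validation metrics are
full-set. Divergence (non-finite loss) is a labelled error reporting the
epoch and learning rate. Given fixed seeds the C++ mt19937 generator makes
splits, initialization, shuffling and dropout — and therefore the trained
weights on one platform — reproducible; bit-identical weights across BLAS
builds are not promised.

**Hyperparameter search.** A Gaussian-process surrogate (squared-
exponential kernel on the unit-cube encoding of the mixed space, fixed
length-scale 0.25) with expected-improvement acquisition, seeded by a
maximin Latin hypercube, budget 15; a pure random-search mode is retained
as a control and fallback. The space: section depth 1–3, log-uniform
learning rate 10⁻³–10⁻¹, momentum 0.5–0.95, log-uniform L2 10⁻⁶–10⁻³,
kernel size {3, 5, 7}, first-block filters 4–16. Candidates failing
(divergence) are recorded and skipped by the surrogate. The search runs
once on the first split and trains each candidate with a truncated budget
(40 epochs, patience 5) — standard practice that ranks settings at a
fraction of full cost; the ten final models then train with the full
budget. Optimizing once and then cross-validating the chosen setting keeps
the selection step out of the repeated test sets.

**Evaluation.** One-vs-rest TP/TN/FP/FN per class from the pooled matrix;
sensitivity, specificity and PPV per the standard definitions, with zero
denominators reported as explicit undefined markers (silent zeros corrupt
averages). Micro-averaged, prevalence-weighted sensitivity equals overall
accuracy — asserted numerically. The confusion structure exports as a
chord-diagram edge list (source = true class, target = predicted class,
weight = count); graphical rendering is out of scope.

## Problem sizes and run times

The shipped benchmark is the full study condition: 1200 spectra
(3 × 20 × 20), QC, 10 repeated splits, search budget 15 — about 12–15
minutes on one CPU. Unit and property tests run on reduced cohorts
(3–8 subjects per class, 4–10 replicates) chosen so each property is
still identifiable; the Monte-Carlo calibration checks use n = 2000 score
vectors (T² level) and five 1200-spectrum clean cohorts (exclusion rate).

## Known limitations

* The class-effect magnitudes and subject variability are invented
  benchmark conditions; passing metrics demonstrate that the pipeline can
  deliver the reference operating point *on data with comparable class
  structure*, not that it would on real sera.
* Replicate-level (spectrum-mode) splits share subjects between train and
  test; their metrics measure replicate recognition plus class structure.
  Subject-mode results are the generalization estimate.
* The QC surrogate reimplements the three named criteria with explicit
  windows but does not reproduce any proprietary tool's numeric thresholds.
* PDS assumes a common grid (resampling is the caller's job) and paired
  transfer measurements; Direct Standardization and warping methods are
  out of scope.
* JCAMP-DX support covers `(X++(Y..Y))` with AFFN/SQZ/DIF/DUP and
  `XYPOINTS`; other compression schemes are rejected with a clear error.
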