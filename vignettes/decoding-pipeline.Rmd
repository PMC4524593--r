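---
title: "Decoding brain states from BOLD timeseries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding brain states from BOLD timeseries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The analysis

`boldmvpa` implements TR-level multivariate pattern analysis (MVPA) of a
two-condition script-driven imagery design: a participant repeatedly
recalls a trauma memory and a neutral memory, each repetition acquired as
a separate ~3-minute EPI run (TR = 2 s, 3 mm isotropic), and a classifier
is trained to predict, from a single volume's voxel pattern, which memory
the participant is recalling. The pipeline is:

1. **Preprocessing** (`preprocess_subject()`): per run, nuisance
   regression against the 24-term Volterra expansion of the six
   rigid-body motion parameters `[R, R^2, R_{t-1}, R^2_{t-1}]` plus mean
   WM and CSF signals; optional iterative smoothing to a target FWHM
   (default 8 mm); polynomial detrending (default order 2); percent
   signal change (PSC) scaling.
2. **Feature construction** (`build_features()`): all TRs of the first
   *k* repetitions of each condition, voxels restricted to a mask,
   z-scored per voxel over the included timeseries.
3. **Decoding** (`mvpa_decode()` / `run_cv()`): 10-fold cross-validation
   over a random TR partition; an RBF-kernel support vector machine with
   `C = 100` and `gamma = 1/P`; accuracy is the median fold accuracy;
   sensitivity/specificity are pooled over held-out predictions; the
   feature-weight map is the per-voxel median across folds of the dual
   pre-image `sum(alpha_i y_i x_i)`.
4. **Methodological permutations** (`run_subject()`): smoothing on/off ×
   training repetitions 1-5 × feature mask (whole GM, eight 6-mm
   PTSD-neurocircuitry ROI spheres, GM minus those ROIs, ten random ROI
   sets).
5. **Reproducibility** (`cross_model_similarity()`): Fisher-z spatial
   correlations among the weight maps of the one- to five-run models.
6. **Group statistics** (`onesample_t_map()`, `robust_regress_map()`,
   `cluster_threshold()`, `roi_level_tests()`): cross-subject inference
   on weight maps, with cluster-extent correction (default: voxel
   p < .01, 47 contiguous voxels) and ROI-level tests.
7. **Motion control** (`motion_control_cv()`): the identical classifier
   with labels replaced by a median split of framewise displacement
   (FD, the sum of absolute temporal differences of the six motion
   parameters), establishing that condition decoding is not motion
   artifact.

# The synthetic-data generator

No public dataset accompanies this design, so `generate_subject()` /
`generate_cohort()` produce data with known ground truth. Per subject,
`2 * n_runs_per_condition` task-only runs are simulated on an ellipsoidal
"brain" (outer GM shell, WM shell, CSF core) with:

* voxelwise AR(1) noise (default lag-1 correlation 0.3, typical of 2-s
  TR data), with stationary SD equal to 1% of the 1000-unit baseline so
  PSC units are natural;
* random per-voxel linear + quadratic drift (default SD 2 noise units);
* shared nuisance signals: temporally smooth (AR 0.5) WM- and
  CSF-compartment signals that bleed weakly into GM — exactly the
  components the WM/CSF mean regressors exist to remove — plus a
  temporally white global component;
* head motion as a bounded six-parameter random walk (default step SD
  0.05 mm/deg), written into the run's motion table (the simulated
  images are already "aligned": realignment is out of scope);
* a condition signal: a spatially clustered set of GM voxels
  (`n_signal_voxels`, default 2500 of the ~3700 default-grid GM voxels)
  with signed amplitudes of `effect_size` noise-SD units, added to
  trauma runs only.

## Why the signal is envelope-modulated

Every preprocessing stage that operates per run (nuisance intercept,
detrending, PSC) removes each voxel's within-run mean. A constant
condition offset therefore cannot survive preprocessing: after per-run
centring, the trauma and neutral class means are *identical by
construction*. The generator consequently modulates the pattern in time
with a blocked engagement envelope (duty cycle 0.35, period 8 s, random
phase per run, amplitude normalized so the mean absolute per-voxel
deviation equals `effect_size`). The envelope is mean-zero within a run
(so it passes through preprocessing undistorted) while making single
trauma TRs separable from neutral TRs; its asymmetry — short strong
peaks against long shallow troughs — mimics narrative "hot spots" and
gives the decision function a consistent direction along the pattern.

Signal extent defaults to roughly two thirds of grey matter. That choice
mirrors the design's own conclusion that the discriminating network is
brain-wide and distributed (decoding survives removal of any specific
ROI set), and it matters quantitatively: with the feature-count kernel
scaling `gamma = 1/P` the kernel is nearly linear at these problem
sizes, and TR-level separability grows with the *fraction* of features
carrying signal, not with per-voxel amplitude alone.

Non-stationarity across repetitions — the observation that repeated
trauma recall changes the engaged network — is modelled as partial
resampling: between repetitions *k* and *k+1*, a fraction
`nonstationarity` of the signal support moves to fresh GM locations
(`nonstationarity = 1` makes successive supports disjoint). This is a
modelling device reproducing the diminishing-returns reproducibility
curve, not a claim about the underlying biology.

Cohorts draw severity from a PCL-like distribution (mean 62, SD 13,
clipped to 17-85), age ~ N(34, 11), depression comorbidity 44%, and
substance-use comorbidity 25%. With `severity_coupling = c`, voxels in
the designated coupling ROI (a 6-mm sphere at the left
amygdalohippocampal coordinate, snapped into GM on small grids) carry
amplitude `effect_size + c * z(severity)`, giving group-level severity
regressions a known target.

# Preprocessing choices

* **Volterra lag boundary**: the lagged terms at t = 1 are zero-padded;
  no TR is dropped, keeping label alignment trivial.
* **Order**: nuisance regression → (optional) smoothing → detrending →
  PSC. Placing PSC last makes the output directly usable as "% signal
  change" features; the PSC denominator is the voxel's baseline mean
  from the raw data, since the residualized series is already centred.
  Polynomial terms can instead be included in the nuisance model
  (`nuisance_polyorder`), but by default drift removal is left to the
  dedicated detrend step.
* **Rotations** enter the nuisance model and FD in native degrees; no
  lever-arm conversion is applied.
* **Smoothness estimation** (`estimate_fwhm()`): from temporally
  differenced data (successive-volume differences suppress task
  structure and drift), the per-axis ratio of neighbouring-voxel
  difference variance to total variance is converted to a Gaussian FWHM
  via `FWHM = sqrt(8 ln 2) * v / sqrt(2 * var(diff)/var)`, and the three
  axes are averaged. White noise reads ~1.18 voxel widths; a spatially
  constant field returns the sentinel `Inf`.
* **Iterative smoothing** (`smooth_to_fwhm()`): incremental Gaussian
  kernels sized by quadrature (`sqrt(target^2 - current^2)`, damped by
  0.9 to avoid overshoot) until the estimate is within `tolerance_mm`
  (default 0.5) of the target; the kernel rows are renormalized at the
  boundary so per-volume means are preserved to well under 1%.
* **Near-zero PSC denominators** (|baseline| below 1% of the global
  in-mask mean) produce zeros, not huge values, and are counted.

# Decoding choices

* `C = 100`, RBF kernel, `gamma = 1/P` (the cited solver's
  feature-count default), both configurable. No hyperparameter search.
* z-scoring uses the statistics of the full included timeseries,
  matching the described procedure; `leakage_safe = TRUE` re-scales
  each training fold with its own statistics and is the recommended
  deviation when leakage matters more than fidelity.
* Random TR-wise folds are the default; `cv_config(contiguous = TRUE)`
  gives a block-wise sensitivity analysis.
* Sensitivity and specificity are pooled over the held-out predictions
  of all folds (well-defined even when single folds are tiny); the
  positive class defaults to the trauma condition.
* Folds whose training half contains one class abort with the fold
  index; nothing is skipped silently.
* **Weight maps**: for a nonlinear SVM the reported "feature weights"
  are not primal weights; they are the support-vector-coefficient-
  weighted sum of support vectors. Interpretation caveats below.

# Group statistics choices

* Robust regression is Huber M-estimation (tuning constant 1.345, IRLS,
  tolerance 1e-8, max 50 iterations) with t-type statistics on n - p
  degrees of freedom. Normal-theory p-values for the severity slope are
  accurate from cohort sizes of a few dozen (the packaged calibration
  checks run at n = 50, where the empirical type-I rate matches the
  nominal 5%); at n = 16 they are mildly anticonservative (~6-7% at
  nominal 5%), which should be kept in mind when reading the ROI tables
  at original-study scale.
* Cluster connectivity defaults to the 26-neighbourhood; 6 and 18 are
  available. The 47-voxel default extent is an input convention tied to
  the original data's smoothness — when analysing other data,
  `estimate_cluster_extent()` recomputes it by Monte Carlo: smooth
  Gaussian null volumes at the stated FWHM are thresholded two-sided at
  the voxel p, and the extent is set just above the
  `1 - target_corrected_p` quantile of the maximum cluster size.
* Binary covariates enter as 0/1 without scaling; zero-variance voxels
  get sentinel p = 1 and are counted, never dropped silently.

# Numerical conventions

* Perfect spatial correlations are reported as ±18.7 (the order of
  `atanh(1 - 1e-16)`) so similarity tables stay numeric.
* FD at the first TR is 0 (no predecessor); median-split ties go to the
  "low" class, so the split is deterministic.
* Sphere masks snap the centre to the nearest voxel centre and use an
  inclusive boundary (≤ radius): a 6-mm sphere on a 3-mm grid has 33
  voxels (strict inequality would give 27). Random ROI spheres may
  overlap; unions are de-duplicated for feature counting.
* All randomness flows from explicit seeds; seeded helpers restore the
  ambient RNG state, and cohort seeds derive deterministically from the
  cohort seed.

# What the synthetic tests do and do not show

The generator emulates the design's spatial and temporal structure, not
real haemodynamics: there is no HRF convolution, no scanner artifact,
no physiological noise, and the "brain" is an ellipsoid. Passing tests
therefore demonstrate that the *pipeline machinery* is correct and that
its statistics behave as designed under known ground truth — not that
comparable accuracies would be reached on real recordings.

Two structural properties of the design deserve emphasis, because the
test suite measures both:

* **TR-wise cross-validation with run-constant labels is not exactly
  calibrated at chance.** Two opposing label-aligned dependencies exist
  between training and test rows: per-run centring forces each run's
  TRs to sum to zero per voxel, anti-correlating a held-out TR with its
  trained run-mates (a below-chance push), while temporally
  autocorrelated noise makes a held-out TR's temporal neighbours
  systematically closer in feature space (an above-chance push). Both
  grow with the voxel count. Labels that are *not* run-aligned do not
  inherit either bias: label-permutation nulls are calibrated (and are
  tested), and the motion-control classifier — whose high/low-motion
  labels interleave within runs — sits near chance on
  motion-independent data, which is exactly why it is the appropriate
  control for this design.
* **RBF weight maps carry no first-order class contrast here.** Because
  per-run centring equalizes the class means exactly, the dual
  pre-image weight map reflects only higher-order asymmetries of the
  support-vector solution, which are an order of magnitude smaller than
  its sampling noise at these problem sizes. Ranking voxels by weight
  magnitude therefore does not recover the simulated signal support,
  even when decoding accuracy exceeds 0.9. Weight maps remain useful as
  *reproducible spatial fingerprints* (their cross-model and
  cross-subject correlation structure is meaningful and is what the
  reproducibility and group modules quantify), but not as univariate
  importance maps — the standard caveat for nonlinear SVM weights, made
  quantitative by the simulation.

# Problem sizes

The package's own checks run on desk-scale grids chosen to keep every
property measurable in minutes on one core: 10-12 voxels per axis
(roughly 250-420 GM voxels) with the study's run length (90 TRs) and
run counts, 300 of 416 GM voxels carrying signal in the
signal-recovery conditions, cohorts of 4-20 for directional and paired
comparisons, and 10-50 seeded replicates for calibration estimates.
Real-size grids pass through the same interfaces unchanged.

# Limitations

Beyond the generator simplifications above: no slice-timing, despiking,
realignment or template registration (inputs are assumed aligned); no
probabilistic atlas lookup (tissue masks are inputs); no permutation
FWE for the voxelwise maps; no multi-class support; and no scrubbing of
high-motion TRs.
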