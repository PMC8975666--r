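---
title: "Methods: Bayesian-network prognosis modelling, phantom segmentation and efficacy evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian-network prognosis modelling, phantom segmentation and efficacy evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prognet)
```

prognet implements a three-part analysis of advanced non-small-cell lung
cancer (NSCLC) treatment data: a Bayesian-network prognosis model learned by
the max-min hill-climbing (MMHC) algorithm, a CT-phantom lesion-segmentation
and measurement pipeline built around a from-scratch backpropagation pixel
classifier, and a RECIST-based efficacy evaluation with Kaplan–Meier
progression-free survival (PFS).  Because no patient-level data are
available, every stage is driven by a synthetic-data generator with a known
ground truth, so each claim the package makes is checkable against that
truth.  This vignette records the models, the tunable parameters, the
numerical choices, and what the synthetic evaluation does and does not show.

## The prognosis model

A discrete Bayesian network is the pair (G, Θ): a directed acyclic graph G =
(V, E) over the clinical variables and, for each node, a conditional
probability table (CPT) P(X_i | Pa(X_i)).  The joint distribution factorizes
as ∏_i P(X_i | Pa(X_i)) (the Markov condition), which is what
`predict_outcome()` sums over when it computes the posterior of survival
status given a patient's evidence by exact enumeration — networks here have
at most 16 nodes, so enumeration is always tractable and no approximate
inference is provided.

### Feature selection

The candidate set is the 16-variable catalog (`variable_catalog()`):
twelve discrete factors and four continuous measurements (diagnosis age,
tumor size, examined and positive lymph-node counts).  Selection follows
the two-step screen used in the source study design:

1. **Chi-square screen** (`chi_square_screen()`): Pearson chi-square of each
   candidate against binary survival status, keep when p < 0.05.
   Continuous candidates are pre-binned with the same equidistant rule used
   later for discretization; the default spec (r = 4 over the observed
   range) applies when no generating spec is supplied.  No continuity
   correction by default — tables are generally larger than 2×2; a Yates
   flag exists for the 2×2 case.  Zero-margin (constant) variables are
   skipped with a warning rather than failing the run.
2. **Logistic filter** (`logistic_filter()`): a maximum-likelihood logistic
   fit of all screened candidates (IRLS, deviance tolerance 1e-8, at most
   100 iterations), retaining variables with Wald p < 0.05 and reporting B,
   its standard error, exp(B) and the Wald interval exp(B ± 1.96·SE).
   Perfect separation aborts with the offending column named; multi-level
   factors enter as treatment-coded dummies with the first level as
   reference (the original study's coding is unknown, so this conventional
   choice is documented rather than inferred).

### Equidistant discretization

`equidistant_discretize()` splits [X_min, X_max] into r equal intervals of
width d = (X_max − X_min)/r and maps x to the level j (0 ≤ j ≤ r − 1) with
X_min + j·d < x ≤ X_min + (j+1)·d.  Intervals are open below and closed
above, and the range minimum is assigned level 0; this makes the map total
and single-valued on the range, which the test suite asserts as a property.
The interval count is deliberately a configuration value (default r = 4 for
a generic continuous variable): the method itself defers r to prior
knowledge, and the generator's own specs use clinically conventional cuts
(age at 65 years, tumor size at 5 cm, examined nodes at 20, positive nodes
at 6).

### Structure learning: MMHC

`mmhc()` runs the hybrid two-stage learner.

**Stage 1 — MMPC skeleton discovery.**  The dependence measure is the
G²-type statistic

Assoc(X, T | Z) = 2 Σ_{a,b,c} N_abc · ln( N_abc · N_c / (N_ac · N_bc) ),

summed over the joint cells of X, T and the conditioning assignment c, with
empty cells contributing zero.  Degrees of freedom are
(|X|−1)(|T|−1)·∏|Z_i|; empty conditioning strata contribute zero to the sum
and are *not* subtracted from the degrees of freedom (the simpler
convention; it is configurable in the sense that the raw statistic and df
are returned, so a caller can re-derive the p-value under a different rule).
MinAssoc minimizes over all conditioning subsets S ⊆ Z up to size `maxk`,
operationalized as the subset with the largest p-value, ties broken by
smallest subset and then lexicographically.  The forward phase repeatedly
admits the variable with the largest MinAssoc (provided its minimizing
p < alpha); the backward phase removes members rendered independent by some
subset of the rest; the symmetry correction then drops X from CPC(T)
whenever T ∉ CPC(X).

Defaults: alpha = 0.05 and maxk = 3.  The exhaustive subset search is
exponential in maxk, and conditioning sets larger than 3 are rarely
informative at cohort-scale n.  A test with fewer than 5 samples per degree
of freedom is flagged unreliable and treated as non-significant — the
standard small-sample guard for G²-type tests; the underlying statistic is
still computed exactly, which is what the oracle-equality tests check.

**Stage 2 — greedy hill-climbing.**  Edges are oriented by a greedy search
over add/delete/reverse moves, additions restricted to skeleton pairs and
cycles forbidden, accepting the best strictly score-improving move until
none remains.  The score is decomposable and cached per (node, parent set).
The scoring function is not named in the study this design follows; BIC is
the default here (parameter count (r−1)·q per node with q parent
configurations) with BDeu (equivalent sample size 10) as an option — both
are score-equivalent over Markov-equivalent DAGs, so purely equivalent
orientations are reported as learned and the test suite compares structures
at the equivalence-class level (CPDAGs via v-structure detection plus the
standard orientation-propagation rules).  All tie-breaks are lexicographic
for determinism.

**Parameters.**  `fit_parameters()` estimates CPT rows as
(count + pseudocount)/(total + pseudocount·levels), pseudocount 1 by
default; with pseudocount 0 an unobserved parent configuration falls back
to a uniform row.

### What the generator emulates

`make_ground_truth()` builds the default seven-node truth: the six final
prognostic variables each a parent of binary survival status, plus one
predictor–predictor edge tumor_stage → positive_lymph_nodes (a
metastatic-burden analogue) so that the conditional-independence search
faces at least one |Z| ≥ 1 case.  The outcome CPT is additive on the
log-odds scale with strong coefficients (|b| between 1.6 and 2.3, intercept
balancing the death rate near 1/2).

Two generator choices deserve explanation:

* **All six predictors are binary.**  Dichotomized grade (low/high), stage
  (IIIB/IV — the cohort is advanced disease by inclusion), and
  median-style cuts for the continuous measurements are standard practice
  in clinical modelling.  They are also what makes the recovery target
  honest: a node with six parents has a CPT whose row count multiplies with
  every parent added, so with multi-level parents the BIC penalty for
  orienting the sixth edge *into* the outcome exceeds any attainable
  likelihood gain at n = 5000 and the collider is not identifiable by any
  score-equivalent search at that sample size.  With binary predictors and
  strong effects the equivalence class is recoverable, which is the regime
  the recovery property is meant to exercise.
* **Continuous values are synthesized level-first.**  A node with a
  generating discretization spec samples its discrete level from the CPT
  and then draws uniformly *inside* that level's interval.  Applying the
  same spec therefore recovers the generating level for every row — a
  crisp, exactly testable inverse — at the cost of continuous marginals
  that are piecewise-uniform rather than smooth.  Real laboratory
  measurements are not piecewise-uniform; nothing downstream depends on
  the shape within a level, but this is a known simplification.

The generator's cohorts also do not emulate missingness, measurement error
in the discrete factors, or correlation among the ten nuisance variables
(they are sampled independently, so the chi-square screen faces a cleaner
null than real registry data would present).  Passing selection and
recovery tests on these cohorts shows the machinery is correct, not that
the model would recover structure from a real 5-year registry.

## The imaging pipeline

Phantoms (`make_phantom()`) are ellipsoidal lesions of known center,
semi-axes, and intensity on a uniform background with additive Gaussian
noise, so the analytic diameter (2 × the largest in-plane semi-axis) and
volume (4/3·π·a·b·c) are available as ground truth.  No anatomical realism
is attempted — the phantom validates the measurement chain, not the
radiology.

* **Wiener denoising** (`wiener_denoise()`): the local-statistics adaptive
  form — output = local mean + max(0, v − ν)/max(v, ν)·(x − mean), with ν
  the mean of the local variances over the window (default 3×3).  Flat
  regions collapse to their mean; edges with variance above the noise floor
  are preserved.
* **Fuzzy enhancement** (`fuzzy_enhance()`): intensities map to memberships
  x/255 and the intensification operator (μ²/c below the crossover
  membership c, 1 − (1−μ)²/(1−c) above) is iterated; 0, the crossover and
  1 are fixed points and contrast about the crossover never decreases.
* **Texture** (`glcm()`, `texture_features()`): the co-occurrence matrix is
  symmetrized and normalized.  The feature formulas exist in two forms
  because the typeset versions of inertia and entropy in the source
  material are non-standard (inertia with a first-power level difference
  vanishes on any symmetric matrix, and the entropy carries an (i−j)
  factor).  The `standard` form (contrast Σ(i−j)²p, mean Σi·p, entropy
  −Σp·log₂p in bits) is the default; the `printed` form evaluates the
  formulas exactly as typeset, and the test suite demonstrates on the
  checkerboard why it is not the default.
* **Fractal dimension** (`fractal_dimension_dbc()`): differential box
  counting.  For block size s (scale r = s/N) the gray axis is divided into
  boxes of height h = s·G/N with G = 256; each block contributes
  l − k + 1 boxes where k, l index the boxes of its min and max gray value;
  the dimension is the least-squares slope of log N_r versus log(1/r)
  across scales.  The scale ratio must be r = s/N (not its reciprocal) for
  the slope to be positive; a constant image yields exactly 2 at every
  scale, and fractional Brownian surfaces order correctly by Hurst
  exponent.  Non-dividing block sizes drop their trailing partial blocks
  with a message; a sliding-window variant is deliberately out of scope.
* **Pixel classifier** (`train_pixel_classifier()`): one sigmoid hidden
  layer and one sigmoid output unit, squared-error objective
  E = ½Σ(V − T)², per-sample gradient-descent updates in a seeded shuffled
  order (the per-pattern update recursion: output delta (V−T)V(1−V), hidden
  deltas backpropagated through the output weights).  Bias terms are
  realized as weights from an always-on constant unit appended to each
  layer.  The hidden width must lie between the rounded mean of the input
  and output widths and the overfitting bound N_s/(α(N_i + N_o)), α = 5 —
  the middle of the conventional 2–10 range.  Analytic gradients are tested
  against central finite differences.
* **Features and segmentation** (`pixel_features()`, `segment()`): five
  channels per pixel — normalized intensity, local mean, local standard
  deviation, local texture entropy, and a local differential-box-count
  roughness channel — over a radius-2 neighborhood by default.  Whether the
  original ANN consumed raw pixels or derived features is not stated in the
  source design; the feature-based reading is this package's choice and is
  flagged as such.  Segmentation thresholds the output unit at 0.5 and
  keeps the largest connected component (8-connectivity in 2D,
  26-connectivity in 3D, via iterative minimum-label propagation).
* **Measurement** (`measure_lesion()`): volume is voxel count × voxel
  volume (exact value stored; reports round to 0.1 cm³), and the long
  diameter is the maximum pairwise distance between boundary-pixel centers
  within the best slice, computed on the convex hull.  The center
  convention understates a shape's geometric extent by about one voxel —
  a digital 20 mm sphere measures ≈ 19.85 mm — and is used consistently in
  the tests' closed forms.

## Efficacy evaluation

`classify_response()` implements the response categories with precedence
CR, PD, PR, SD: complete remission requires all target lesions undetectable
with a confirmed ≥ 4-week duration; progression is a new lesion or a
diameter-sum increase of ≥ 20% (inclusive boundary); partial remission is a
reduction of *more than* 30% (strict boundary, following the wording this
design is based on; `dialect = "standard"` switches to the usual inclusive
≥ 30% cut); everything else is stable disease.  `efficacy_rates()` reports
ORR = 100·(CR+PR)/n and DCR = 100·(CR+PR+SD)/n to 0.1%.

`km_curve()` wraps the product-limit estimator; the median is the earliest
time at which the estimate reaches 0.5 or below (when the curve sits exactly
at 0.5 over an interval, the earliest time is reported rather than an
interval midpoint), and a curve that never crosses 0.5 yields a flagged,
undefined median.  Group comparison uses the Pearson chi-square on the 2×2
success table (`chi2_compare()`), Yates correction optional.  A published
two-arm DCR contrast of 18/20 versus 15/20 does not reach p < 0.05 under
this test; the package reports its own computed p-value and makes no attempt
to force that significance marker.  No log-rank test is provided — the
source reports only a P threshold for PFS without naming a test.

## The end-to-end pipeline

`run_pipeline()` composes everything from a single `pipeline_config()`:
simulate a training cohort (default n = 2000) with the ten independent
nuisance variables; screen, filter, discretize; learn the network
(alpha 0.05, maxk 3, BIC); simulate a 40-patient validation cohort; assign
each patient to the research arm when the posterior probability of the
favourable status is ≥ 0.5 (the original split by "predicted better
curative effect" states no rule, so the natural posterior threshold is
used); simulate per-patient diameter responses with arm-specific shrinkage
and new-lesion probabilities; classify responses and compute ORR/DCR and
the group chi-square; simulate two-arm exponential PFS (medians 4.8 and 7.1
months, censoring at 24 months) and estimate the Kaplan–Meier curves; and
run one phantom exemplar per arm and timepoint through
preprocess → segment → measure → volume change.  Every stage derives its
seed from the master seed, and re-running a config reproduces its tabular
artifacts byte for byte.

Problem sizes used by the shipped tests and the acceptance script: n = 5000
for structure recovery, n = 1000 held-out rows for prediction accuracy,
n = 2000 for the PFS median, 64×64 images for texture/fractal fixtures,
48×48 single-slice phantoms for segmentation, 8×40×40 stacks for the
pipeline's imaging exemplars.  These sizes make the whole suite run in
about a minute while leaving every stochastic check comfortably inside its
tolerance.

## Known limitations

* The synthetic truth is far stronger and cleaner than a real retrospective
  cohort; recovery results bound the machinery's correctness, not clinical
  performance.
* Enumeration inference is exponential in the number of unobserved nodes
  and intended only for the small networks this problem produces.
* The published logistic-regression table this design descends from is
  internally inconsistent for three of its four continuous rows (exp(B)
  does not equal e^B); the package reports exponentials computed from its
  own fits and checks only the one self-consistent row.
* The PFS medians of the two real treatment arms (7.1 vs 4.8 months) are
  not reproducible without patient-level data; they enter only as the
  generator's default hazards and as a parameter-recovery check.
* No DICOM ingestion, no registration between timepoints, no 3D surface
  rendering (volume arithmetic only), and no multi-class segmentation.
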