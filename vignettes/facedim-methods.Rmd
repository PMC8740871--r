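---
title: "Quantifying facial and body sexual dimorphism from 2D landmarks"
author: "facedim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying facial and body sexual dimorphism from 2D landmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facedim)
```

## The problem

How strongly do male and female faces differ within a population, once age,
body composition and face size are taken into account?  In populations with
weak facial dimorphism the honest answer is a small variance fraction — a
percent or two of total shape variance — and extracting such a small signal
reliably requires careful geometry (superimposition, sliding semilandmarks,
symmetrization) and sequential variance decomposition with permutation
inference.  `facedim` implements that pipeline for 2D frontal facial
landmarks plus standard anthropometrics, together with a synthetic-cohort
generator whose planted effects are calibrated analytically, so that every
estimator in the pipeline can be validated by parameter recovery rather
than by eye.

## Data model

A face is an ordered configuration of 71 points: 37 fixed anatomical
landmarks (9 midline — trichion, glabella, nasion, pronasale, subnasale,
labiale superius, stomion, labiale inferius, gnathion — and 14 bilateral
pairs, among them zygion, gonion, cheilion, alare and the eye landmarks)
and 34 semilandmarks covering the facial outline, the eyebrows and the
lips.  Semilandmark positions along their curves are arbitrary, so they are
optimized ("slid") during superimposition.  The bundled scheme
(`default_scheme()`, also shipped as
`inst/extdata/frontal71_scheme.yaml`) encodes the named anatomical points
with plausibly spaced curve points; it is a synthetic stand-in with the
documented structure, not a digitization template from any real study.

TPS landmark files are read with `read_tps()`: raw coordinates are
multiplied by each record's SCALE (cm per digitizer unit) and the y axis is
negated so that all downstream mathematics is y-up.  The y flip is a pure
reflection of the image convention; nothing downstream depends on
handedness because left/right structure is carried by the scheme's
bilateral pairs, not by coordinate signs.

## Superimposition

`gpa()` removes position, scale and orientation by generalized Procrustes
analysis: configurations are centred, scaled to unit centroid size, and
iteratively rotated onto the evolving consensus until the consensus moves
less than `tol` (default 1e-8, overridable).  Centroid sizes in cm are
recorded *before* scaling and are unaffected by the slide and symmetrize
options.  Two numerical choices deserve mention:

* **Canonical orientation.**  The final consensus is rotated so its major
  principal axis is vertical, with the sign fixed by the third moment of
  the vertical coordinate (faces are not up-down symmetric, so this is
  stable).  This makes GPA output strictly invariant — not merely invariant
  up to rotation — under similarity transforms of any input, which in turn
  makes the invariance testable at 1e-8.
* **Sliding schedule.**  When `slide = TRUE`, semilandmarks are slid once
  per iteration during the first `slide_rounds` (default 5) iterations,
  after which plain alignment continues to convergence.  Sliding moves each
  semilandmark only along its tangent, the unit chord between its slider
  neighbours in the current configuration, by the exact solution of the
  bending-energy least-squares problem against the consensus
  (`slide_semilandmarks()`); since the zero displacement is always
  feasible, total bending energy never increases.  A singular normal
  system (collinear tangents) falls back to a ridge-regularized solve with
  a message.

The bending energy model (`bending_energy_model()`) uses the standard 2D
thin-plate-spline kernel `r^2 log r`; affine displacement fields have
exactly zero energy, which the tests assert directly.  `tps_warp()` and
`tps_grid()` expose the same machinery for deformation-grid visualization
of mean-shape differences, conventionally with the difference exaggerated
by a factor of 3 (`exaggerate()`).

**Symmetrization.**  Head posture in 2D photographs induces spurious
asymmetric shape variation.  `symmetrize()` removes it by object symmetry:
each configuration is averaged with its reflected, relabelled,
Procrustes-refitted copy, iterated to a fixed point, then rotated so the
symmetry axis (total-least-squares line through midline points and pair
midpoints) is exactly vertical.  Output pairs are exact mirror images and
midline points sit exactly on the axis, so idempotence and zero directional
asymmetry are testable at machine precision.  The pipeline default is
GPA + slide, then symmetrize, then re-superimpose; both orders are
available since the literature does not fix one.

## Inference on shape

`permanova()` performs the sequential (type I) Euclidean variance
decomposition of the flattened aligned coordinates: each term's sum of
squares is its incremental explained SS given all earlier terms,
`R^2 = SS/SS_total`, and every pseudo-F uses the full-model residual mean
square.  p-values come from permutations of raw observation rows,
`p = (#{F* >= F} + 1)/(n_perm + 1)` (default `n_perm = 10000`; a seeded RNG
is mandatory and the caller's RNG stream is left untouched).  Term order is
scientific, not alphabetical: the standard models are age before sex for
the whole sample and BMI before sex within cohorts, so that the sex
fraction is reported net of the earlier term.  On a one-column response the
decomposition reduces exactly to classical sequential ANOVA, and the
multivariate path is cross-checked against an independent implementation in
the test suite.  An `exact = TRUE` mode enumerates all relabellings of a
two-level factor for small samples.

`repeatability()` quantifies digitization reliability from a joint
superimposition of replicate digitizations: a one-way multivariate variance
decomposition over individuals yields the among-individual and
measurement-error components via the expected mean squares of the one-way
layout, and repeatability is `among/(among + error)`, truncated to [0, 1].

`allometry_test()` regresses shape on a size measure (log centroid size by
convention, or body height), optionally after a covariate such as BMI,
within one sex at a time.

## Facial indices and body statistics

`compute_indices()` evaluates twelve classical ratios — four upper-face
width-to-height variants (bizygomatic width over nasion/glabella to
stomion/labiale-superius heights), total and lower fWHR, cheekbone
prominence, mandibular and nasal indices, mouth shape, mouth-face index and
the mean eye height-to-width ratio — from Euclidean inter-landmark
distances, so all are similarity-invariant.  Heights are Euclidean point
distances rather than axis projections (switchable reading of an ambiguous
convention; for symmetrized faces with a vertical midline the two coincide
for midline segments).  Exactly these 12 variables form the
multiple-testing family, hence the Bonferroni divisor of 12.

Body statistics follow the conventions of the originating statistics
culture: Levene's test (mean-centred) gates the pooled vs Welch two-sample
t; Hedges' g uses the pooled SD and the `1 - 3/(4 df - 1)` small-sample
correction, signed male-minus-female; ANCOVA/MANCOVA effects are type III
(drop-term) with partial eta squared `SS_effect/(SS_effect + SS_residual)`;
stepwise logistic selection is forward by Rao score test with backward Wald
checks (entry 0.05, removal 0.10, ties broken by larger statistic then
input order — fully deterministic), reporting Nagelkerke and Cox-Snell
pseudo-R², apparent accuracy at the 0.5 cutoff and optionally k-fold
cross-validated accuracy; stepwise linear selection is forward by partial
F.  Perfect separation is detected and flagged as non-convergence.  All
analyses are complete-case per variable, which is why degrees of freedom
vary across rows of a dimorphism table.

## The synthetic cohort generator

No individual-level field data are redistributable for this kind of study,
so the generator *is* the study-conditions module, not a test fixture.  Its
defaults encode the reference conditions:

* 305 subjects in three age cohorts (young 17–29: 72 m / 46 f; mid 30–50:
  70 m / 46 f; elderly >50: 43 m / 28 f — the overall 185:120 sex ratio
  applied within cohorts, matching the published cohort totals of 118, 116
  and 71).  Ages are uniform within cohorts (the true age histogram is not
  published); the elderly upper bound defaults to 90.
* Body parameters per sex and cohort are drawn from the published means and
  SDs (young and mid-adult rows); the elderly cohort reuses the mid-adult
  moments as a labelled stand-in because no reference values exist for it.
  Parameters are independent within sex (no covariance is published), with
  an optional correlation matrix for stress tests; weight is derived from
  height and BMI so the BMI identity holds exactly.
* Faces are the symmetric template plus a planted sex mean-shift, a linear
  age trajectory, an optional BMI widening of the cheek/bigonial region,
  and isotropic individual noise (default SD 0.25 cm per coordinate at
  template scale — about 2.5 mm of individual landmark variation, a
  realistic magnitude), then scaled to the subject's drawn centroid size
  and pose-jittered.  The male direction encodes the qualitative pattern of
  the reference population: relatively narrower and vertically prolonged
  face, wider nose, narrower-set and lower eyebrows, wider mouth, higher
  forehead hairline.
* Default planted variance fractions: sex 1.8% and age 6% of total shape
  variance (the whole-sample reference values); the target inter-observer
  repeatability is 0.91.

Two design choices matter for interpretation:

* **Tangent-space generation.**  All planted directions and noise live in
  the Kendall tangent space of the template (translation, rotation and
  scaling directions projected out), so the effective noise dimension is
  `2p - 4 = 138` and superimposition recovers exactly what was planted.
  Real digitization noise has components along those directions too, but
  they are annihilated by GPA anyway; generating them would only slow the
  null convergence of the estimator checks without changing any estimand.
* **Estimator-expectation calibration.**  `calibrate_effect()` solves for
  the shift magnitude in closed form.  The default targets the expectation
  of the *estimated* sequential R², which includes the `sigma^2 * dim` of
  noise that any fitted single-df term captures; the naive population
  fraction (available as `expectation = "population"`) would over-recover
  by about `1/(n - 1)` — 0.3 pp at n = 305 and 1.4 pp at n = 71, which is
  material when the planted fraction itself is 1.8–4%.  Published variance
  fractions are themselves estimates, so matching the estimator's
  expectation is the appropriate recovery target.  `generate_cohort()`
  uses the realized-design analogue (exact projections of the drawn age
  vector and sex indicator), never hand-tuned magnitudes.
* **BMI shape effect defaults to zero.**  The reference study reports that
  BMI contributes "considerably" to facial shape but prints no variance
  fraction for it, and a BMI shape effect correlated with sex would
  confound the analytically planted sex fraction in the age-then-sex
  model.  Keeping the default at zero keeps the planted decomposition
  exactly identifiable; the `bmi_effect` field exists for sensitivity
  analyses.

What passing recovery tests do and do not show: they demonstrate that the
estimators are unbiased and correctly calibrated under the stated
conditions — isotropic individual variation, linear age trajectory,
independent body parameters.  Real faces have correlated, anisotropic,
low-rank shape variation and correlated anthropometrics; recovery under
the synthetic conditions validates the estimators, not the biological
conclusions one would draw from any particular dataset.

## Validation protocol and problem sizes

The package validates itself at the reference sample sizes: 50 replicates
for the whole-sample (n = 305) and cohort-level (n = 116 and 71) variance-
fraction recoveries with 999 permutations per test, 200 replicates of the
40 x 2 repeatability design, 500 replicates of the young-adult height
effect size (71/46, the split implied by the published df of 115), and 100
replicates of the ten-candidate stepwise sex classifier on 234 young- and
mid-adults.  Recovery runs superimpose without sliding or symmetrization:
both operations project out part of the planted tangential/asymmetric
variation and would change the effective noise dimension, whereas the
planted effects are defined on the fixed homologous positions.  The full
report pipeline (`run_full()`) defaults to 10 000 permutations and
completes on a single CPU well within minutes at n = 305.

## Known limitations

* 2D frontal projections only; no 3D morphometrics, no partial least
  squares integration analyses, and no quantification of asymmetry (it is
  removed, not measured).
* The template and scheme are stand-ins with correct structure and
  realistic proportions, not population averages; index *means* computed on
  synthetic cohorts inherit the template's values by construction.
* The exact-enumeration mode of `permanova()` supports a single two-level
  factor; larger exact designs are out of scope.
* Cubic age trends are descriptive cross-sectional fits, not longitudinal
  growth models.
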