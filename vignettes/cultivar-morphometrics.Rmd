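---
title: "Methods: morphometric cultivar identification with an accuracy-weighted ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometric cultivar identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pomometrics)
```

## The identification problem and its assumptions

Cultivars of domesticated fruit are clones: within-cultivar variation is
environmental, so each fruit has exactly one correct label, and a
classifier's error rate is a meaningful, well-defined quantity. At the
same time cultivars overlap heavily in every single character, which is
what makes the problem hard and what motivates combining *linear*
morphometrics (lengths, weights, areas, colour) with *geometric*
morphometrics (landmark shape) rather than betting on either alone.

The pipeline assumes a standardized imaging protocol: fixed camera
height (so image scale is constant and TPS coordinates can stay in
pixels), a blue background that does not interact with red/green fruit
skin, six photographs per fruit — calyx end, pedicel end, and four side
views at 90° steps of which only the first two carry unique shape
information (the other two are their mirror images) — and two independent
digitisations of every image to quantify landmark placement error.

## Shape analysis

**Superimposition.** `gpa()` removes translation, scale and rotation by
partial generalized Procrustes analysis: every configuration is centered,
scaled to unit centroid size, and rotated onto the iteratively
re-estimated consensus until the consensus moves by less than `tol` in
Procrustes distance. Defaults `tol = 1e-8`, `max_iter = 100` converge in
a handful of sweeps for realistic (low-dispersion) shape samples;
wide-dispersion clouds of random shapes may legitimately need a few
hundred sweeps, and non-convergence is an error carrying the last state,
never a silent result. Reflections are excluded by default (determinant
+1) with an explicit `allow_reflection` switch, because mirror-image side
views are a real feature of the imaging protocol.

Two numerical choices deserve note:

* **Canonical frame.** A Procrustes consensus is only defined up to
  rotation. `gpa()` therefore rotates the converged solution into the
  consensus' principal axes, with a deterministic 180° flip rule, so that
  the *coordinates* (not just the shapes) of its output are reproducible
  and invariant to rigid transforms or reordering of the inputs. This
  matters for regression tests and for byte-stable downstream artifacts.
* **Tangent-space PCA.** Unit-centroid-size shapes live on a curved
  sphere; their raw covariance therefore carries a spurious radial
  eigenvalue beyond the 2k − 4 dimensions of shape space. `shape_pca()`
  projects the superimposed coordinates onto the tangent hyperplane at
  the mean direction before the eigendecomposition — the standard
  tangent-coordinate linearization — restoring the exact rank bound
  (≤ 8 components for 6 two-dimensional landmarks). Component signs
  follow a fixed convention (largest-magnitude loading positive).

**View averaging.** Each fruit's two shape-informative views enter one
joint superimposition across all fruit and views; the fruit's shape is
the landmark-wise average of its two superimposed views, re-projected to
unit centroid size, and its centroid size is the mean of the two views'
original centroid sizes. Whether the original analysis superimposed
views per fruit pair or globally, and which centroid size it recorded,
is not documented; the global choice is adopted here because it puts all
fruit in a single common frame (a prerequisite for a single PCA), and
the averaged-then-renormalized shape keeps fruit shapes on the same
footing as any other Procrustes coordinates. The two digitisation
replicates of a view are averaged in the raw image frame *before*
superimposition — both replicates digitise the same photograph, so their
coordinates are directly commensurable.

**Digitisation error.** `procrustes_anova()` decomposes Procrustes sums
of squares of repeatedly digitised configurations into among-individual
and among-replicate components after a joint superimposition, with
Goodall-style degrees of freedom (conventional factor df × (2k − 4)).
The F ratio MS(individual)/MS(error) is the summary of interest: values
far above 1 mean landmark placement noise is negligible relative to real
shape variation. The test suite checks both the closed decomposition
identity (SS terms recomputed by direct per-cell deviation sums) and the
qualitative regime (replicate noise set to 1/10 of within-cultivar
landmark noise yields F well above 10).

## Linear features

`colour_pc1()` averages each fruit's per-image RGB means and takes the
first principal component across fruit as the single colour measurement,
oriented so redder fruit score positive (a reproducible sign makes scores
comparable across runs). Averaging the six images per fruit before the
PCA is a deliberate resolution of an ambiguity — pooling all images and
then averaging scores would weight within-fruit variation into the
component; per-fruit means match how every other feature in the table is
one-row-per-fruit. A constant colour matrix leaves the component
undefined: the result is flagged degenerate with zero scores rather than
an arbitrary direction.

Outline areas use the shoelace formula on the digitised calyx and eye
polygons, rejecting self-intersecting outlines at load. Feature tables
are assembled with fixed column orders (linear: max_length, max_diameter,
weight, colour_pc1, calyx_area, eye_area; geometric: weight, colour_pc1,
calyx_area, eye_area, shape PCs, centroid_size) and the kitchen-sink
concatenation verifies that the four shared columns agree numerically
(tolerance 1e-9) before including them once.

Feature scaling is *never* baked into the tables: the classification
harness standardizes fold-wise, inside each training fold only, for
scale-sensitive learners. A dedicated canary test constructs a case
where a leaked (pooled train+test) standardization provably flips a
prediction, and asserts the harness matches the train-only computation.

## Classification harness

`stratified_split()` allocates, per cultivar, ⌊n/4⌋ fruit to test and
the rest to training (15/5 at the design's 20 fruit per cultivar), and
the same plan is reused for the linear, geometric and kitchen-sink
tables so their test accuracies are directly comparable.
`cross_validate()` runs three repeats of 10-fold cultivar-stratified
cross-validation (fold membership randomized per class so that classes
smaller than the fold count do not all skip the same fold), records
per-resample accuracy and Cohen's kappa, pools the held-out predictions
into per-cultivar CV accuracies (the quantities the ensemble consumes),
selects hyperparameters from a small fixed grid by mean CV accuracy, and
refits on the full training part. Classifier failures mark a resample
invalid; more than 20% invalid aborts the fit. Paired comparisons
(`compare_classifiers()`) use the two-sided paired t-test over resamples
and demand literally identical resample plans; zero-variance differences
are flagged degenerate rather than fed to the t distribution.

The learner roster maps the families commonly applied to morphometric
tables onto standard implementations: ridge-penalized multinomial
regression (`glmnet`) stands in for penalized discriminant analysis, a
random forest with importance-based feature selection for the
feature-selection forest, plus LDA, KNN, naive Bayes, CART (with split
controls sized for ~15-fruit classes), bagged trees, a radial SVM and a
single-hidden-layer network. The harness contract is classifier-agnostic,
so the roster is configuration, not code; `classifier_suite()` exposes
it, and suite order is the final tie-breaker in `select_best()` (after
mean CV accuracy, then mean CV kappa).

## The manual ensemble

When the linear-dataset classifier (slot a) and the geometric-dataset
classifier (slot b) disagree, each is scored by its own training-phase
cross-validation accuracy *for the class it just predicted*, and the
strictly higher score wins. This is the formalization of expert
flexibility: trust the shape specialist on cultivars it is demonstrably
good at, the size/colour specialist on its own strengths. Design points:

* **Own-class rule.** Scoring each classifier only on its own predicted
  class is the simpler of two defensible readings (the other would
  consult both predicted classes on both classifiers); it is adopted as
  the primary rule, implemented in `manual_ensemble()` as a pure
  function whose decision table is tested exhaustively.
* **Tie hierarchy.** Exact per-class ties fall back to overall CV
  accuracy, then to slot a. Ties are measure-zero for pooled CV
  accuracies but must still be deterministic.
* **No test-set leakage.** Only training-phase CV accuracies enter the
  rule.

## What the synthetic generator emulates — and what it does not

`generate_study()` reproduces the statistical structure the analysis
relies on: cultivar-specific mean shapes (Gaussian displacement of a
bilaterally symmetric six-landmark apple template), within-cultivar
landmark noise, much smaller digitisation noise layered per replicate,
size-correlated linear traits (a shared lognormal size factor driving
length, diameter and weight³), cultivar-specific red/green colour
mixes, and outline polygons whose areas track image scale. One master
seed drives deterministic per-fruit substreams, so studies are
bit-reproducible and individual fruit can be regenerated stably.

Defaults are fixed once, as the study conditions: 27 cultivars × 20
fruit; landmark noise sd 0.02 and digitisation noise sd 0.002 (both as
fractions of template centroid size — a 10:1 ratio, putting digitisation
error firmly in the negligible regime); between-cultivar shape sd 0.015,
deliberately *below* the within-cultivar landmark noise so that shape
classification is good but imperfect, which is the qualitative regime of
real cultivar data; trait-mean ranges 50–90 mm (length), 55–95 mm
(diameter), 100–250 g (weight) with 6% within-cultivar CV, spanning
typical dessert apples; red fraction 0.1–0.9. `complementary_mode`
reshapes the study so the first half of cultivars differ only in shape
and the second half only in length/diameter: the regime in which the
ensemble's advantage over either base classifier is structural, used by
the acceptance suite (20 replicate seeds, 8 cultivars × 12 fruit — sizes
chosen so the full 20-seed experiment stays a desk-scale computation).

The generator does *not* render pixels: no russeting, no texture, no
ripening series, no lighting artifacts; colour is a two-primary mix, so
its first principal component explains nearly all variance, whereas real
camera data leave more off-axis variation. Passing tests on synthetic
studies therefore validate the pipeline's statistics and plumbing, not
the biological difficulty of any real cultivar set; real-data behaviour
is exercised only through `reproduce_study_analysis()` on deposited
feature tables.

## Degenerate inputs and numerical policy

Coincident-landmark configurations, self-intersecting outlines, empty
confusion matrices, single-class kappa (chance agreement 1), undefined
one-vs-rest ratios (e.g. PPV of a never-predicted class), and constant
colour are all explicit, flagged outcomes — `NA` with a warning or a
classed error — never silently zeroed. TPS records are parsed strictly:
a record with the wrong landmark count or a non-numeric coordinate is an
error naming the record, and no record is ever dropped. Coordinates are
written at 9 decimal places, making write/read round trips exact to far
below digitisation precision and repeated exports byte-identical.

## Problem sizes in the test suite

Module tests run on handfuls of configurations and 3–8-class feature
tables; the end-to-end acceptance checks use a full 27 × 20 study for
the counting arithmetic, a 5 × 4 study for the digitisation-error
regime, and 20 replicate 8 × 12 complementary studies for the ensemble
property — sizes at which the whole suite completes in about a minute
while every property is still exercised at its natural scale.

## Known limitations

* Two-classifier arbitration only; stacking, probability averaging and
  larger ensembles are out of scope by design.
* 2-D landmarks without semilandmarks or deformation grids; no
  allometry correction beyond carrying centroid size as a feature.
* The balanced design is assumed: no class-imbalance handling.
* True penalized/robust/mixture discriminant variants are approximated
  by the ridge-multinomial and shrinkage members of the roster; the
  harness treats learners as black boxes, so richer implementations can
  be slotted in via `classifier_spec()` without touching the pipeline.
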