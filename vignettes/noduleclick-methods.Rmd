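---
title: "Click-seeded nodule segmentation and the BEED ensemble: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Click-seeded nodule segmentation and the BEED ensemble: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noduleclick)
```

This vignette documents the models, the tunable parameters, the
numerical decisions, and the limits of what the synthetic test bed can
show. It is the design record of the package; the README shows the
user-facing workflow.

## The segmentation model

A CT slice stores integers `SV`; the physically meaningful scale is
Hounsfield units, `HU = B + M·SV`, with the intercept `B` and slope `M`
taken from the image metadata (air ≈ −1000 HU, water 0 HU, soft tissue
0–100 HU). All segmentation logic runs in HU.

The click-seeded segmenter assumes a nodule is a connected region that
is *brighter* than the lung parenchyma surrounding it, and that the
clicked pixel is representative of the nodule's intensity. From the
clicked value `Start` it estimates the nodule's mean and spread with
two regressions fitted offline on marked nodules:

* `Avg = β₀ + β₁·Start` — ordinary least squares of nodule mean on
  clicked value. Shipped defaults: β₀ = −173.34 HU, β₁ = 0.71.
* `Std = c₀ + c₁·Start + c₂·Avg` — ordinary least squares on the two
  named predictors. The regression family for the spread model is a
  design choice: "multiple regression on `Start` and `Avg`" is read as
  multiple *linear* regression with no interaction or polynomial
  terms, the simplest member of that family; nothing in the estimation
  chain requires more, and the two predictors are already strongly
  collinear, which argues against enriching the design.

The threshold is `Avg − α·Std`. It is a **lower bound only**: the
rationale for subtracting from the mean is to catch the nodule's darker
tail, and a matching upper bound has no analogous justification — a
clicked nodule cannot be "too bright" relative to itself. `α`
(unitless, default 2) trades recall against precision: larger `α` lowers
the threshold and enlarges the grown region monotonically (asserted as a
property test over α ∈ {0.5, 1, 2, 3}).

Growth is 8-connected flood fill from the click over
`{HU ≥ threshold} ∩ lung`; morphology is one 3×3 erosion, noise
removal, one 3×3 dilation, in that order.

### Numerical and degenerate-case decisions

* **Negative spread predictions clamp to 0**, so the threshold never
  rises above the estimated mean. An extrapolated negative standard
  deviation is physically meaningless; clamping is the least surprising
  repair.
* **Borders are background** for all morphology: a mask touching the
  image edge erodes at the edge like any other boundary. This matches
  the set-arithmetic definition of erosion with a finite grid and keeps
  `erode(dilate(x)) ⊇ x ⊇ dilate(erode(x))` exact.
* **Noise removal** keeps the 8-connected component containing the
  click (8 rather than 4 for consistency with the growth step). If the
  single erosion has removed the clicked pixel itself, the component
  whose centroid is nearest the click is kept instead — the click
  addressed a region that still exists, and discarding everything would
  turn a one-pixel alignment artefact into a spurious null.
* **A null result is the fallback signal.** If growth or erosion
  empties the mask, the result is flagged null rather than patched,
  because the pipeline's switch to the candidate-fusion fallback is
  keyed on exactly that flag.
* The calibration is an extrapolating linear model: for clicks far
  darker than the fitted range (parenchyma at ≈ −800 HU) the estimated
  threshold tracks the click downward and typically stays *below* it,
  so a parenchyma click over-grows rather than nulls at the default α.
  This is a property of the published formula, not a defect of the
  implementation; the seed-exclusion semantics are exercised at α = 0
  in the tests, where the threshold equals the estimated mean.

## Candidate fusion and anchor accounting

When TM is null, a *provider* supplies candidate masks. The shipped
provider re-runs the TM chain at α ∈ {1, 2, 3} with the lung constraint
removed — deliberately cheap, fully deterministic, and sufficient to
exercise the fusion rule end-to-end; any external detector (e.g. a
trained instance-segmentation network) can be plugged in through the
same contract (a function from image and click to a list of masks).
Fallback masks may extend outside the lung; that asymmetry is the point
of the fallback, since juxtapleural nodules lie partly outside any lung
mask.

The fusion rule builds `U`, the union of all pairwise intersections of
distinct candidates, and keeps the candidate maximising `|candidate ∩
U|`. Overlap is raw intersection *area*, not a normalised coefficient:
normalising would let a tiny candidate with incidental overlap defeat a
large corroborated one, which inverts the rule's intent of keeping the
mask most supported by the others. Ties go to the larger candidate,
then to input order; self-intersections are excluded from `U` (with
them, `U` would be the union of all candidates and the rule would
degenerate to area-maximisation).

Anchor accounting justifies fixing the detector's search window at the
click: a full pyramid scan of a `512×512` input at strides
4/8/16/32/64 with one anchor per position evaluates
`Σ ceil(512/s)² = 21824` positions, while a 3×3 window per level costs
at most `9 × 5 = 45`, truncated at feature-map borders. The default
configuration is a reconstruction — it is the unique natural pyramid
reproducing both published counts — and one anchor per position is
forced by the same counts.

## The BEED ensemble

With `m` majority and `n ≤ m` minority rows, equalized down-sampling
shuffles the majority ids (seeded), takes `⌊m/n⌋` disjoint blocks of
size `n` and discards the remainder (logged): ragged subsets are
disallowed because every subset must match the minority size exactly.
Each block plus the full minority class trains one base classifier.

Member `i` is evaluated on the union of the other subsets,
**deduplicated by id** — the minority rows appear in every subset, and
counting them once per appearance would weight the evaluation toward
the minority class by a factor of the member count. Weights are the
min-max normalisation of these AUCs; when all AUCs are equal the
weights are all 1 (the normalisation is 0/0 and the members are
indistinguishable, so uniform weighting is the only coherent choice).
Note min-max weighting always zeroes the worst member; with many
members that is a feature (the worst of many balanced models is
redundant), with two members it reduces the ensemble to its better
half.

Prediction sums **hard votes** (each member's own positive call), not
probabilities: the combined score is `Σwᵢvᵢ/Σwᵢ` and the case is
positive when the score strictly exceeds the criterion (default 0.5; a
score of exactly 0.5 is negative). Normalising by `Σwᵢ` makes the 0.5
criterion scale-free — without it the criterion would mean different
things for different member counts. If every weight is 0 (possible
only in the two-member degenerate case) an unweighted majority vote is
used. Despite "boosting" in the name, members are trained in parallel
and never reweight each other's errors.

Base learners are thin wrappers over the standard implementations
(`MASS::lda`, `randomForest`, `nnet`, `xgboost`, `e1071::svm`), plus a
compact discrete AdaBoost over decision stumps written in-package.
Feature ranking offers χ² (on min-max-scaled features, since the
statistic requires non-negative input), one-way ANOVA F, information
gain with a **median split** (the simplest deterministic
discretisation; the ranking contract is ordering, not the absolute
gain value), and absolute Pearson correlation with the 0/1 label.
Constant features score 0 and are flagged; ties in top-k selection
break by feature name for reproducibility.

## What the synthetic test bed shows — and what it cannot

The phantom generator emulates exactly the assumptions the segmenter
relies on: tissue classes at their nominal HU levels (air −1000, body
0, lung −800, nodules configurable, all with Gaussian noise), stored
values under `B = −1024, M = 1`, and juxtapleural nodules placed
astride the lung boundary with their centroid outside the lung mask so
the lung-constrained path must fail. The feature-table generator
produces two-class Gaussian tables at the reference 160:30 imbalance
with 5 informative features of 20 and a class shift of δ = 1.2 per
informative feature — chosen once so that a single classifier trained
on the raw imbalance clearly under-serves the minority class
(specificity well below 0.8) while the classes still overlap, which is
the regime the ensemble exists for.

Not modelled: beam hardening, streaks, vasculature and airway
structure, partial-volume effects, real nodule texture, inter-reader
click variability beyond uniform jitter, and any correlation structure
among radiomics features. Passing tests therefore demonstrate the
algorithmic contracts (exact component recovery, monotonicity,
conservation, the published constants) and the *direction* of the
imbalance result, not clinical performance on hospital data.

Problem sizes in the shipped tests and acceptance script — 512×512
phantoms for the end-to-end checks, 96–128 px phantoms for unit tests,
200 random 24×24 grids for the growth oracle, 500 calibration samples
for recovery, 50 replicate tables for the imbalance comparison — were
chosen as the smallest sizes at which each property is comfortably
away from its noise floor.

## Known limitations

* Strictly 2-D: no volume assembly, no 3-D features, no DICOM series.
* The in-package DICOM reader handles single-frame uncompressed
  little-endian files only; anything else should be converted upstream.
* The radiomics set (~23 features) is a deliberate, documented subset;
  it does not aim for parity with commercial inventories, and sweeps
  over hundreds of features are out of scope.
* Lung masks are inputs. The bundled HU-threshold lung masker is for
  phantoms and demos, not clinical use.
* The shipped spread-model coefficients are fitted on the synthetic
  calibration set (seed recorded in `default_calibration()`); users
  with marked nodules should refit with `fit_calibration()`.
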