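# noduleclick

Click-seeded lung-nodule segmentation on 2-D CT slices, and
imbalance-robust classification of nodule invasiveness.

## The problem

Marking lung nodules on CT for treatment planning is expensive when done
by full manual contouring, and fully automatic detectors need training
data that is itself expensive to mark. A practical middle ground is
*semi-automated* segmentation: a radiologist clicks once inside the
nodule and the algorithm does the rest. Downstream, the clinically
important question — is the nodule invasive adenocarcinoma or not — is a
heavily imbalanced classification problem (invasive nodules typically
outnumber non-invasive ones several-fold in surgical series), and a
classifier trained naively on such data buys accuracy by ignoring the
minority class.

`noduleclick` implements both halves for users who want a reproducible,
scriptable reference implementation: image analysts working with
single-slice CT exports, and methodologists studying undersampling
ensembles.

## The methods

**Adaptive-threshold segmentation (TM).** Stored CT values are converted
to Hounsfield units, `HU = B + M·SV`. From the clicked pixel `Start`,
two offline-fitted regressions estimate the nodule's intensity profile:

    Avg = β₀ + β₁·Start            (simple linear regression)
    Std = c₀ + c₁·Start + c₂·Avg   (multiple linear regression)
    Threshold = Avg − α·Std        (α = 2 by default)

The shipped mean-model coefficients are β₀ = −173.34, β₁ = 0.71. An
8-connected region is grown from the click over
`{HU ≥ Threshold} ∩ lung`, then refined by one 3×3 erosion, removal of
components not containing the click, and one 3×3 dilation.

**Candidate fusion fallback.** When TM returns nothing (typically
juxtapleural nodules, which sit astride the lung boundary and outside
the lung mask), a pluggable provider proposes candidate masks without
the lung constraint; the retained candidate is the one with maximum
overlap against U, the union of all pairwise intersections of the
candidates. Restricting a detection window to a 3×3 neighbourhood of
the click on each of 5 pyramid levels costs 45 anchor evaluations where
a full scan of a 512×512 input at strides 4–64 costs 21824.

**BEED classifier.** With m majority and n minority training nodules,
the majority class is shuffled into ⌊m/n⌋ disjoint blocks of size n;
each block plus the whole minority class forms a balanced subset (for
the reference 160:30 data: 5 subsets of 30+30). One base classifier
(LDA, RF, NN, AdaBoost, XGBoost or SVM) is fitted per subset, weighted
by `wᵢ = (AUCᵢ − min)/(max − min)` where AUCᵢ is measured on the union
of the *other* subsets, and predictions combine hard votes as
`Σwᵢvᵢ/Σwᵢ > 0.5`. Feature ranking (χ², ANOVA F, information gain,
Pearson) precedes training.

Synthetic CT phantoms (air/body/lung/nodule tissue model) and
imbalanced Gaussian feature tables make every stage runnable and
testable with no external data.

## Worked example

```r
library(noduleclick)

ph  <- make_phantom(phantom_spec(seed = 42))   # 512x512 synthetic slice
hu  <- to_hounsfield(ph$slice)
cal <- default_calibration()
seg <- tm_segment(hu, ph$lung, ph$click, cal)
seg
#> <nodule_segmentation> TM, non-null, area 437 px, threshold -470.1 HU
mask_metrics(seg$mask, ph$truth)[, 1:4]
#> # A tibble: 1 × 4
#>    dice precision recall f_measure
#> 1 0.995         1  0.991     0.995
```

The click sat on a −300 HU phantom nodule; the calibration estimated
its mean (≈ −390 HU via the β line) and spread, set the threshold at
−470 HU, and the grown-then-opened mask recovers the ground-truth disc
at Dice 0.995 with no pixels outside the truth.

```r
tbl <- make_feature_table(table_spec(seed = 42))  # 160 invasive : 30 not
fit <- train_beed(tbl, base_kind = "RF", feature_method = "info_gain",
                  k = 10, seed = 42)
fit
#> <beed_model> 5 x RF member(s), 10 feature(s), criterion 0.5
#>   member AUCs: 0.997 0.996 0.994 0.998 0.998 | weights: 0.625 0.438 0 1 0.844

run_cross_validation(tbl, folds = 5, base_kind = "RF",
                     feature_method = "info_gain", k = 10, seed = 42)
#> <beed_cv> 5-fold, RF: accuracy 0.895, AUC 0.928, sens 0.900, spec 0.867
```

The 160:30 table yields five balanced 30+30 subsets; the five member
AUCs are min-max normalised into voting weights, and stratified
five-fold cross-validation reports a specificity (0.867) far above what
a single classifier achieves on the raw imbalance (≈ 0.4 under the same
conditions) at a small accuracy cost.

A thin command-line wrapper over the same functions ships in
`inst/cli/noduleclick` (subcommands `simulate`, `calibrate`, `segment`,
`train`, `predict`, `cv`, `evaluate`).

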