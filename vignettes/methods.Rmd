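---
title: "Methods: morphometric embryo scoring, prediction models, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometric embryo scoring, prediction models, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryoselect)
```

This vignette documents the models, the tunable parameters, the numerical
choices, and the design decisions behind `embryoselect`, in the spirit of a
statistical-methods appendix. It states no empirical result that the test
suite does not itself compute.

## 1. The morphometric (CASS) feature model

A cleavage-stage embryo is reduced to manually drawn diameters: one zygote
diameter on Day 1 and one diameter per visible object on Days 2 and 3.

**Blastomere vs fragment.** An object is a blastomere when its diameter is
at least 45 µm on Day 2, 40 µm on Day 3 (thresholds inclusive, following
the published morphometric criteria). Everything smaller is a fragment.

**Sphere model.** Volumes are computed as `V = (π/6) d³`. The imaging
literature behind computer-assisted scoring computes volumes from drawn
diameters without stating a shape model; the sphere is the only shape a
single diameter determines, so it is the package's explicit modelling
choice rather than an empirical claim.

**Features per day.**

* `TCV` — total cytoplasmic volume, the sum of blastomere volumes (µm³).
* `COD` — coefficient of diversity, largest/smallest blastomere
  *diameter*. The alternative volume-ratio definition would simply be
  `COD³` and would not change any ranking; the diameter form is used
  because size is described in diameter terms throughout the measurement
  protocol.
* `frag` — fragmentation, `(TCV₁ − TCV_d)/TCV₁`, exploiting conservation
  of cytoplasmic volume during early cleavage. Measurement noise can make
  the later TCV exceed Day 1; the value is then clamped to 0, a warning is
  raised, and the raw value is kept in `frag_*_raw` for diagnostics.
* `parity` — indicator that the Day-2 blastomere count is even.
* `n_d3_dev` — `|n₃ − 8.4|`. The 8.4 optimum comes from the published
  quadratic fit of implantation rate on Day-3 count; an embryo with 8
  blastomeres is recoded as 0.4. The constant is exposed as the
  `day3_optimum` argument (default 8.4) but is a fixed constant of the
  published model, not a tuning knob.

The visual (SSS) counterparts are the blastomere counts, a fragmentation
category (0 = none, 1 = 0–10 %, 2 = 10–20 %, 3 = 20–50 %, 4 = > 50 %;
edges implemented lower-exclusive since the printed bands overlap at the
edges) and a symmetry grade (0–2), mapped from COD via the size deficit
`1 − 1/COD` with 25 % and 50 % cut points.

## 2. Candidate predictors and screening

The CASS model-ready table has 12 predictors (TCV on Days 1–3, Day-2 count
and parity, fragmentation and COD on Days 2–3, `n_d3_dev`, both partner
ages); the SSS table has the visual grades, counts, parity and ages. The
`transport_problem` covariate is carried in profiles but never offered to
models (excluded in the source data for missingness); remaining missing
values are handled complete-case, with the dropped count reported — the
modelling pipeline assumes a fixed covariate set rather than imputation.
Infertility type is encoded 0 = primary / 1 = secondary (the encoding is
not fixed by the source material; only the 0/1 contrast matters).

`univariate_screen()` fits one logistic regression per candidate and
retains those with Wald p < 0.3. The deliberately liberal level reflects
the usual variable-selection argument that wrongly excluding a predictor
is costlier than carrying a weak one into the multivariable step. Wald
statistics are used because the screening output format (β, OR, 95 % CI,
p per feature) is Wald-shaped.

## 3. Logistic regression with stepwise elimination

`fit_logistic()` is plain maximum-likelihood IRLS: convergence when the
relative log-likelihood change falls below 1e−8 (max 100 iterations), with
step-halving if a step would decrease the likelihood. Wald SEs come from
the inverse observed information. Error conditions are explicit: a
single-class outcome, a rank-deficient design (the offending columns are
named), and separation — declared when any |β| exceeds 15 at convergence
*or* when all fitted probabilities saturate at the labels; the two
triggers are complementary because the |β| bound is scale-dependent.

`backward_eliminate()` starts from all screened main effects plus all
pairwise products and repeatedly removes the eligible term whose removal
likelihood-ratio test has the largest p ≥ 0.1 ("removal does not
significantly reduce the model's predictive outcome"). Hierarchy is
enforced: a main effect is eligible only when no retained product contains
it. Ties break by largest p then lexicographic term name, which makes the
procedure invariant to input column order. `removal_p = 1` removes
everything down to the intercept. The sequential nature of the procedure
implies that with two null terms the probability of removing both is about
`(1 − 0.1)² ≈ 0.81`, which the property tests assert (a naive per-term
expectation would overstate it).

**The published fixed equation.** The 12 printed coefficients are stored
verbatim in `inst/extdata/table7_coefficients.csv` and evaluated by
`published_score()`. Two documentation-critical conventions: the
`Number_Day3` term is the *transformed* `|n₃ − 8.4|` (the recoding was
applied before the multivariable fit and is not restated next to the
coefficients), and every printed row — whether written with `:` or `*` —
carries exactly one coefficient and is therefore treated as a plain
product term. The units that produced the TCV coefficient (−1.572) are not
stated in the source; the package applies a configurable `tcv_scale`
(default 1e−5, i.e. TCV in units of 10⁵ µm³), which puts the TCV term on
the same order as the others and yields cohort-level predicted
probabilities near the observed one-third pregnancy prevalence. The scale
is configuration, not a fitted quantity.

## 4. MARS

`mars_forward()` builds reflected hinge pairs `max(0, x−k)`/`max(0, k−x)`;
a basis function is a product of at most `max_degree` hinges (default 2,
mirroring the LR model's two-way interactions), never reusing a variable
within one product. The forward cap is `min(200, max(20, 2d)) + 1`
(`max_basis_count()`), the GCV penalty per knot is 3, and cross-validation
uses 10 outcome-stratified folds — all published settings. Remaining
choices follow standard MARS practice:

* Knot candidates are observed data values on the support of the parent
  basis, thinned by Friedman's automatic `minspan`/`endspan` runs-of-noise
  guards (α = 0.05) and capped at `max_knot_candidates` (default 128)
  evenly spaced order statistics. The guards matter: without them the
  greedy search over every observed value absorbs roughly 3σ² of RSS per
  noise basis, which neutralizes the GCV charge of 2.5 per basis.
* The candidate search is exact and vectorized: since the parent `b` is a
  column of the current basis matrix `B`, the span of `{B, b·(x−k)₊,
  b·(k−x)₊}` equals the span of `{B, b·x, b·(x−k)₊}`, so for each
  (parent, variable) all knots are scored with one projection of the
  hinge-candidate matrix onto the orthogonal complement of `[B, b·x]`.
* Stopping: basis cap reached, or best RSS improvement below
  `1e−8 · var(y)`.
* Tie-breaks: lowest variable name, then smallest knot.
* A binary outcome is fitted by least squares on the 0/1 labels (the
  squared-error MARS of the original toolbox); scores feed ranking and
  ROC analysis only, so no link function is needed. Piecewise-cubic
  smoothing is out of scope.

`mars_backward()` performs classic stepwise deletion, returning the subset
with minimal GCV over the whole deletion path; GCV charges effective
parameters `C = m + 3·(m−1)/2`, i.e. one knot per reflected pair. When the
forward model has at most 6 basis functions the deletion path is replaced
by exhaustive enumeration of all subsets (≤ 32), because a greedy path
cannot guarantee the exact optimum that the package's invariants (and its
oracle tests) demand at that size. Cross-validation estimates prediction
error only; hyperparameters are not selected on it, and the final model is
refit on all data.

## 5. Evaluation

AUC is computed as the normalized Mann–Whitney statistic via midranks
(ties count one half), which equals the trapezoidal area under the
empirical ROC curve; its variance is DeLong's structural-component
estimate. `compare_auc()` uses the paired DeLong covariance test when both
models score the same cases and an independent-variance z-test for
disjoint cohorts (training vs temporally separate validation). Grading
bands are implemented lower-inclusive everywhere (AUC 0.70 → "fair",
ICC 0.60 → "good") because the printed scales overlap at band edges; AUC
below 0.5 grades "fail". ICC is the two-way mixed, absolute-agreement,
single-measure form ICC(A,1) — the natural intra-observer design of one
rater measuring each subject twice. Kappa is unweighted. Collinearity
diagnostics are Belsley–Kuh–Welsch: unit-length scaling including the
intercept, condition indices from singular values, variance-decomposition
proportions (each coefficient's column sums to 1), VIF per predictor, and
the < 30 / 30–100 / > 100 flag bands. Mutual information uses quintile
binning for continuous features and the plug-in estimator in bits; the
estimator is a package choice, as the source figure's scale is unlabeled —
only feature rankings should be interpreted.

## 6. The synthetic cohort generator

The generator's defaults describe one fixed, plausible single-embryo
transfer world; they are stated here once and are not tuned against test
outcomes.

| Parameter | Default | Rationale |
|---|---|---|
| Day-1 diameter | N(115, 5) µm | human zygote scale |
| Day-2 / Day-3 counts | round N(4, 0.8) / N(8, 1.2), clamped | modal 4- and 8-cell stages |
| fragmentation | Beta, mean 8 % by Day 2, +5 % by Day 3, concentration 20 | mild right-skewed losses |
| asymmetry | log-normal σ = 0.25 on volume weights | Day-3 8-cell COD ≈ 1.26, matching reported CODs |
| measurement noise | 1 µm on every diameter | sub-pixel drawing error; reproduces ICC ≈ 0.95 scale agreement |
| mis-grading rate | 10 % (per graded item, ±1 level) | reported observer variability |
| maternal age | N(31, 3), truncated < 36 | study inclusion criterion |
| outcome truth | published fixed equation | prevalence ≈ 1/3, matching the printed rates |

Geometry is generated volume-first: the Day-1 sphere volume is split among
blastomeres with log-normal weights after removing the drawn fragmentation
fraction, which is shed as explicit fragment objects below the day's size
threshold (so the classification step is genuinely exercised); volumes are
converted back to diameters and jittered. Volume bookkeeping
(blastomeres + fragments = Day-1 volume up to sub-µm dust) is a tested
invariant, as is the generator–analyzer round trip (derived features
recover the latent fragmentation within noise tolerance). All randomness
flows from one master seed through per-patient counter-derived substreams,
so cohorts are byte-reproducible and order-independent across patients.

**What a green test does not establish.** The generator draws clinical
covariates independently, uses a single grading-noise mechanism, has no
time-lapse kinetics, no correlation between embryos of one patient beyond
the shared profile, and its truth is (by default) the published equation
itself. Green simulation suites therefore validate the *machinery*
(estimation, pruning, ROC, selection logic), not the clinical validity of
the published coefficients.

## 7. Acceptance experiments and their scaling

The acceptance suite re-derives the in-study arithmetic exactly (count
transforms, pregnancy rates, the 36/104 selection concordance, the
published equation term by term), checks oracle equivalences (AUC vs
brute-force pair counting, pruning vs exhaustive subset search, logistic
slope vs closed-form log odds ratio), and runs simulation suites with
fixed seeds: LR coefficient coverage within ±2 SE (run at n = 800 instead
of the nominal 5000 — coverage is sample-size invariant — to fit the test
budget), MARS knot recovery, DeLong type-I calibration, and a
MARS-vs-LR comparison under a V-shaped truth in Day-2 TCV (both low and
high volumes unfavourable — a shape a linear-logistic model cannot
represent, so hinge bases win on validation AUC).

The generalization contrast mirrors the pipeline's central qualitative
claim: with continuous CASS features and adequate samples (train 2000 /
validation 1000), the train→validation AUC gap stays within ±0.05; with
40 % mis-graded categorical SSS features and a small training cohort
(250), stepwise models fit grading noise and the validation AUC drops by
more than 0.05 in most seeds. The training-set size for the SSS arm is
deliberately small because the optimism mechanism scales with terms per
observation; this is a designed contrast, not a fitted constant.

## 8. Known limitations

* The published equation's TCV scale is a convention (`tcv_scale`); only
  score *rankings*, not absolute probabilities, should be compared across
  different scale choices.
* MARS inference is descriptive: no SEs on basis coefficients.
* The stepwise LR p-values are post-selection and should be read as
  descriptive, as in the source material.
* Fragmentation clamping discards information when measured volumes grow
  between days; the raw values are retained but not modelled.
* The selection comparison breaks ties among equally graded top embryos
  by lowest embryo id; the lab's actual tie-break is undocumented, and
  every report flags this convention.
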