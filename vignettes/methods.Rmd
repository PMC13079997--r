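---
title: "Methods: augmenting SCORE2 and modelling screening benefit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: augmenting SCORE2 and modelling screening benefit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models, the assumptions they lean on, the knobs that matter, the design
choices made where more than one reasonable implementation existed, and
what the synthetic-cohort results do and do not establish.

## The risk model and its augmentation

SCORE2 estimates 10-year risk of fatal plus non-fatal CVD for adults aged
40–69 from age, sex, smoking status, systolic blood pressure, total and
HDL cholesterol. Internally it is a sex-specific Cox-type index: the
covariates are centred and scaled with fixed transformation constants
(age at 60/5, SBP at 120/20 mmHg, total cholesterol at 6/1 mmol/L, HDL at
1.3/0.5 mmol/L), four age interactions capture the attenuation of
relative hazards with age, and the linear predictor is mapped to absolute
risk through a baseline 10-year survival `S0` and then a region
calibration pair `(s1, s2)` acting on the complementary-log-log scale.
The coefficient file shipped with the package carries the published
low-risk-region scales (appropriate for the UK); the pair is
configurable, and `(0, 1)` makes calibration the identity.

Augmentation models ask what a new covariate adds *beyond* SCORE2 rather
than re-deriving the risk score. Each is a sex-stratified Cox
proportional-hazards regression over 10-year follow-up in which the
SCORE2 linear predictor enters as an **offset** — a term with coefficient
fixed at 1 — and the added covariates (clinical biomarkers, NMR scores,
polygenic scores) are estimated. Two consequences worth noting:

* the offset pins the conventional risk factors at their SCORE2 weights,
  so the estimated coefficients are incremental log-hazards, and any
  constant shift of the offset is absorbed without changing them;
* covariates are standardized to mean 0, SD 1 *within the fitting cohort
  per sex* before fitting, so `exp(beta)` is a hazard ratio per SD — the
  fitting cohort's standardization constants travel with the model and
  are reused verbatim when predicting in a replication cohort.

Skewed analytes (CRP, GGT, AST, Lp(a), ALP) are natural-log transformed
before standardization. This is conventional for these analytes; the set
is configurable per fit (`log_transform`).

The offset is the **uncalibrated** sex-specific linear predictor, not the
calibrated risk: offsets must live on the log-hazard scale, and region
calibration is a monotone transform of risk, not of the linear predictor.

Absolute risks for augmented models extend the SCORE2 linear predictor
with the fitted augmentation term, mean-centred within the evaluation
cohort per sex, then apply the same risk transform. Centring makes the
augmentation reshuffle the risk ranking without shifting the average risk
scale, which is the behaviour wanted when the question is reclassification
rather than recalibration; no further recalibration of augmented models
is attempted.

**NMR scores.** The two metabolomic scores are trained by elastic-net Cox
regression (`alpha = 0.5`, 5-fold cross-validation, penalty at the
CV-optimum) over the 106 standardized fundamental NMR measures, in the
discovery cohort only. The training method sits behind a small interface
and is deliberately pluggable — penalized proportional hazards is a
defensible default, not a claim about the only possible choice. The
"CHD" score trains against the full CVD endpoint and the "IS" score
against the narrower endpoint subset, giving two distinct scores as in a
two-endpoint panel; with weak signal the cross-validated penalty can
legitimately shrink a score to all-zero weights, in which case downstream
code should simply omit it (a constant covariate is refused by the
fitting function).

## Evaluation

**Discrimination.** Harrell's C-index is computed sex-stratified:
comparable pairs are formed within sex only and the concordant /
discordant / predictor-tied counts are pooled across the strata (the
common stratified convention; an inverse-variance average of per-sex C
is available as an option). Pairs tied on event time are not comparable;
pairs tied on the predictor count 1/2. Ten-year administrative
truncation is applied before pair formation. The standard error is the
infinitesimal-jackknife estimator, and ΔC between two models on the
identical participant subset gets a *paired* SE from the difference of
the two models' per-participant influence values — equivalent to a
grouped jackknife and much cheaper. P-values use the normal
approximation.

**Reclassification.** Categorical NRI at the ESC 2021 thresholds
(age < 50: 2.5% and 7.5%; age ≥ 50: 5% and 10%; intervals half-open with
the upper bound exclusive for low and medium, so a risk exactly at a
cut-point takes the higher category; "under 50" means integer baseline
age ≤ 49). Case NRI is the net percentage of 10-year cases moved up;
non-case NRI the net percentage of non-cases moved down. Cases are
participants with an observed event within 10 years; participants
censored earlier without an event count as non-cases, i.e. NRI is
computed on observed case status. Closed-form multinomial standard
errors are the default; the bootstrap can override them.

**Multiplicity.** Panels of per-biomarker tests are adjusted by
Benjamini–Hochberg step-up, with flags at q < 0.05.

## Population modelling

Cohort allocation is standardized to an external screening population on
sex × 5-year age-band strata (40–44 … 65–69): each stratum contributes
`100000·share·incidence` expected cases and `100000·share·(1−incidence)`
non-cases per 100,000 screened, allocated to risk categories with the
cohort's observed `P(category | case status, stratum)` and summed. This
is the simplest standardization consistent with reweighting a cohort's
stratification to external demographics and incidence while keeping
cases and non-cases separate; it requires every stratum with positive
share to contain at least one cohort case and one non-case, and fails
loudly naming the offending cell otherwise.

Screening metrics follow from the high-risk row of the standardized
table: events prevented = `effect × CVD_high-risk` with the statin
effect defaulting to 0.20 (one event in five prevented among treated),
`NNS = 100000 / prevented`, `NNT = N_high-risk / prevented`. Three
strategies are compared: population-wide screening with each model;
targeted re-screening, in which only the SCORE2 medium-risk group is
re-assessed by the augmented model (low and high are never re-assessed);
and a size-matched comparator that instead promotes the highest-SCORE2-
risk non-high participants until the standardized high-risk count grows
by the same amount (ties broken by stable participant order; the match
is exact to within one participant's standardized weight).

The bootstrap resamples participants with replacement within sex
(preserving sex totals), recomputes categories, standardization and all
metrics per replicate, and reports percentile 95% intervals with
normal-approximation p-values from the bootstrap SE. Replicates that
produce an empty stratum cell are redrawn and counted. The default mode
freezes the fitted coefficients and resamples allocation only;
re-estimation per replicate is available through a `refit` callback.
Coefficient uncertainty is second-order for the standardized-allocation
deltas these intervals describe, and the fixed mode keeps B = 1000
routine; the mode used is recorded in the result.

## The synthetic-cohort generator

The generator produces cohorts with the statistical structure the
analysis assumes, so that every downstream stage has a recoverable
truth. Defaults were fixed once, to emulate the published baseline
characteristics of a UK screening-eligible cohort:

* 57.2% female; ages uniform within six 5-year bands with configurable
  band weights;
* sex-specific risk factors — smoking 12.2%/8.5% (M/F), SBP N(140,17)/
  N(134,19) mmHg, total cholesterol N(5.8,1.0)/N(6.0,1.1) mmol/L, HDL
  N(1.3,0.3)/N(1.6,0.4) mmol/L;
* observed 10-year event fractions 4.4% (male) and 1.9% (female),
  non-CVD death 3.2%/2.3%, loss to follow-up ~2.1%;
* fatal fractions 20.2%/15.6% of events; half of events meet the
  narrower endpoint.

Event times are exponential per sex with log-hazard = baseline + linear
predictor — the simplest model satisfying the proportional-hazards
assumption every downstream fit makes. The generating linear predictor
uses the *real* SCORE2 linear predictor (weight configurable), so offset
models see a correctly specified offset; to it are added per-SD effects
for the 11 clinical biomarkers, an NMR latent factor, and the two
polygenic scores. Competing non-CVD death is an independent exponential;
administrative censoring at 10 years and uniform loss to follow-up
complete the observation scheme. Rather than asking the user to guess
baseline hazards, the generator *solves* for them: given the configured
effects it finds, per sex, the baseline rate whose implied observed
event fraction (closed form under the competing/censoring scheme)
matches the configured target. Targets are therefore met under any
effect configuration, including the all-effects-zero null.

The 11 clinical biomarkers arise from a one-factor Gaussian model: a
shared latent (inflammation-like) factor, correlated 0.3 with the
standardized SCORE2 linear predictor, with per-biomarker loadings, so
multivariable fits show the attenuation seen when correlated biomarkers
are modelled jointly. Skewed analytes are lognormal on the raw scale;
effects act on the latent standardized scale, so per-SD log-hazards are
exactly recoverable after the conventional log transform. The NMR panel
is 106 noisy loadings on three latent factors, one of which carries CVD
signal — giving score training a target that generalizes out of sample.
Polygenic scores are independent standard normals with their own hazard
effects, reflecting that genotype-derived scores are essentially
orthogonal to mid-life circulating biomarkers.

What the generator does **not** emulate: real eligibility filtering from
health records, assay noise and batch structure, non-proportional
hazards, informative censoring, the true correlation geometry of a real
NMR platform, or ancestry structure in polygenic scores. Passing tests
on this synthetic structure show the *machinery* is correct and the
qualitative conclusions follow when signal is present and proportional
hazards holds — they do not certify effect sizes in any real population.

## Numerical choices and degenerate inputs

* Baseline-hazard solving uses `uniroot` on the log rate to 1e-12.
* Risk-category boundaries are half-open exactly as printed ("<" below,
  "≥" at and above the cut).
* Event-time ties are non-comparable pairs; predictor ties count 1/2.
* A model predicted with all-zero coefficients returns exactly the
  offset; a zero-beta augmentation returns exactly the SCORE2 risk.
* `cvd_prevented = 0` reports NNS and NNT as infinite with a flag rather
  than erroring.
* Constant covariates are refused by the Cox fit (per sex, after
  complete-case filtering); constant NMR columns are dropped with a
  warning before penalized training.
* All randomness flows from explicit integer seeds; generator and
  bootstrap restore the caller's RNG state.

## Problem sizes used by the test suite

The suite exercises parameter recovery at n = 50,000 over 50 replicates,
null calibration at n = 50,000 over 20 replicates, and the end-to-end
qualitative comparison at n = 25,000 over 3 replicates — sizes chosen so
each check has the statistical resolution it needs (a per-SD log-hazard
of 0.15 estimated to SE ≈ 0.03–0.04; null biases held below Monte-Carlo
noise) while the whole suite stays routine on a laptop. The
null-calibration check deliberately uses a large fitting cohort and
pooled discovery+replication evaluation: categorical NRI has a known
second-order artifact under null augmentations (symmetric risk jitter
moves more people up than down wherever the risk density falls across a
category boundary), and the artifact — O(β²) in the fitted null
coefficient — must sit below sampling noise for a centring assertion to
be meaningful.

## Known limitations

* Absolute risks of augmented models are offset-extensions of SCORE2; no
  re-estimation of baseline survival or regional recalibration of the
  augmented models is performed.
* NRI uses observed case status; a Kaplan–Meier-weighted variant for
  censoring robustness is a natural extension and is not implemented.
* The standardization assumes the strata table's incidence applies to a
  screening-eligible population as-is; eligibility attrition with age is
  not modelled.
* Competing risk of non-CVD death is simulated but the fits are
  cause-specific Cox models, not Fine–Gray subdistribution models.
* The elastic-net training stands in for whatever score-construction
  method a user prefers; it is a default, not a benchmarked optimum.
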