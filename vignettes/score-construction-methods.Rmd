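---
title: "Building point-based cardiovascular risk scores with J/U-shape handling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building point-based cardiovascular risk scores with J/U-shape handling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patients with type 2 diabetes face elevated risk of acute myocardial
infarction (AMI) and of sudden cardiac death (SCD) not related to an
infarction — sustained ventricular tachycardia, ventricular fibrillation, or
unexplained cardiac arrest. Clinically usable risk stratification for these
outcomes is usually delivered as a *point score*: a handful of yes/no items,
each worth one or two points, summed at the bedside. Two features of the
epidemiology complicate the classical "one threshold per risk factor"
recipe. First, glycaemic and lipid markers (long-term mean HbA1c, HDL-C,
total cholesterol) can relate to hazard non-monotonically: risk is elevated
at *both* extremes, a J- or U-shaped relationship, so a single cut-off is
the wrong shape of rule. Second, SCD episodes that occur in the immediate
aftermath of an infarction are a different clinical entity and must be
separated from "primary" arrhythmic death before any model is fitted.

`cardioscore` implements the full construction pipeline for such scores,
from raw electronic-health-record style tables to an evaluated scorecard,
together with a synthetic cohort generator with known ground truth so that
every stage can be validated by parameter recovery.

## Cohort and outcome derivation

The cohort engine consumes three delimited tables (patients, episodes,
labs) under a `study_config()` that fixes the calendar frame. Defaults
follow a decade-long EHR design: follow-up from an index date of
2009-01-01 to 2019-12-31, diabetes evidence (diagnosis code or
anti-diabetic prescription) required inside a one-year recruitment window,
age strictly above 40 at index, baseline labs averaged over the year before
index, and "window-mean" labs (mean HbA1c, mean fasting glucose) averaged
over the five years before index. All dates are day-precision, all windows
closed, and a linkage "week" is 7 days inclusive.

Decisions worth making explicit:

* **Diabetes onset** is the earliest of: first diabetes diagnosis code,
  first HbA1c strictly above 6.5%, first fasting glucose strictly above
  7 mmol/L. Strict inequalities throughout; a value exactly at a threshold
  is not evidence.
* **Anaemia** is haemoglobin strictly below 13 g/dL (men) / 12 g/dL
  (women).
* **Death is censoring.** A patient who dies without the outcome is
  right-censored at the death date. No competing-risk decomposition is
  attempted: the downstream machinery is a cause-specific Cox model, and
  the score inherits that interpretation.
* **Non-AMI SCD exclusions are patient-level.** A patient is excluded from
  the SCD analysis (not merely censored) when any SCD episode has an AMI
  within ±7 days (AMI-related arrest) or when an AMI precedes the first SCD
  at any distance. The two paths are audited separately because they are
  clinically distinct.
* **Inclusion is a partition.** Rules are applied in a fixed order (age,
  diabetes evidence, prior AMI/SCD) and each excluded patient is counted
  against the first rule it fails, so audit counts always reconcile with
  the input size.

The descriptive `event_rate_summary()` reports the annualized rate
(episodes per 100 patient-years, using the 365.25 days/year convention) and the mean annual episode frequency among patients who
experienced the event.

## Predictor selection

Selection is deliberately simple and mirrors common clinical-score
practice: univariate Cox screening keeps candidates with Wald p < 0.10;
the survivors enter one joint Cox model; covariates with p ≥ 0.05 are
dropped *once*; and the model is refitted on the remainder. No
stepwise-to-convergence iteration is performed — the procedure is two
stages by design, which keeps it auditable and cheap. Ties are handled by
Breslow's approximation (the cohorts of interest have day-resolution times
and few ties; the choice is recorded in the fit object). Missing covariates
are handled by complete-case deletion per model, with the dropped count
reported, because a bedside score cannot impute.

`fit_cox()` is a thin, validated wrapper around `survival::coxph()`; its
estimates are cross-checked in the test suite against an independent
grid-search maximizer of the Breslow log partial likelihood and against
direct maximization of the enumerated risk-set product on small fixtures.

## Decile profiling of J/U shapes

For each designated continuous exposure the profiler:

1. assigns patients to sample deciles (right-closed bins; values tied with
   a boundary fall into the lower bin; bins may be unequal under heavy
   ties);
2. contrasts each decile against the rest of the cohort in a univariate
   Cox model, and takes as **reference** the interior decile (2–9) with
   the minimal hazard ratio — the first and last deciles are never
   eligible, so an extreme tail cannot anchor the comparison; ties resolve
   to the lowest index for determinism;
3. refits one Cox model on the decile factor with that reference as
   baseline, storing HR, 95% CI and Wald p per decile.

A profile is called **J_or_U** when at least one decile on each side of the
reference is significantly *elevated* (Wald p < 0.05 and HR > 1;
significantly protective deciles do not count), **linear** when only one
side is elevated, **flat** otherwise. The per-decile tests are deliberately
unadjusted for multiplicity: the profile is a descriptive device feeding a
conservative interval rule, not a family of confirmatory hypotheses.

For a J/U-shaped exposure the scoring band is the maximal contiguous run of
deciles containing the reference whose HR does not differ significantly
from it (p ≥ 0.05). The run's outer boundary values become
`cutoff_low`/`cutoff_high`: values inside the closed band score zero,
values outside score the component's points. Contiguity is enforced — a
significant decile interrupts the run even if more distant deciles look
compatible — because the deliverable is an interval a clinician can apply.
A zero-event decile has no estimable HR and also interrupts the run: no
claim of "not different from the reference" can be made for it.

## From model to scorecard

Points follow a hazard-ratio band rule: HR within 0.67–1.5 contributes
1 point, anything outside 2 points. The band is implemented as the closed
interval [1/1.5, 1.5]: 0.67 is the conventional rounded form of 1/1.5, and
implementing the rounded constant literally would break the band's
log-scale symmetry (a factor and its exact protective reciprocal would
score differently). The printed constant 0.67 itself lies inside the band,
so every conventional worked example is unaffected.

A per-unit hazard ratio of a continuous variable (age at 1.02/year, say)
would make any band rule vacuous — the HR depends on the measurement unit.
The construction therefore dichotomizes every continuous component first:
J/U-shaped exposures by their profile band, the rest at the
Youden-optimal threshold (maximizing sensitivity + specificity against the
event label, candidate thresholds at midpoints of consecutive distinct
values, ties to the lower threshold; protective predictors are thresholded
on the reversed axis). The multivariate model is then refitted once on the
indicator matrix, and *those* indicator HRs feed the band rule. Protective
indicators (HR below 1/1.5) flip their trigger direction so that absence of
the protective factor scores the points — not exercised by typical final
models, but defined for completeness.

`risk_score()` packages the whole construction behind a formula interface
and returns an S3 object with `print`, `summary`, `coef`, `predict`,
`plot` and `residuals` methods; `apply_score()` scores new patients, with
a configurable missing-data policy (propagate `NA` by default — a bedside
score with an unmeasured item has no defined value; `score_as_zero`
optionally treats missing as untriggered).

## Evaluation

Discrimination is reported two ways. The ROC/AUC treats "event during
follow-up" as a binary label, matching how point scores are usually
presented; the AUC uses the rank formulation with tie correction and a
DeLong 95% interval (seeded bootstrap optional). The time-aware metric is
Harrell's C over comparable pairs (event–event with distinct times,
event–censored when censoring is at or after the event; score ties credit
1/2). Both are verified in the tests against exhaustive pair enumeration.
`cv_evaluate()` adds an event-stratified k-fold harness with a minimal
`fit`/`predict_risk` learner contract, so external survival learners
(random survival forests and the like, which this package deliberately does
not implement) can be benchmarked on identical folds. The precision/recall
threshold defaults to the median predicted risk — a reconstruction, stated
in the output, since no canonical threshold exists for integer scores.

## The synthetic cohort generator

The generator exists so that every downstream stage has a recoverable
truth; it emulates the *structure* of a large diabetes EHR cohort, not any
particular dataset. Covariates come from a Gaussian copula with eleven
mixed-type defaults chosen once to be clinically realistic for a
middle-aged type 2 diabetes population: age 66 ± 11.8 years, 47.6% male,
hypertension 23.1%, IHD 7.7%, heart failure 3.5%, atrial fibrillation
2.8%, baseline anaemia 14.3%, mean HbA1c 7.67 ± 1.17%, HDL-C
1.20 ± 0.34 mmol/L, total cholesterol 4.84 ± 1.03 mmol/L, and a lognormal
creatinine centred near 100 µmol/L, with a sparse plausible latent
correlation pattern. Event times follow a Weibull-baseline
proportional-hazards model,

$$ h(t \mid x) = \frac{k}{\lambda}\Big(\frac{t}{\lambda}\Big)^{k-1}
   \exp\!\Big(\beta^\top (x - c) + \gamma\,(x_u - \text{nadir})^2\Big), $$

inverted in closed form for sampling. Continuous covariates are centred at
their configured means ($c$), so the baseline describes a comorbidity-free
patient at average lab values and the default scale λ = 87 years with
shape k = 1.2 yields roughly an 8% event fraction over the 11-year horizon
— the order of first-AMI incidence in such cohorts. Death is an independent
exponential process at 0.037/year (about a third of the cohort dying over
11 years), matching the censoring-at-death convention of the cohort
engine. Default effect sizes are per-unit log hazard ratios of the
magnitude seen in published diabetes cohorts (e.g. 1.02/year for age, 1.59
for IHD, 0.802 per mmol/L HDL-C).

The quadratic term is the ground truth for shape recovery: γ > 0 bends the
log-hazard into a U with its minimum at `nadir`. The validation suite
places the nadir at the exposure's 40th percentile and uses γ = 0.6 per
unit² as its "strong shape" condition. That value is chosen on
signal-to-noise grounds: at n = 20,000 with the default baseline
(~170 events per decile) the sampling SE of a decile log-HR contrast is
about 0.09, and γ = 0.6 puts the expected contrast between the
nadir-adjacent deciles and their neighbours (≈ 0.16) clearly above that
floor — the regime in which a decile-resolution procedure is meant to
operate. Much weaker curvature is detectable as a *shape* (the extreme
deciles still rise) but cannot pin the reference decile against noise,
which is a property of decile binning, not of the implementation.

What the generator does **not** emulate: longitudinal lab trajectories
(window-mean labs are drawn directly), recurrent-episode dynamics beyond
an optional post-hoc Poisson count, informative censoring, measurement
error, and code-assignment noise. Passing recovery tests on this generator
therefore demonstrates correctness of the estimators and rules under the
stated model, not robustness to real EHR pathologies.

## Problem sizes and numerical choices

The validation suite runs at the sizes the procedures target where that is
cheap enough to be routine: single cohorts of n = 20,000 for parameter,
shape and cut-off recovery (100, 50 and 50 seeded replicates
respectively), n = 2,000 × 200 replicates for CI coverage, and exhaustive
oracles at n ≤ 100. Cox convergence uses `coxph`'s iteration limit with a
tightened tolerance (1e-9 relative log-likelihood); decile assignment uses
type-7 sample quantiles; all tie-breaks (reference decile, Youden
threshold) resolve to the lowest index/value so that every output is
deterministic given the data and seed. The pipeline writes every
intermediate to disk and is byte-reproducible given its seed.

## Known limitations

* The two-stage selection inherits the instabilities of significance-based
  selection; it is implemented because it is the procedure under study,
  not because it is recommended statistical practice.
* Point values are confined to {1, 2}; scores needing finer weighting
  should use the fitted Cox model directly.
* The shape classifier is decile-bound: nadirs in the outer deciles are
  not locatable by construction (the reference must be interior), and
  curvature below the decile noise floor is reported as linear/flat.
* Adjusted (multivariate) decile profiling is intentionally out of scope;
  both profiling passes are univariate.
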