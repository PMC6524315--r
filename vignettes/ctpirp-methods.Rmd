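---
title: "Methods: risk-group stratification and temporal validation for CKD prognosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: risk-group stratification and temporal validation for CKD prognosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctpirp)
library(dplyr)
```

## The problem

Chronic kidney disease (CKD) progresses at very different speeds in
different patients. The CT-PIRP model stratifies incident CKD patients into
seven clinical phenotypes ("nodes") using a fixed classification tree over
six routinely collected baseline variables — proteinuria, baseline eGFR,
serum phosphate, age, diabetes and sex. The model was derived on an early
enrolment wave of a regional nephrology registry; this package implements
the machinery needed to ask whether the same subgroups carry over to a
later enrolment wave as predictors of two terminal outcomes, initiation of
renal replacement therapy (RRT) and death, which compete with each other
and with loss to follow-up.

Because the registry data are not public, the package pairs every analysis
component with a synthetic cohort generator that emulates the documented
cohort structure, so that each stage — classification, survival estimation,
competing risks, calibration, matching — is testable end to end.

## The classification tree

The tree is a fixed algorithm, not re-learned here. All internal splits
send "less than or equal" to the left branch:

| Node | Definition |
|------|------------|
| 1 | proteinuric, eGFR > 33.652 |
| 2 | proteinuric, eGFR <= 33.652, phosphate <= 4.3 mg/dL |
| 3 | proteinuric, eGFR <= 33.652, phosphate > 4.3 mg/dL |
| 4 | non-proteinuric, age <= 67, non-diabetic |
| 5 | non-proteinuric, age <= 67, diabetic |
| 6 | non-proteinuric, age > 67, female |
| 7 | non-proteinuric, age > 67, male |

Proteinuria is present if any available component exceeds its threshold
(dipstick > 20 mg/dL, 24-h urine protein > 0.3 g/24 h, or microalbuminuria
> 20 mg/L); comparisons are strict and missing components are
non-informative. The eGFR and phosphate thresholds are printed to full
precision in the source model; the numeric age threshold is not printed, so
67 years is used as the default — it is consistent with the published
subgroup age distributions (the younger diabetic node averages 61 ± 6
years, the older male node 78 ± 6) — and is configurable via
`tree_config(age_split = )`. Any analysis sensitive to ages near the split
should set it explicitly.

Proteinuric patients below the eGFR split need a phosphate value; about a
fifth of registry patients lack one. Such patients are reported as
unassignable and excluded from survival analyses, mirroring the original
restriction to patients with complete data on the tree variables; they are
never silently dropped.

## Survival machinery

All follow-up clocks start at enrolment; risk sets start at 6 months
(`entry_time = 0.5`), the minimum required follow-up, implemented as
delayed entry (risk-set truncation) rather than shifting the time origin.

**Kaplan-Meier (`km_curve`)** uses the product-limit estimator with the
competing outcome censored at its occurrence time; Greenwood variance and
log(-log) confidence bands. This deliberately estimates the *net* risk; the
Aalen-Johansen cumulative incidence pipeline (`cif_curves`) is the
corrective companion wherever absolute risks in the presence of competing
events are wanted. The conservation identity — cause CIFs plus event-free
survival summing to one at every event time — is asserted exactly in the
test suite.

**Cox models (`fit_cox`)** maximise the partial likelihood with Breslow tie
handling by default (Efron by flag), matching the convention of the
software environment the original analysis was run in. Standard errors are
cluster-robust sandwich estimates, clustering patients by nephrology unit
when a cluster column is supplied, and collapsing to the ordinary
score-residual robust covariance when each subject is its own cluster. The
baseline survival function at the reference covariate pattern comes from
the Breslow cumulative-hazard estimator, exponentiated. AIC is
`-2 loglik + 2 df`; BIC uses the number of *events* as the effective sample
size, the usual convention for partial-likelihood models (the source tables
do not state their choice; this one is documented here).

**Fine-Gray models (`fit_fine_gray`)** maximise the IPCW-weighted partial
likelihood in which subjects who failed from a competing cause remain in
later risk sets, weighted by the ratio of censoring-distribution
Kaplan-Meier values `G(t)/G(s)` (the Geskus weighted-data construction).
The cause set is a parameter: loss to follow-up can be treated as a third
competing cause (the default, matching the stacked-CIF display) or folded
into censoring. Whether the original subdistribution models used
cluster-robust standard errors is not stated; cluster-robust is the default
here for consistency with the Cox models. Very small late-time weights are
left untruncated because the weighted-dataset construction bounds them away
from pathological values at observed event times.

## Temporal validation

`censor_at_horizon()` administratively censors both cohorts at 4 years to
balance follow-up length between enrolment waves.

**Discrimination** (`discrimination_summary`) reports per-node Kaplan-Meier
curves plus, for each node pair, the maximum absolute survival difference
over the horizon and a log-rank statistic. The published criterion is
visual ("well separated curves"); the numeric summaries are additions of
this package and are labelled as such in its outputs.

**Calibration** (`calibration_curves`) transfers the baseline survival:
with node indicators as the only predictors in the derivation-cohort Cox
model, the expected curve of node *j* in the validation cohort is
`S0(t)^exp(beta_j)`. Expected and observed (validation Kaplan-Meier) curves
are compared on a half-yearly grid from 0.5 to 4 years; a node is flagged
miscalibrated when the sup-norm gap exceeds 0.05. The threshold is a design
choice turning a graphical assessment into a testable rule: self-calibration
(derivation on derivation, n = 5000 synthetic patients) stays below 0.03
for every node, while halving one node's event hazard moves that node's gap
well above 0.05 (both properties are computed by the test suite and the
acceptance script, not assumed).

**Interaction models** (`interaction_model`) fit node + cohort +
node-by-cohort terms (6 + 1 + 6 coefficients for seven nodes), for both the
cause-specific Cox and the Fine-Gray model. The reference node is chosen
automatically as the node with the largest number of events of the outcome
— with event tables mirroring the derivation cohort that is the older-male
node for death and the low-phosphate proteinuric node for RRT — and can be
overridden.

**Risk ranking** (`rank_nodes`) maps hazard ratios to qualitative bands:
very low below 0.5, low in (0.5, 0.8], high in (0.8, 2], very high above 2.
The published band list names (0.8, 1.5) "high" and leaves (1.5, 2]
unnamed; it is mapped to "high" here because only a hazard ratio of 2.93 is
annotated "very high" in the source ranking — a documented inconsistency of
the source, resolved conservatively.

**Model comparison** (`compare_models`) refits the outcome on three
univariate stratifications — the seven nodes (6 df), five baseline CKD-EPI
stages with stages 1–2 merged (4 df), and five annual eGFR-progression
bands (4 df) — and reports AIC/BIC. The progression bands are not stated in
the source; the defaults `<= -5, (-5,-3], (-3,-1], (-1,1], > 1` mL/min/1.73
m^2 per year reproduce the stated degrees of freedom and are configurable.

**Matching** (`match_cohorts`) pairs validation to derivation patients 1:1
within cells of node and follow-up duration rounded to whole months
(`floor(days/30.4375 + 0.5)`). The source does not say how pairs were
chosen within oversubscribed cells; pairing in sorted patient-id order
makes the result deterministic and order-invariant. An optional caliper
admits nearest-month pairs.

## The synthetic cohort generator

`simulate_cohort()` draws node labels at the derivation-cohort prevalences
(230, 378, 152, 264, 90, 410, 741 of 2265), then covariates from normal
laws with the published per-node means and standard deviations, truncated
to the node's defining predicate region, so that the classifier round-trips
every generated label exactly. Diabetes and sex are Bernoulli at the
published prevalences where the tree leaves them free and degenerate where
it does not.

Event times are competing exponentials per node. The rates are calibrated
so the 6-year *net* risks (what the competing-event-censored Kaplan-Meier
estimates) match the published curves: RRT 71.9% for node 3, about 19% for
nodes 1, 6 and 7, and the published 32–39% band for nodes 2, 4 and 5
ordered by their reported hazard ratios; mortality 9.1% (node 4) up to
around 49% (older males). Matching net risks rather than crude event
proportions is deliberate: crude proportions confound hazard, follow-up and
competition, and cannot hold simultaneously with the published Kaplan-Meier
figures under constant hazards. The loss-to-follow-up rate is set to lose
about 10% by 6 years — the registry's loss pattern is unpublished, so this
is a labelled stand-in. Administrative censoring arises from staggered
enrolment against a fixed closing date, giving 6.5–12.75 years of potential
follow-up; the 6-month minimum follow-up is enforced by conditional
sampling, which for exponentials is a memoryless time shift.

Creatinine series are synthesised backward: a per-patient annual eGFR slope
is drawn from the node's published change distribution, visit-level eGFR
values get observation noise (sd 2 mL/min), and the CKD-EPI 2009 equation
is inverted to creatinine at the age reached at each visit. The generator
does not model nonlinear trajectories, treatment effects, or informative
loss to follow-up — so passing tests demonstrate correctness of the
estimators and pipeline under the stated laws, not robustness to those
real-data features.

An optional log-normal per-center frailty induces within-unit correlation:
with frailty the cluster-robust standard errors exceed the model-based
ones, which is the regime the sandwich estimator exists for.

For recovery of *subdistribution* parameters, `simulate_fg_cohort()` draws
directly from the proportional-subdistribution-hazards mixture
`CIF1(t; x) = 1 - (1 - p(1 - e^{-t}))^{exp(beta x)}`. Constant
cause-specific hazards cannot produce a constant subdistribution hazard
ratio, so using the exponential generator there would measure model
misspecification rather than estimator quality.

## Numerical choices and degenerate inputs

- eGFR per visit is recomputed from creatinine via CKD-EPI 2009 (the
  equation the registry used at entry is not stated; precomputed eGFR
  columns can be supplied instead).
- Follow-up time is `(exit - enrol)/365.25` years at day precision.
- Dates must be strictly increasing within a creatinine series; fewer than
  four measurements, non-positive ages or eGFRs, unknown outcome codes and
  follow-up under 6 months reject the row with a per-row diagnostic.
- Cox fitting reports possible monotone likelihood (complete separation) as
  a warning instead of silently converging; zero-event models error.
- Ties: Breslow default everywhere; the oracle tests use tie-free fixtures
  so that both tie conventions coincide.
- `rank_nodes` rejects non-positive hazard ratios; `incidence_rate_ratio`
  rejects zero events in both groups and non-positive person-time.

## Problem sizes used by the checks

The test suite and acceptance script use synthetic cohorts of 2000–5000
patients for distributional checks (Kaplan-Meier calibration, node shares,
self-calibration), 100 replicates of n = 2000 for subdistribution-parameter
recovery, and 6–8-subject fixtures for the exact oracle-equivalence checks.
These sizes keep Monte-Carlo error comfortably inside the asserted
tolerances (for example, a 5000-patient single-node cohort puts the
Kaplan-Meier standard error at 6 years near 0.007 against a +/-0.02
assertion).

## Known limitations

- The tree's age split is an assumption (67 y), configurable but not
  verifiable from the published text.
- Calibration thresholds (0.05 flag, 0.03 self-consistency) are package
  conventions for making a graphical criterion testable.
- The generator's loss-to-follow-up rate and the within-cell matching
  preference are stand-ins for unpublished registry details.
- No concordance statistic is computed: the validated object is a grouping,
  not a risk score, and the package follows the group-based validation
  criteria throughout.
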