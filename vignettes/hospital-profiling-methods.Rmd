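---
title: "Risk adjustment and hospital profiling: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Risk adjustment and hospital profiling: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Comparing outcomes between hospitals is only meaningful after correcting
for case mix: hospitals admitting older, sicker patients will show worse
crude rates regardless of the care they deliver. Administrative discharge
abstracts are cheap and universal but describe chronic comorbidity, not
acute severity. This package implements a complete, testable version of a
two-model comparison for two indicators:

* **AMI**: death within 30 days of an admission for acute myocardial
  infarction (outcome indicator);
* **HF**: surgery within 48 hours of a hip-fracture admission (process
  indicator).

For each indicator two risk-adjustment models are built — one from
discharge data alone, one adding admission-level clinical values (systolic
blood pressure for AMI; INR for hip fracture) and three-month drug
dispensing histories — and hospitals are profiled with both, to ask
whether the richer model changes either discrimination or the hospital
ranking.

Because the original regional registries are confidential, the package
ships a synthetic-registry generator with known ground truth. Every
result the test-suite asserts is computed on data whose generating
parameters are known exactly.

## Cohort construction

Index admissions are selected from discharge records inside the study
period (defaults to January–November 2010):

* AMI: principal diagnosis 410.xx, or secondary 410.xx with a principal
  diagnosis from the myocardial-infarction complication list (423.0,
  427.0–427.4, 427.6, 427.8, 427.9, 429.5, 429.6, 518.4, 780.2, 799.1,
  998.2). Re-admissions within 28 days of the episode's first admission
  are the same episode; the window anchors at the first admission, so
  admissions at days 0, 20 and 40 yield episodes at day 0 and day 40.
  Ages 18–100, residents only.
* HF: principal or secondary 820.xx, then seven ordered exclusions
  (fracture in the prior two years; age outside 65–100; non-resident;
  cancer 140–208 on the index admission or in the prior two years;
  multiple-trauma DRG 484–487; direct intensive-care admission; death
  within 48 hours without surgery). Each exclusion is logged in an
  attrition table that sums exactly to input minus output.

**Windows are half-open** `[index - w, index)`: a diagnosis or a
dispensing on the index date itself never counts as *prior* exposure —
"preceding the admission" is read strictly. Comorbidities use a 730-day
lookback over principal and secondary diagnoses of prior admissions; drug
exposure uses 90 days over ATC prefixes with optional exclusions (e.g.
other lipid-modifying agents = C10 minus C10AA). Conditions that may also
be read off the index admission's secondary diagnoses (e.g. blood
disorders) are kept as *separate* indicator columns, because acute-phase
and chronic ascertainment can act in opposite directions.

Boundary conventions, each encoded in a test: day 30 counts as death
within 30 days; surgery counts on calendar days 0 and 1; SBP exactly 100
is in the low category; INR 0.9 and 1.2 are in range; a prior admission
exactly 730 days before the index is inside the lookback. Missing
clinical values are an explicit `missing` category, never dropped;
missing *administrative* fields (age, gender, hospital) drop the episode.

The comorbidity code map is a deliberately small, fully overridable
prefix map (production lists are richer and typically proprietary);
`spec_for_generator()` derives a map that matches any custom generator
configuration exactly.

## The synthetic-data generator

`generator_config()` defaults encode the reference cohorts: 7613 AMI
patients across 62 hospitals with a 10.8% crude mortality (6348 / 83 /
19.8% for hip fracture), age 70.1 (SD 13.5) years, 35.3% female, and one
covariate row per model term with its marginal prevalence and true odds
ratio (diabetes 10.89% / OR 1.34; SBP ≤ 100 mmHg 10.05% / OR 4.60;
diuretics 20.71% / OR 1.69; INR out of range 13.47% / OR 0.56; and so
on). Outcomes are drawn from

$$\text{logit } P(Y=1) = \alpha + \sum_i \beta_i x_i +
\beta_{age}(age - \bar a) + \beta_F\,\text{female} + u_{h},$$

with $u_h$ mean-centred Gaussian hospital effects and $\alpha$ calibrated
by monotone root finding so the marginal event rate matches the target to
`1e-6`. Design choices:

* **Covariates are mutually independent** by default — only marginal
  prevalences are available. The one structured deviation is
  `hospital_prevalence_shift`, which makes a chosen covariate's
  prevalence differ between hospital strata to create a genuinely
  confounded comparison.
* **Hospital effects are Gaussian on the log-odds scale**, matching the
  random-intercept model used for the sensitivity analysis. The default
  SD of 0.2 gives roughly ±40% odds variation across hospitals, a
  moderate, realistic spread for regional mortality indicators.
* **Comorbidities leave real registry traces**: a comorbid patient gets a
  genuine prior discharge row carrying the condition's code, placed
  inside the lookback window with probability `lookback_fraction`
  (default 0.9 — most, but not all, chronic disease is visible in a
  two-year hospital history) and otherwise before it. The cohort builder
  must therefore run its real lookback logic, and flags are expected to
  equal the *recorded* (in-window) status, not the latent one.
* **Missingness is completely at random**: the data sources report
  missing percentages but no mechanism.
* **Seeding**: one master seed with per-record-type substreams, so adding
  dispensings does not perturb discharge draws; identical config and seed
  give byte-identical CSVs.

What the generator does *not* emulate: correlated comorbidity profiles,
inter-hospital transfers, longitudinal disease progression, coding error
and upcoding. Passing tests therefore demonstrate correctness of the
pipeline's logic and statistics, not robustness to real-world coding
noise.

## Risk-adjustment models

Age and gender are forced into every model. The remaining candidates are
screened by **bootstrap stepwise selection**: the cohort is resampled with
replacement, a bidirectional stepwise logistic selection (score-test
entry, Wald-test stay, both thresholds 0.05, ties broken by candidate
name for determinism) is run on each resample, and a candidate's
*selection frequency* is the fraction of usable replicates in which it
sits in the final model at p ≤ 0.05. Candidates at frequency ≥ 0.30 are
retained (an absolute-count alternative is exposed as `retain_count`;
the two readings of "at least 30 times in at least 30%" disagree at
B = 1000, and the package does not guess which was meant). Replicates with
separation or non-convergence are dropped and the denominator is the
usable count; more than half failing is an error, not a silent result.
Categorical clinical variables enter as indicator blocks (reference
levels: SBP > 100, INR in range) that are selected or dropped together.

Discrimination is the apparent (in-sample) c-statistic, computed by the
midrank Mann–Whitney method in O(n log n); tests require exact equality
with brute-force pair counting, including ties, and agreement with an
independent ROC implementation.

**A note on false retention.** A bootstrap selection frequency measures
the *stability of an association in the observed dataset*, not its truth.
If a noise covariate happens to show a chance association of about
|z| ≥ 1.44 in the realized data, its resampling selection frequency
exceeds 0.30 and it is retained; under the null this happens in roughly
15% of datasets. The package's operating-characteristics tests measure
12–16% empirically, matching this closed-form analysis. Users should
read the retained set as "stably associated in these data", not as a 5%
false-discovery guarantee.

## Hospital comparison by direct standardisation

A logistic model with **no global intercept**, one indicator per hospital
and **mean-centred** adjustment covariates estimates each hospital's
log-odds for the cohort-average case mix. Back-transformation uses

$$\text{Adj proportion}_j = \frac{e^{\text{estimate}_j}}
{1 + e^{\text{estimate}_j}} \times K, \qquad
K = \frac{\text{observed events}}{\sum_j p_j n_j},$$

where $p_j$ is the *uncorrected* back-transformed proportion. Taken
literally the published formula is circular ($p_j$ is called the adjusted
proportion); the single-pass reading is implemented, and one pass already
enforces the defining conservation identity
$\sum_j \text{adj}_j \, n_j = \text{observed events}$ (relative error
below 1e-8 in every test). K corrects the Jensen gap of the logistic
back-transform: with strong covariates the probability at the average
case mix is below the average probability, so K is typically above 1 for
the AMI model and near 1 for the weakly-discriminating HF model. With no
adjustment covariates the hospital model is saturated, every adjusted
proportion equals the observed rate, and K = 1 exactly.

Numerical edge cases: hospitals below `min_volume` (default 10) are
excluded and flagged; a hospital with zero or all events has an unbounded
indicator and is fitted with a tiny ridge (1e-4) on the hospital
indicators only, flagged `penalised`. A centred constant covariate column
is identically zero and is dropped. Adjusted proportions above 1
(possible with large K) are reported with a warning, never clipped.

**Funnel plots** place each hospital's adjusted proportion against its
volume, with control limits
$\theta \pm z\sqrt{\theta(1-\theta)/n}$ at 95% (z = 1.96) and 99.8%
(z = 3.09) around the overall rate; an exact-binomial option exists. The
precision axis is $n_j$ (an effective-sample-size axis was considered and
rejected as unstated in the source method). Limits are closed: a point
exactly on a limit is inside. Coverage under the null is verified by
simulation (1000 hospitals at rate 0.1, n = 200: 3–8% outside the 95%
limits, at most 1% outside 99.8%).

The **sensitivity analysis** refits the adjustment model with a Gaussian
random intercept per hospital (Laplace-approximate ML via `lme4`),
reporting the between-hospital SD and shrunken per-hospital estimates;
parameter-recovery tests confirm SD 0 and SD 0.5 are recovered (the
latter within 25% relative at 50 hospitals × 300 patients).
`rank_agreement()` compares two profiles by Spearman correlation of
adjusted proportions and concordance of outlier classifications.

The in-silico reproduction of the central substantive claim — a strong
covariate (OR 4) distributed identically across hospitals leaves the
two models' rankings essentially unchanged (ρ > 0.95), while making its
prevalence hospital-dependent (5% vs 40%) visibly degrades agreement and
flips outlier classifications — is part of the acceptance suite.

## Problem sizes and reproducibility

Test and script scales are chosen to keep the full suite comfortably
interactive: coefficient recovery uses 50 simulations of n = 20 000;
selection operating characteristics use 50 experiments of B = 200
bootstrap replicates at n = 5000; the acceptance script runs both default
cohorts at their reference sizes with B = 200. All randomness flows from
explicit seeds; `run_pipeline()` writes a manifest (seed, config hash,
package version) sufficient to reproduce any run, and identical
config + seed produce byte-identical CSV outputs.

## Known limitations

* The printed odds ratios and c-statistics of the original cohorts are
  not reproducible without the confidential registries; the package
  validates properties and operating characteristics instead, and its
  default synthetic experiment lands close to the published
  discrimination values by construction of the generator.
* Stepwise selection inherits its known biases (overfit ORs for
  marginally retained terms); the bootstrap wrapper quantifies stability
  but does not remove selection-induced optimism, and the c-statistic is
  apparent, not cross-validated — both deliberate, to mirror the source
  procedure.
* ICD-9-CM matching is by dot-stripped string prefix and DRG by exact
  string; no ICD-10 mapping, no probabilistic record linkage.
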