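---
title: "Methods: screening, diet scoring, the health-space score, and the evaluation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, diet scoring, the health-space score, and the evaluation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metspace)
```

`metspace` implements the computational core of a personalized-nutrition
intervention workflow for adults at risk of metabolic syndrome (MetS):
risk screening, Dutch Healthy Diet Index (DHDI) scoring, a "health space"
personal health score, an automated stage-1 dietary-advice algorithm, and
the longitudinal statistics used to evaluate a one-group
pretest–posttest design over 16 weeks. Because individual-level data from
such studies are not publicly available, the package ships a seeded
synthetic-cohort generator that reproduces the *published cohort-level*
structure (group means and SDs, visit schedule, strategy frequencies), so
every stage can be exercised and validated end to end. This vignette
documents the models, the tunable parameters, and the design choices that
were genuinely open.

## Risk screening

A participant-visit is flagged on five indicators, with the boundary
semantics of the clinical rule set applied verbatim:

* excessive waist circumference: ≥ 88 cm (women), ≥ 102 cm (men);
* elevated fasting triglycerides: ≥ 1.7 mmol/L;
* reduced HDL cholesterol: < 1.03 mmol/L (men), < 1.29 mmol/L (women);
* high blood pressure: systolic ≥ 130 or diastolic ≥ 85 mm Hg;
* elevated fasting glucose: > 5.6 mmol/L.

"At risk of MetS" means the waist criterion **plus at least one** of the
four secondary indicators; the manifest-MetS rule used to assemble the
MetS reference group means waist **plus at least two**. The latter follows
the International Diabetes Federation's central-obesity-plus-two structure
but deliberately reuses this package's single threshold table rather than
the IDF's ethnicity-specific waist cut-offs; every threshold is
configurable through `default_risk_rules()`, so either convention is
expressible. Any missing value needed by a rule raises an error: screening
requires complete panels, and silent skipping would bias eligibility.

Glucose and blood pressure are measured twice per visit and averaged
(`average_duplicates()`). HOMA-IR is computed from glucose and C-peptide
as `glucose × (c_peptide × k) / 22.5` with `k = 20` µU/mL per nmol/L as an
insulin-equivalent conversion. C-peptide-based HOMA variants are not
uniquely standardized, so both constants are explicit configuration
(`homa_config()`), and any closed form can be substituted; no package
result depends on the default.

## DHDI diet quality

Eight food categories — vegetables, fruit, oils and fats, fish, wholegrain
products, dairy, nuts, sugar-containing beverages — are each scored 1–10
for guideline adherence; the total is their sum (8–80). The canonical
input of the pipeline is the category score itself, as produced by an FFQ
instrument; `score_component()` is offered only as a documented linear
scoring convenience for synthetic intake data (1 at/below the lower
guideline bound, 10 at/above the upper bound for adequacy components;
mirrored for moderation components). Blood carotenoids (µmol/L) ride on
the diet profile as an independent fruit/vegetable biomarker; they are
never folded into a category score, because the workflow uses them only as
an advice input and a reported outcome.

## The health-space score

The personal health score projects an individual's fasting biomarker panel
(triglycerides, LDL, HDL, glucose, C-peptide) onto an axis anchored by two
reference groups: subjects with manifest MetS (class code 1) and healthy
subjects (class code 2).

**Healthy-reference selection.** From a screened pool, candidates are kept
when BMI lies in 18–25 kg/m² and no risk flag fires. Within the eligible
pool each biomarker is ranked with the healthiest extreme first (low
triglycerides/LDL/glucose/C-peptide, high HDL; ranks are position/n with
ties sharing the mean position). Each subject's five normalized ranks are
aggregated with the robust rank aggregation score

$$\rho = \min_{k} P\!\left(\mathrm{Beta}(k,\, m-k+1) \le r_{(k)}\right),$$

the minimum beta order-statistic probability over the sorted ranks — small
$\rho$ means consistently near the healthy top across all lists; $m\rho$
is a Bonferroni-conservative p-value. The `n_top` subjects with the
smallest $\rho$ (ties broken by participant id, for determinism) form the
healthy reference; the default `n_top = 10` matches the published
workflow.

**Model.** With the two groups coded 1/2, the five biomarkers are
standardized by the *pooled training* mean/SD — both stored in the model
object so that projecting new individuals is self-contained — and a linear
mixed model is fitted by maximum likelihood with sex as a random effect:
by default an uncorrelated random intercept plus random slopes on all five
features, i.e. the sex level may shift every coefficient. With only two
sex levels the variance components are weakly identified and the fit is
routinely singular; this is tolerated (the sex adjustments then shrink
toward zero) and `random = "intercept"` or `"none"` restricts the
structure. A linear rather than logistic outcome model is used because the
score is interpreted as a *continuous* position on the 1–2 axis (observed
cohort means around 1.2–1.6), not as a probability; scores are not clipped
to [1, 2]. Classification, when wanted, dichotomizes at the midpoint 1.5,
and `classification_metrics()` reports accuracy and Cohen's κ with
marginal-product chance agreement.

The published workflow reports 99% accuracy and κ = 0.94 for its model on
survey reference data; those exact figures depend on that external data
set and are not reproducible here. What the package validates instead, by
simulation from the published group moments (200 subjects per group, 100
seeded replicates), is that the fitted model separates the groups with
accuracy well above 0.85 and recovers the direction of every group
difference in ≥ 99% of replicates. Note one direction is
counter-clinical: the published healthy reference group has *higher* LDL
and total cholesterol than the MetS group, so the LDL coefficient is
legitimately positive toward healthy, and with the small standardized LDL
gap (≈ 0.4 SD) its sign is the only one that occasionally flips at this
sample size.

## Stage-1 advice

The advice algorithm makes two passes. Pass 1 checks per food category
whether intake and nutrient status are sufficient: a category is advised
when its DHDI score is below its cut-off, and fruit/vegetables are advised
when blood carotenoids (if measured) fall below a biomarker cut-off. Pass
2 maps each present metabolic abnormality to food categories whose
adequate intake it emphasizes. The plan is the union, in fixed category
order, with every entry carrying machine-checkable reason provenance
(`insufficient-diet-score`, `insufficient-biomarker`,
`metabolic-emphasis`, plus the triggering value), so re-composing a plan
from its own logged triggers reproduces it exactly.

The operational cut-offs and the abnormality→category mapping of the
original advice system are not published. The shipped defaults are
therefore explicit assumptions, held in an editable rule object
(`default_advice_rules()`), not in code: sufficiency at a category score
of 8/10; carotenoid cut-off 1.0 µmol/L (just below the cohort baseline
mean of 1.21, so an average participant is *not* biomarker-flagged);
triglycerides → fish, sugar-containing beverages, oils and fats; low HDL →
fish, nuts, oils and fats; glucose → wholegrain, sugar-containing
beverages; blood pressure → vegetables, dairy; waist → sugar-containing
beverages, oils and fats, nuts. Any result that depends on these rules is
config-dependent and should be labeled as such. Stage 2 — the dietitian
consultation — is modeled only as (possibly seeded) subset selection of
the advised categories into a behavior-change strategy.

## Evaluation statistics

Continuous outcomes are analyzed with a linear mixed model: time
(categorical weeks 0/8/16) as fixed effect, subject as random intercept,
maximum-likelihood estimation. The overall time effect is a
likelihood-ratio test against the intercept-only model (the published
analysis names no test statistic; LRT is the ML-consistent default).
Observations with an absolute residual greater than 3 × the model RMSE are
flagged as outliers and the model is refitted once without them — a single
pass, no iteration, and the boundary is strict (exactly 3 × RMSE is
kept). Pairwise timepoint contrasts use t statistics with
`n_subjects − 1` degrees of freedom (exact for the balanced paired
contrast, conservative otherwise) and are Benjamini–Hochberg-adjusted
*within outcome* — the adjustment family is not stated in the published
analysis, so the three within-outcome contrasts are the default family
and the raw p-values are always reported alongside. On balanced complete
data the week contrasts coincide with paired mean differences, which the
test suite verifies in closed form.

Likert outcomes (7-point self-perceived health items, weeks 0 and 16) use
a cumulative-logit mixed model with subject random intercept, implemented
in-package and estimated by maximum likelihood with 15-point Gauss–Hermite
quadrature over the random effect; the time effect is again an LRT.
Response levels without observations are collapsed (with a warning when
interior levels are empty). Correlations between per-subject change
scores use Pearson's test; because the published workflow accepted only
correlations that survived visual scatterplot confirmation — which cannot
be automated — significant correlations are instead screened with an
explicit leave-one-out diagnostic: a correlation whose significance
vanishes when the single most influential pair is dropped is flagged
`fragile`. Per-category analyses include only participants whose
behavior-change strategy contains the category; categories with fewer
than `min_category_n = 5` such participants are reported without
statistics, mirroring how the study withheld statistics for
sugar-containing beverages (3 participants).

`sample_size_paired()` documents the power arithmetic for a paired mean
change (e.g. δ = 1.85 cm, SD 2.67 for waist circumference); the published
calculation omits the power level and sidedness, so the utility takes both
as arguments rather than asserting a particular n.

## The synthetic generator

`generate_reference_pool()` draws subjects from per-feature truncated
normals coupled by a Gaussian copula. Only means and SDs are published, so
marginal truncated normals are the simplest faithful model; the
physiological truncation bounds are package defaults (e.g. glucose ≥ 3
mmol/L). The underlying normal parameters are *moment-calibrated* — solved
(multi-start Nelder–Mead on the closed-form truncated moments) so that the
realized truncated distribution has exactly the requested mean and SD.
Without this, heavily truncated features drift: the MetS-reference glucose
(mean 7.07, SD 3.08 against the floor of 3) would come out ≈ 0.57 mmol/L
too high. Feature correlations are not published; the default copula is
independence except for a single HDL–triglycerides correlation of −0.3
(the well-established inverse association), and the whole matrix is
overridable.

`generate_intervention_cohort()` builds week 0/8/16 visits as
`baseline + Δ(week) + subject intercept + residual`, with the subject
intercept carrying a fraction `icc` of the baseline variance so the
within-subject correlation of repeated measures equals `icc` (default 0.6
— not published, a stated assumption). Each subject draws a fixed
behavior-change strategy with the published inclusion probabilities
(vegetables 31/34, …, sugar-containing beverages 3/34; empty draws are
redrawn), and DHDI category changes apply only to subjects whose strategy
includes the category — which is also the analysis population for that
category. Total DHDI is generated directly on its own published
trajectory (+3.6 at week 8, +4.3 at week 16) rather than as the category
sum, because the published totals come from the instrument, not from
summing strategy-gated categories. Likert items are latent-normal values
rounded and clamped to 1–7.

Two honesty notes on what the generator does *not* reproduce. First,
bounded scores are clamped to their valid ranges, which attenuates mean
changes near a bound: an outcome moving from 6.2 to 8.4 (SD ≈ 3) against
a ceiling of 10 realizes roughly 0.2–0.3 less mean change than specified.
Tests of exact moment convergence therefore use specs whose bounds do not
bind; pipeline estimates on the default cohort (e.g. the total-DHDI
week-16 contrast ≈ 4.0–4.2 against the specified 4.3) inherit the
attenuation. Second, the generator matches published *marginals and mean
trajectories* only: real biomarker panels have richer covariance, the
real cohort was 100% at-risk by inclusion design (the synthetic cohort
reproduces the marginal moments, under which ≈ 80% of subjects meet the
at-risk rule), and real dropout and learning effects are not emulated
beyond complete-record dropout. Passing tests therefore validate the
*pipeline's logic and statistical calibration*, not the biology of any
real cohort.

## Problem sizes and numerical choices

The validation suite runs the generator-based checks at sizes chosen to
make Monte-Carlo noise negligible relative to each tolerance: n = 10,000
for marginal moments (3·SD/√n bands), n = 2,000–5,000 for trajectory and
correlation convergence, 100 replicates of 200-per-group fits for the
health-space recovery check, 1,000 replicates at the study size (n = 34)
for the type-I-error band [0.03, 0.07], and 400 replicates for contrast
CI coverage (band 93–97%). Reference-group selection draws a raw healthy
pool of 1,200 by default because the zero-flag filter is strict — the
published healthy group's own mean systolic pressure (138 mm Hg) implies
most draws fail the blood-pressure flag, leaving roughly 4–5% eligible.
All randomness is seeded through `withr::with_seed()`, so every generated
table, selection tie-break (rho, then participant id) and report is
bit-reproducible from its configuration.

## Known limitations

* The healthy/MetS reference selection rules reconstruct the published
  *procedure*, but the original reference data set is external; fitted
  coefficients and classification metrics here describe synthetic groups.
* The advice rule set is an assumption standing in for unpublished
  cut-offs; frequencies of advised categories depend on it.
* The sex random effect with two levels is weakly identified; per-sex
  coefficient adjustments should be read as regularized tendencies, not
  estimates with useful uncertainty.
* The ordinal model assumes proportional odds and a normal random
  intercept; with only two timepoints neither is testable.
* HOMA-IR from C-peptide uses a conversion constant that is an explicit
  assumption; absolute HOMA-IR levels are not comparable across
  conventions.
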