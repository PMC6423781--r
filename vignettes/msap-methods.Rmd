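---
title: "Methods: the multi-component sexual activity profile and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the multi-component sexual activity profile and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msap)
```

## The problem

Self-reported sexual activity under-counts sexually active adolescents:
social desirability, gender norms and reluctance to admit early sexual debut
all push survey answers toward "no". In settings where sexual activity is the
key proxy for HIV/STI and pregnancy risk, that under-count misdirects
prevention work. The multi-component sexual activity profile (MSAP) addresses
this by combining the self-report item with five indicators that each suggest
a prior (typically unprotected) sexual encounter:

* HIV serostatus (positive),
* HSV-2 serostatus (positive),
* a urine pregnancy test (positive; females only),
* a report of a prior pregnancy or of having made someone pregnant,
* a three-item STI symptom screen (genital/urethral discharge, genital sore
  or ulcer, pain on urination — the symptomatic screen used in South African
  public health care; any positive item counts).

A student is MSAP-active if they self-report activity **or** carry at least
one positive indicator. Students who answer "no" but carry a positive
indicator are the **newly identified** group — the quantity of interest.

## The classification rule

`classify_cohort()` is deterministic. Per student, the positive-indicator set
is assembled from the five fields above (the symptom composite is "yes" if
any item is yes, "no" if all three are no, missing otherwise), and the status
is:

| self-report | indicators | status |
|---|---|---|
| yes | any | `self_reported_active` |
| no | ≥ 1 positive | `newly_identified` |
| no | none | `not_active` |
| missing | none | `excluded` |
| missing | ≥ 1 positive | policy: `newly_identified` (default) or `excluded` |

Two policy switches exist because the design is genuinely open at two points.
First, a missing self-report with a positive indicator never occurred in the
motivating data (all non-responders were indicator-negative), so either
resolution is defensible; the default follows the profile's stated aim of
identifying the *maximum* number of possibly active students, and
`msap_policy(missing_self_report = "excluded")` gives the strict variant.
Second, an HIV-positive result can reflect vertical (mother-to-child)
transmission rather than sexual exposure; HIV is kept in the indicator set by
default (an unsuppressed positive student is relevant to onward risk
regardless of route), and `msap_policy(include_hiv = FALSE)` supports the
sensitivity analysis that drops it.

Missing data are handled per variable (complete case): a missing field never
contributes a positive indicator, and every prevalence denominator counts
only records with that variable observed. This matches how denominators
shrink variable-by-variable in surveys of this kind and needs only a single
missing state, with the male pregnancy test stored as missing and enforced
structurally (a male record with a positive pregnancy test is a validation
error, not data).

## Staged attribution and profile categories

Two decompositions describe the newly identified group.

**Staged attribution** (`attribute_stages()`): fix an ordering of the five
indicators and attribute each student to the *first* indicator in the order
that is positive for them. The stage counts are the incremental yield of
adding each indicator to the profile; they always sum to the newly
identified total, and the first stage always equals that indicator's
marginal. The default order — HIV, HSV-2, pregnancy test, ever pregnant, STI
symptom — is the order the profile variables are conventionally listed in;
it is one staging, not a canonical one, so the order is an argument.
Per-stage counts depend on the order, the total does not; both properties
are asserted by brute force in the test suite.

**Profile categories** (`profile_breakdown()`): the mutually exclusive
indicator combinations. Labels render deterministically — singletons as
`Only <indicator>`, larger sets joined by `*` in the fixed canonical order —
so category membership is the tested contract, not any particular label
typography.

## Cluster-summary statistics

The data structure is a school-based sample: students within 14 schools
(clusters). With so few clusters, regression-based adjustment is fragile, so
the package implements the textbook cluster-summary approach:

* **Unadjusted prevalence** — pooled numerator over pooled complete-case
  denominator across all clusters.
* **Adjusted prevalence** — the *unweighted* mean of per-cluster prevalences
  over clusters with a non-empty denominator. Unweighted is the standard
  summary for cluster-level inference with few clusters and is what a
  t-test on cluster summaries presumes; clusters with a zero denominator for
  a variable are dropped from the mean.
* **Inference** — a two-sided two-independent-sample t-test on the two
  vectors of cluster-level percents (`cluster_summary_ttest()`), pooled
  variance by default ("t-test for two independent samples" conventionally
  denotes the Student form) with Welch and paired variants by flag. The
  paired variant exists because contrasts such as male vs female are really
  measured in the same schools; the independent-samples form stays the
  default as the convention for this design. The test needs at least two
  clusters per group and refuses fewer. No multiple-testing adjustment is
  applied; batch outputs report one row per contrast so the number of tests
  is visible.

The two estimates coincide exactly when all cluster denominators are equal —
an identity the suite checks — and the t statistic is checked against the
closed-form Student/Welch formulas to 1e-12.

## The reconstructed fixture cohort

`build_inpaper_fixture()` rebuilds, from published marginal counts alone, a
2,675-student cohort on which the whole pipeline can be exercised
deterministically: 1,066 self-reported active (619 male / 447 female) with
each indicator's numerator and complete-case denominator matched per sex;
1,579 self-reported not active, of whom 223 carry exactly the published
indicator combinations (93 only-STI-symptom, 32 only-HIV, 51 only-HSV-2, 15
only-pregnancy-test, 7 only-ever-pregnant, and ten multi-indicator
combinations summing to 25) and 1,356 are negative throughout; and 30
non-responders, all indicator-negative.

Where the publication determines a joint distribution, the fixture matches
it; where it only determines margins, one valid completion is used and
documented:

* indicator overlaps in the self-reported-active stratum are unpublished, so
  positives there are assigned to distinct students (the marginal totals
  permit it) — every reproduced statistic depends only on the margins, which
  are exact;
* per-variable missing codes are placed on students clear of any positive
  assignment;
* ages follow the published age-band counts per cell (the non-responders'
  bands are fixed exactly by subtraction), with representative ages
  14/16/18/21 per band;
* risk perception matches the published group-level 4-level tables and the
  newly-identified-by-sex table jointly; the published risk-by-indicator
  joints are additionally under-determined and are *not* constrained;
* unconstrained fields are set to missing rather than invented;
* cluster labels are synthetic (round-robin over 14 schools) because real
  school compositions are unpublished — so any cluster-summary statistic on
  the fixture demonstrates the estimator but reproduces nothing, and
  `cmd_classify()` flags this in its report.

A constants table transcribing every published numerator/denominator ships
with the package, and a test recounts all of them from the fixture records.

## The synthetic generator

`generate_cohort()` draws cohorts with the latent structure the analysis
assumes, so the pipeline can be validated against a known truth:

1. school sizes — negative binomial around `cluster_size_mean` (dispersion
   0.05 by default; 0 gives equal schools);
2. sex (P(female) = 0.532) and age band (33/39/21/7% across ≤15, 16–17,
   18–19, ≥20), matching the cohort's composition;
3. latent activity — Bernoulli with sex- and band-specific probability on
   the logit scale plus a per-school N(0, 0.3²) effect; rates rise with age
   (females 0.25→0.72, males 0.32→0.80 across the bands);
4. disclosure — an active student self-reports "yes" with probability rising
   with age and lower for females (females 0.40→0.75, males 0.62→0.85),
   reflecting the observed pattern that young women under-report most; the
   self-report item is missing completely at random at rate 30/2675;
5. indicators — drawn independently given the latent state, with
   sensitivities and false-positive rates of the magnitude seen in the
   motivating survey (e.g. female HIV 0.110 | active vs 0.010 | inactive,
   the latter encoding vertical transmission; HSV-2 0.210/0.012; pregnancy
   test 0.063 among active females and structurally 0 for males; ever
   pregnant 0.45/0.004; STI symptom 0.14 with misreport floor 0.04–0.07);
6. risk perception — a 4-level draw whose distribution depends on
   (activity, disclosure), with non-disclosing actives more likely to answer
   "no risk".

These defaults were fixed once, as the study conditions the generator
emulates, and are not test-tuned. Conditional independence of indicators
given the latent state is the default joint model (none is published); an
`indicator_dependence_sd` knob adds a shared latent severity score on the
logit scale for sensitivity analyses, because the observed multi-indicator
overlap suggests positive dependence.

What the generator does *not* emulate: within-school correlation of
disclosure (only activity gets a school effect), age as a continuous
confounder (band-level only), item-level missingness patterns beyond the
self-report item, and any covariate structure linking the `cov_` columns to
activity. Passing calibration tests therefore validate the estimators under
the stated model, not the behaviour of any real survey.

## Closed forms and calibration checks

With independent indicators, the probability an active student shows at
least one positive indicator is $1-\prod_i(1-\text{sens}_i)$ (and the
analogue with false-positive rates for inactive students), so the expected
**identified gap** — MSAP% minus self-report%, both over the non-excluded
cohort — has a closed form: the sex×band-weighted mean of
$p_a(1-d)\,s_+ + (1-p_a)f_+$, divided by the expected non-excluded fraction,
where the activity probability $p_a$ is integrated over the school effect
with `stats::integrate` (the gap is linear in $p_a$, so the marginal
probability substitutes exactly). `expected_identified_gap()` and
`expected_indicator_prevalence()` refuse configurations with dependent
indicators, where the product form is wrong.

The validation suite runs three simulation studies, sized to keep the whole
suite under a minute while leaving Monte-Carlo intervals tight enough to be
informative:

* **law of large numbers** — one 100,000-student cohort (school effects off,
  so the target is the pure mixture) must land within 3 standard errors of
  the analytic stratum prevalences;
* **type-I error** — 500 replicates of a 14-school null cohort split 7 vs 7
  schools; the rejection count of the cluster-summary t-test at α = 0.05
  must fall in the central 95% binomial interval;
* **gap calibration** — 500 replicates at the default size (~2,675
  students); the closed-form gap must fall in the 99% Monte-Carlo interval
  of the empirical mean.

## Numerical and degenerate-input conventions

* Percentages are kept as doubles end to end and rounded only for display.
* Empty complete-case denominators raise an estimation error naming the
  variable and subset rather than returning NaN.
* `attribute_stages()` on zero newly identified students returns zero counts
  with undefined percentages (`NA`), not an error.
* Ties never arise: attribution is first-match over a validated permutation,
  and profile labels use one fixed member order.
* Cohort generation saves and restores the caller's RNG state, so seeded
  pipelines compose deterministically.

## Known limitations

* The MSAP is a deterministic rule; no latent-class estimate of "true"
  activity, and no regression or mixed-model adjustment (deliberately out of
  scope for a 14-cluster design).
* Adjusted (cluster-summary) percentages computed on the fixture do not
  reproduce any published adjusted figure, because real cluster compositions
  are unpublished.
* The ever-pregnant variable in the self-reported-active stratum has heavy,
  structurally unexplained missingness in the source tables; it is stored as
  published but treated as unreliable for that stratum.
* Indicator false positives (vertical transmission, symptom misreport) and
  false negatives (window periods) mean MSAP status is evidence of possible
  activity, not ground truth; the recovery experiment quantifies exactly
  this under the generator's assumptions.

## A worked run

```{r worked}
fx <- build_inpaper_fixture()
res <- classify_cohort(fx)
table(res$status)
attribute_stages(res)$counts
rec <- recovery_experiment(simulation_config(), n_reps = 30)
rec
```
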