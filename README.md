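# msap

Identifying sexually active adolescents from survey-plus-biomarker cohorts
with a **multi-component sexual activity profile (MSAP)**.

Self-reported sexual activity under-counts sexually active young people —
especially young women — because of social desirability and reluctance to
admit early sexual debut. In school-based cohorts where sexual activity is
the key proxy for HIV/STI and pregnancy risk, that under-count matters. The
MSAP combines the self-report item with five indicators of prior sexual
exposure, classifying a student as sexually active if they

```
self-report activity  OR  at least one of:
  HIV positive, HSV-2 positive, urine pregnancy test positive,
  ever pregnant / made someone pregnant, STI symptom screen positive
```

Students who self-report "no" but carry a positive indicator are the **newly
identified** group. The package is aimed at epidemiologists and trial
statisticians working with cluster (school)-sampled adolescent cohorts, and
provides the full pipeline:

* `read_cohort()` / `write_cohort()` — validated delimited cohort I/O with
  missing-code normalisation and survey-dialect remapping;
* `classify_cohort()` — the deterministic MSAP rule, with policy switches
  for missing self-report and for dropping HIV (vertical-transmission
  sensitivity analysis);
* `attribute_stages()` / `profile_breakdown()` — staged (first-match)
  attribution of the newly identified to an ordered indicator sequence, and
  the mutually exclusive indicator-combination table;
* `build_flow_diagram()` — participant-flow cells (self-report split × sex,
  complete-case indicator counts), with JSON and Graphviz DOT export;
* `prevalence()`, `cluster_summary_ttest()`, `compare_groups()`,
  `risk_crosstab()` — pooled ("unadjusted") and unweighted cluster-mean
  ("adjusted") prevalence, and two-sample t-tests on cluster-level
  summaries, the standard inference for cluster-randomised designs with few
  clusters (pooled/Welch/paired variants);
* `generate_cohort()` / `recovery_experiment()` — a seeded synthetic cohort
  generator with latent activity, partial disclosure, imperfect indicators
  and school-level effects, plus closed-form calibration targets;
* `build_inpaper_fixture()` — a deterministic 2,675-student cohort
  reconstructed from published marginal counts, on which every headline
  statistic is exactly recomputable;
* `cmd_simulate()` / `cmd_classify()` / `cmd_compare()` and a thin
  `exec/msap` script for shell use.

## Worked example

```r
library(msap)

fx  <- build_inpaper_fixture()      # 2,675 students, 14 schools
res <- classify_cohort(fx)
table(res$status)
#>             excluded     newly_identified           not_active self_reported_active
#>                   30                  223                 1356                 1066
```

Of 2,645 students who answered the self-report item, 1,066 (40.3%) reported
being sexually active; the MSAP adds 223 newly identified students, raising
the proportion to 48.7%. Staging the indicators shows where the extra
identifications come from:

```r
attribute_stages(res)$counts
#>   stage indicator       n percent
#> 1     1 HIV            45   20.2
#> 2     2 HSV2           62   27.8
#> 3     3 PREG_TEST      15    6.73
#> 4     4 EVER_PREG       8    3.59
#> 5     5 STI_SYMPTOM    93   41.7
```

HIV testing alone flags 45 of the 223 (20.2%); adding HSV-2 another 62
(27.8%); the STI symptom screen contributes the final 93 (41.7%).
Prevalence and group contrasts use the cluster-summary machinery:

```r
prevalence(fx, hiv_result == "positive", subset = self_report_active == "yes")
#> hiv_result == "positive": 61/1066 = 5.7% unadjusted; 5.7% adjusted (14 clusters)

compare_groups(fx, res, sex == "female",
               status == "newly_identified", status == "self_reported_active")
#> status == "newly_identified" (66.4%) vs status == "self_reported_active" (41.9%):
#>   t = 29.821, df = 26.00, p = 0.0000 [pooled]
```

66.4% of the newly identified are female against 41.9% of self-reporters —
the under-reporting is concentrated in young women. (The fixture's cluster
labels are synthetic round-robin assignments, so adjusted/cluster-level
figures on it demonstrate the estimators rather than reproduce any published
value; classification reports flag this.) The synthetic generator validates
the pipeline against a known truth:

```r
recovery_experiment(simulation_config(), n_reps = 30)
#> Recovery experiment over 30 replicates
#>   MSAP sensitivity among non-disclosing active: 0.581 [0.569, 0.593]
#>   false identification rate among inactive:    0.072 [0.069, 0.075]
#>   identified gap (%): 13.22 [12.89, 13.55]; closed form 13.26
```

Under the default calibration, the profile recovers 58% of active students
who did not disclose, at a 7% false-identification rate among the truly
inactive, and the simulated self-report-to-MSAP gap matches its analytic
expectation.

See `vignettes/msap-methods.Rmd` for the model, the fixture-construction and
generator-calibration choices, and known limitations.

## Command line

```sh
msap fixture  --out-dir data/
msap simulate --out-dir sim/ --seed 3 [--config cfg.yaml]
msap classify --cohort data/fixture.csv --out-dir out/ \
              [--policy-missing-selfreport excluded] [--no-hiv-indicator]
msap compare  --cohort sim/cohort.csv --results out/results.csv \
              --contrasts contrasts.yaml --out-dir out/ [--ttest welch]
```
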