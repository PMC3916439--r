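# msrelapse

Claims-based relapse and persistence outcomes in multiple sclerosis (MS)
therapy-switch cohorts.

## The problem

Patients with relapsing-remitting MS who do not respond to, or cannot
tolerate, interferon (IFN) therapy switch to another disease-modifying
therapy (DMT), and payers and clinicians want to know whether switching to
oral fingolimod or to injectable glatiramer acetate (GA) controls relapses
better in routine care. Administrative claims databases can answer this at
scale, but they record no relapses, no randomization and no protocolized
follow-up. Everything must be *operationalized*: a relapse becomes "an
inpatient stay with primary ICD-9 diagnosis 340, or an outpatient 340
visit with an oral/IV corticosteroid claim within 7 days, absent a primary
exclusionary diagnosis, with events inside a 30-day window collapsed to
one episode"; staying on therapy becomes a days-supply runout plus 60-day
gap rule; confounding by indication is handled by 1:1 nearest-neighbor
propensity matching (caliper 0.01) inside pre-index relapse-count strata.

`msrelapse` implements that full pipeline as a tested, reusable R package
for analysts who run matched-cohort relapse studies on claims data:
readers and validators for the three claim tables, the relapse detector,
the persistence engine, cohort selection with a conserving attrition
table, the propensity matcher with balance diagnostics, and the outcome
models. Because real claims databases are licensed, the package also
ships a seeded synthetic claims generator with known ground truth, so
every stage - and the whole pipeline - is verifiable end to end.

## The estimators

For matched members persistent for `t_i` years (360-day years) with
relapse indicator `y_i` and episode count `k_i`, the package fits, with
the matched pair as GEE cluster (exchangeable working correlation, robust
variance):

* relapse probability: logistic GEE
  `logit P(y_i = 1) = b0 + b1 * fingolimod_i + log(t_i)`,
  reporting the odds ratio `exp(b1)`;
* relapse rate: negative-binomial GEE
  `log E[k_i] = c0 + c1 * fingolimod_i + log(t_i)` with dispersion
  profiled by maximum likelihood and held fixed, reporting the rate ratio
  `exp(c1)` and model-based annualized relapse rates (ARRs) per arm;
* crude ARRs (episodes per person-year), Kaplan-Meier time to first
  relapse with the log-rank test, baseline tables (chi-square / Wilcoxon),
  and a sensitivity re-adjustment for baseline symptoms not used in the
  matching.

## Worked example

```r
library(msrelapse)

cfg <- study_config(sim = sim_config(n_members = 952, seed = 1))
report <- run_study(cfg)
report
```

```
Matched-cohort relapse study report
  cohort: 942 members; 356 matched pairs ( 712 members )
  attrition: 1.1% of identified members excluded
  persistence fingolimod: 74.4% at horizon, 310+-98 days
  persistence GA: 65.4% at horizon, 286+-114 days
  relapse while persistent: fingolimod 13.5%, GA 30.1% (p = 0.0000)
  ARR pre: fingolimod 0.35, GA 0.35; post (model): 0.18 / 0.47
  OR 0.32 (95% CI 0.22-0.47); p = 0.0000
  RR 0.37 (95% CI 0.27-0.51); p = 0.0000
  log-rank chi-square 35.13, p = 3.08e-09
```

Reading this: 952 simulated IFN switchers enter, members failing the
selection criteria drop out in the attrition table, and matching leaves
356 fingolimod/GA pairs. Pre-index annualized relapse rates are balanced
(the matching worked); post-index, the fingolimod arm relapses at roughly
a third of the GA arm's rate - the generator's built-in rate ratio is
0.38, and the estimate recovers it up to sampling noise and the claims
noise the generator deliberately includes (see the methods vignette).
`write_report()`
writes the attrition, baseline, balance, persistence, pairs and
Kaplan-Meier tables plus `summary.json`; each stage (`find_index_switch()`,
`detect_relapse_episodes()`, `compute_persistence()`,
`match_nearest_neighbor()`, `fit_relapse_rate()`, ...) is exported and
documented for standalone use, and `inst/scripts/msrelapse` wraps
simulation and full runs for the shell.

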