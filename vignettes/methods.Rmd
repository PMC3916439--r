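---
title: "Methods: claims-based relapse outcomes in MS therapy-switch cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based relapse outcomes in MS therapy-switch cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The study design this package implements

`msrelapse` implements the complete analytic pipeline of a matched-cohort
claims study of relapse outcomes in multiple sclerosis (MS) patients who
switch from interferon (IFN) therapy to either fingolimod or glatiramer
acetate (GA). Administrative claims carry no direct marker of an MS
relapse, no randomization, and no protocolized follow-up, so the analysis
is a chain of operational definitions, each of which this package makes
explicit, configurable, and testable:

1. **Index switch**: the first fingolimod or GA initiation (pharmacy fill
   or clinic-administration procedure claim) inside a calendar index window
   (default October 1, 2010 - March 31, 2012) whose nearest preceding IFN
   claim is at most 90 days earlier. The gap is measured claim date to
   claim date, because the rule is stated in terms of *a claim for IFN*,
   not of exposure runout. Day 0 of all windows is the index date; the
   pre-index window is days [-360, -1] and the post-index window
   [0, +359], so the index date is owned by the post period.
2. **Selection**: continuous enrollment covering both windows (zero gap
   days tolerated; administrative spans that abut by one day are merged at
   load time), at least one MS-diagnosis claim (ICD-9 prefix 340) within
   360 days of index, age 18+ at index (index year minus birth year, the
   granularity claims extracts provide), no index-DMT claim in the
   pre-index period, no index-therapy fill with missing or zero days
   supply, and no data-quality flags. Every criterion contributes one row
   to an attrition table whose counts are conserved by construction.
3. **Relapse detection**: an inpatient claim whose *primary* diagnosis is
   MS, or an outpatient MS-diagnosis visit with an oral or intravenous
   corticosteroid claim within 7 days, excluded when any same-day claim
   carries a primary exclusionary diagnosis (asthma, gout, rheumatoid
   arthritis, uveitis - the shipped set is editable because the source
   lists disease names, not codes, and marks the list non-exhaustive).
   Events within the same 30-day period collapse to one episode.
4. **Persistence**: days supply accumulates into an exposure timeline;
   discontinuation is a gap of at least 60 days after the expected-next-
   dispense date, a claim for a different disease-modifying therapy (IFN,
   GA, fingolimod, natalizumab) ends persistence the day before the claim,
   and follow-up is censored at 360 days.
5. **Matching**: a logistic propensity model for fingolimod use, then 1:1
   nearest-neighbor matching without replacement inside pre-index
   relapse-count strata (0/1/2/3+) with a caliper of 0.01 on the
   probability scale.
6. **Outcomes**: relapse probability while persistent (logistic GEE with a
   log-years offset), annualized relapse rate (negative-binomial GEE with
   the same offset), crude ARRs, Kaplan-Meier time to first relapse with
   the log-rank test, a baseline table with chi-square / Wilcoxon
   comparisons, and a sensitivity re-adjustment for baseline symptoms not
   used in matching.

## Conventions that needed a decision

Several rules in this lineage of claims algorithms are stated in words that
admit more than one arithmetic reading. The package fixes one reading each,
states it here, and exposes a switch where the alternative is defensible.

* **Day arithmetic.** A day count between two dates is the plain
  difference in whole days; "within k days" means difference <= k. All
  windows are inclusive integer day intervals relative to index.
* **Steroid window direction.** "Corticosteroid use within 7 days of the
  outpatient visit" is read as the 7 days *following* the visit
  (treatment follows assessment); `direction = "symmetric"` gives the
  +/- 7 reading.
* **30-day collapsing.** "The same 30-day period" is anchored at the
  episode's first event: every event within 30 days of the anchor joins
  the episode, and the next unassigned event opens a new one. A rolling
  (chained) mode is available, but the anchored reading is the default
  because chains can merge unboundedly long spans. When an episode
  contains both kinds of event, inpatient dominates the episode kind; the
  both-kind flags are kept so inpatient/outpatient tallies whose
  percentages exceed 100% remain reproducible.
* **Discontinuation gap.** "A gap of at least 60 days" discontinues when
  (next fill - runout) >= 60, or when no fill follows and at least 60
  uncovered days fit before the 360-day horizon. The persistence end is
  the runout day itself, not the end of the gap: relapse counting "while
  persistent" should not credit unexposed days. `days_persistent` is the
  number of covered days from index; the end day is
  `days_persistent - 1`; a gap shorter than 60 days does not end
  persistence.
* **Stockpiling.** Early refills queue after current coverage
  (`stockpile = FALSE` truncates overlaps). Clinic administrations carry
  no days supply and are credited a fixed coverage (default 28 days).
  Persistence never re-opens after its first qualifying end.
* **Caliper.** 0.01 on the fitted-probability scale. The source marks its
  own value "e.g."; 0.01 is the default here and is logged in every run's
  provenance block.
* **MS-diagnosis window.** The "within 360 days of index" criterion uses
  [-360, +359], consistent with the post window owning the index day;
  both bounds are configurable.
* **Randomness in matching.** "Randomly matched" is realized as a seeded
  random processing order of treated members with greedy nearest-neighbor
  selection; ties between equidistant controls go to the lowest member id
  so a (seed, data) pair fully determines the pairing.

## The synthetic claims generator

Licensed claims databases cannot ship with a package, so every stage is
exercised against a generator (`generate_bundle()`) whose defaults encode
the study conditions: 360-day pre/post windows inside one enrollment span
(1080 days), an IFN fill history ending 7-60 days before the index claim,
uniformly drawn index dates in the calendar window, a pre-index relapse
intensity of 0.47 per 360 days, post-index GA intensity 0.51 with a true
fingolimod/GA rate ratio of 0.38, and arm-specific exponential
discontinuation hazards chosen so that 360-day persistence is 73.5%
(fingolimod) and 62.9% (GA).

Relapses follow a per-member homogeneous Poisson process multiplied by a
gamma frailty (shape 1.5, mean 1). The frailty is shared by the pre- and
post-index periods, which makes pre-index relapse counts a genuine
confounder proxy and makes post-index counts overdispersed - exactly the
situation the negative-binomial outcome model assumes. Treatment
assignment is logistic in the pre-index relapse count, fatigue,
depression, diabetes and age, scaled by `confounding_strength` (0 =
randomized), so the matcher demonstrably changes estimates. Each relapse
manifests as an inpatient stay (probability 0.1) or an outpatient visit
whose corticosteroid claim appears 0-7 days later with probability 0.95;
baseline symptom and comorbidity flags (prevalences from the matched
cohort's baseline table) are emitted as pre-index claims so that covariate
construction runs off claims alone. Noise channels - routine MS visits
without steroids, non-MS visits, stray steroid fills - are configurable.

Randomness is organized as one master seed from which per-member
substreams are derived, so adding members never perturbs existing
members' draws; identical (config, seed) pairs give byte-identical
bundles.

**What the generator does not emulate**: real NDC/procedure coding
variety (the shipped drug-code dictionaries are synthetic but structurally
valid, since the real lists are licensed supplements), pricing realism,
geographic structure, seasonality, multi-switch treatment trajectories, or
coding error beyond the explicit noise channels. Passing tests show the
pipeline implements its stated rules and recovers known effects under the
assumed data-generating process - not that the claims algorithm itself is
clinically valid; that evidence belongs to the validation literature the
algorithm comes from.

## Statistical models

Both outcome models are fitted by generalized estimating equations with
the matched pair as cluster, an exchangeable working correlation, and
robust (sandwich) variance - the matched pair is the only disclosed
clustering. No GEE implementation ships with this package's dependency
set, so `gee_fit()` implements the standard iterative scheme (moment
estimates of scale and exchangeable correlation between Fisher-scoring
updates, closed-form exchangeable inverse). Two oracle properties pin it
down in the tests: with singleton clusters it must reproduce `glm()`
maximum likelihood to four decimals, and with an independence working
correlation its sandwich must equal the clustered HC0 covariance from the
`sandwich` package.

The relapse-probability model is logistic with log years-on-therapy
entered as an *offset in the linear predictor*, exactly as the design
specifies. Offsets in logit models are unusual (the coefficient no longer
has a pure rate interpretation), so the no-offset companion fit is
attached to every estimate for transparency. The relapse-rate model is
negative binomial: the dispersion is estimated by maximum likelihood on
the pooled data (`MASS::glm.nb`) and then held fixed inside the GEE fit;
when the pooled fit degenerates toward Poisson (theta above 1e5 or a
failed fit) the Poisson family is used. Model-based ARRs are the average
predicted rates at one year of exposure; crude ARRs divide episode totals
by person-time in 360-day years, matching the study's 360-day windows (the
pre-index crude ARR then equals the mean per-member count). Members with
zero persistent days are excluded from offset models (log 0 is undefined)
with a logged count. Time to first relapse is censored at discontinuation
or 360 days; treating discontinuation as a censoring event rather than a
competing risk mirrors the source design and carries the usual caveat of
informative censoring.

Baseline-table chi-square tests are Pearson tests without continuity
correction - that convention, not Yates correction, reproduces the
published p-value (0.0120) from the printed relapse counts.

## Numerical and degenerate-input choices

* GEE Fisher scoring converges on a max coefficient step below 1e-9
  (50 iterations cap); means are clamped away from the variance-function
  boundary so quasi-separated refits surface as huge robust standard
  errors, never as NaN estimating equations.
* The propensity model drops constant covariates with a warning; fitted
  probabilities numerically at 0/1 trigger a ridge-penalized refit
  (lambda 1e-3, intercept unpenalized) so scores stay inside (0, 1).
  Stepwise mode is forward selection with likelihood-ratio entry p < 0.15
  and removal p > 0.15 - the source names stepwise selection but no
  thresholds, so the fixed final variable list is the primary mode.
* Zero relapse events in an arm makes the odds ratio non-identifiable:
  the estimate is returned as NA with a warning, never silently.
* An all-zero count vector is an error naming the degeneracy.
* An empty cohort or an empty pairing yields a degenerate report with
  zero-row tables and NA estimates, so batch runs always produce files.
* Collapsing ties (two events on one day) stay in one episode; multiple
  same-day MS visits emit one pre-collapse event per claim, which is
  immaterial after collapsing.

## Simulation evidence the test suite computes

The acceptance tests (`tests/testthat/test-acceptance.R`) regenerate all
of the following from scratch:

* worked examples from the published tables (matched-cohort proportions,
  attrition percentage, matched sample size, relative reductions implied
  by the printed odds and rate ratios, and the 2x2 chi-square p-value);
* equivalence of episode collapsing and of persistence runout/gap logic
  with brute-force day-by-day simulations on 1000 random claim streams
  each;
* exact recovery of ground-truth episodes on noise-free bundles
  (steroid capture 1.0, all noise channels 0) for 500 members;
* end-to-end parameter recovery: 200 replicates of the full pipeline
  (simulate, select, detect, persist, match, fit) at about 500 matched
  pairs per replicate with true rate ratio 0.38, requiring the mean
  estimate in [0.33, 0.43] and 95% CI coverage in [0.90, 0.98]; and 300
  null replicates (true ratio 1) requiring type-I error in [0.03, 0.08].
  The recovery scenario keeps the default confounding, capture and visit
  noise but sets the stray-steroid channel to zero: stray steroid fills
  near routine MS visits create false-positive episodes in both arms,
  which attenuates any true ratio toward 1 (at the default stray rate the
  recovered ratio sits near 0.46 instead of 0.38). That attenuation is a
  real property of claims-based outcome ascertainment worth knowing
  about, and it is documented here rather than hidden by turning the
  noise off globally;
* matching validity on every run (caliper, one-use, identical stratum
  histograms across arms) and strict improvement of the worst
  standardized mean difference after matching in at least 95% of 50
  confounded replicates.

Replicate sizes (1350 members to yield roughly 500 pairs, 200 + 300
replicates, 50 matching seeds, 2000-member calibration runs over 20 seeds)
are the package's chosen study sizes for these checks; they keep the whole
suite in the tens of minutes on a single core.

## Known limitations

* Age is index year minus birth year; claims extracts carry birth year
  only, so ages can be off by up to one year around birthdays.
* The schema carries no inpatient drug field: DMTs administered during a
  hospital stay are invisible, as in the source data.
* A discontinuation followed by a restart of the index therapy inside the
  horizon does not re-open persistence (first-event precedence).
* The Kaplan-Meier analysis censors at discontinuation; if
  discontinuation is informative for relapse risk the curves carry that
  bias, and a competing-risk treatment is out of scope.
* Adherence ratios (MPR/PDC), cost outcomes, disability progression and
  multiplicity adjustment are out of scope by design.
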