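---
title: "Simulating and evaluating AI-assisted double reading in breast screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and evaluating AI-assisted double reading in breast screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

UK breast screening reads every mammography episode twice: two human readers
independently decide recall or no recall, a third reader arbitrates
disagreements, and — depending on the site — either recalls agreed-positive
cases directly or arbitrates those too. Double reading is safe but expensive,
and reader capacity is the binding constraint of many programmes.

A fixed-operating-point AI system that emits a binary recall opinion can be
inserted into this workflow as an *independent second reader*. screenflow
simulates and evaluates the two standard insertions:

* **sIR** (supporting independent reader): the AI acts as the second reader
  whenever it agrees with reader 1, in either direction. Agreed no-recall
  ends the episode after one human read; agreed recall is recalled directly
  (or arbitrated, per site policy). On disagreement the case falls back to
  standard double reading using the recorded second-reader and arbiter
  opinions.
* **DRT** (double reader triage): the AI replaces the second reader only for
  agreed no-recall cases; everything else follows standard double reading.

Because DRT only ever converts "would-be recalls" into no-recalls on cases
where reader 1 and the AI both said no, its recalls are a subset of double
reading's on any cohort — an invariant the test suite checks exhaustively.

A third insertion, **XR** (additional reader), cannot be replayed
retrospectively: the AI flags cases double reading did not recall, and some
of those recalls would have found cancers that instead surfaced later as
interval cancers. Its retrospective proxy is the *interval-cancer flag
rate*: the fraction of known interval-cancer cases the standalone AI flags.

## Why a synthetic cohort generator

Case-level screening data of this kind are not publicly deposited. The
generator (`generate_cohort()`) therefore *is* the package's data module: it
produces cohorts with the statistical structure the analysis machinery
assumes, so every downstream operation can be exercised and calibrated on
data whose truth is known.

Each case carries counterfactually complete opinions — reader 1, reader 2,
arbiter and AI — even though a real retrospective extract only contains the
opinions actually rendered. This is what makes paired, within-cohort
workflow comparison possible: every workflow is replayed on the same cases.

The generative model, per centre:

1. outcome flags first: screen-detected and interval-cancer indicators are
   independent Bernoulli draws (so a case can carry both, which matches how
   such cohorts report overlapping cancer sets);
2. attributes: age is a band draw followed by a uniform draw within the band
   (published cohorts report band counts, not full age distributions);
   density, ethnicity and screening year are categorical draws; missingness
   is completely at random at the configured rates (no mechanism is
   published, so the simplest one is used);
3. opinions conditional on outcome: sensitivities apply to screen-detected
   cases and specificities to everything else. Reader 2 copies reader 1 with
   probability `reader_dependence` and is otherwise an independent draw —
   the simplest mechanism that produces positive inter-reader agreement, and
   deliberately replaceable. Interval-cancer-only cases draw their human
   opinions from the *specificity* branch: by construction the humans did
   not recall them (that is what made the cancer an interval cancer), which
   encodes the retrospective constraint. Their AI flag is drawn with
   `ai_interval_flag_rate`.

One master seed drives everything; per-centre streams are derived
deterministically from it, so a cohort is a pure function of its parameters.

### The three-centre preset

`three_centre_preset()` encodes the package's default study conditions: a
three-centre UK cohort of 306 839 episodes (189 257 / 65 839 / 51 743)
screened 2017–2021, with the published age-band, density, ethnicity and
year marginals entered as exact count ratios, screen-detected prevalence
around 0.8% and interval-cancer prevalence around 0.1% per centre
(ethnicity is captured at the largest centre only).

Reader-level operating characteristics are *not* published for such cohorts
— only workflow-level outcomes are — so the preset's values are calibrated
defaults derived from closed-form expectations of the double-reading rules:

* In retrospective data "screen-detected" means the double-reading pathway
  recalled the case, so the workflow-level detection probability must be
  close to 1. With reader sensitivity 0.99, dependence 0.4 and arbiter
  sensitivity 0.97 under direct recall, the expected detection probability
  is `s(d + (1-d)s) + 2s(1-s)(1-d) × 0.97 ≈ 0.996`, putting simulated CDR
  within rounding distance of per-centre prevalence.
* The false-positive recall probability under direct recall is
  `f(d + (1-d)f) + 2f(1-f)(1-d)(1-arbiter specificity)` with `f` the reader
  false-positive rate. Solving for the published per-centre recall rates
  (5.0%, 5.0%, 3.3%) with arbiter specificity 0.80 gives reader
  specificities 0.938, 0.938 and 0.9597.
* AI specificity 0.94 reproduces recall-rate reductions of the published
  order; AI sensitivity 0.87 and an interval flag rate of 0.412 match the
  published standalone behaviour.

These values were fixed once from the algebra above and are documented
defaults, not published facts. One structural limitation is worth stating:
the generator draws the AI opinion independently of the human opinions given
truth. Real AI and human false positives are positively correlated
(suspicious-looking normals look suspicious to both), which makes real
reader-1/AI agreement-to-recall far more common than the independence model
allows. Consequently the preset reproduces recall rates and detection rates
well, but compresses the gap between sIR and DRT workload savings (both
land near 44–45%, where the published figures are 42.5% and 39.6%).
Modelling that correlation would need an AI–reader dependence parameter
analogous to `reader_dependence`; it is deliberately out of scope of the
current parameterisation.

A woman-level structure (about 30% of women contribute two episodes) is
generated so the schema is realistic, but episodes of one woman are
otherwise independent, and all resampling treats the episode as the unit.

## Metrics, pooling and intervals

All metrics follow screening conventions and are computed from counts:
CDR (recalled screen-detected cancers per 1000 episodes), PPV (% of recalls
that are detections), recall rate (%), sensitivity (% of all cancers —
screen-detected *or* interval — that are detected; interval cancers depress
it equally for every workflow), specificity, arbitration rate, and workload
saving (1 − ratio of total human reads, where one read is one human reading
event and arbitration counts as exactly one extra read; AI opinions are
free). A workflow *detects* a cancer only if it recalls a screen-detected
case: simulated workflows can never convert an interval cancer into a
detection, again by the retrospective constraint.

Per-centre proportions get two-sided 95% Wilson score intervals, which
behave well at the tiny proportions involved (detection rates of a few per
1000). Overall estimates are *equally weighted means of the per-centre
points*, so a large centre cannot dominate the overall statistic. The Wilson
form does not apply to a mean of proportions, so pooled points carry a
percentile interval from the same stratified bootstrap used for testing —
an explicit approximation, recorded as such. Zero-denominator estimates
(e.g. PPV in a stratum with no recalls) propagate as flagged-undefined
values and are excluded from pooling with a warning, never silently coerced
to zero.

Report-time rounding is one decimal on the reporting scale; all internal
arithmetic is unrounded, and pipelines always write the unrounded table next
to the display table.

Stratification schemes cover centre, age (<60 vs ≥60, and four bands),
density (A/B vs C/D, and four levels), ethnicity (White vs Non-White, the
latter the union of Asian, Black and Mixed/other, and four levels) and
screening year. Ages compare as reals with the right stratum inclusive
(60.0 falls in ≥60). Cases missing the scheme's variable are excluded from
that stratification only, and stratum sizes plus exclusions always
reconstruct the cohort.

## Non-inferiority testing

Each AI workflow is compared with double reading on the *ratio* of equally
weighted pooled metrics (workflow / DR), with a one-sided 5% relative margin
at alpha 0.05 and a superiority test gated on a non-inferiority pass. CDR
and PPV test higher-is-better; recall rate tests lower-is-better with the
ratio orientation kept fixed and the direction handled by the decision rule.

Resampling is stratified by centre with the screening episode as the unit,
and both workflows are recomputed from the same resample, preserving the
paired design. Two implementation choices deserve explanation:

* **Multinomial profile resampling.** Every supported metric is a function
  of sums of per-case indicators, so resampling n cases with replacement
  within a centre is distributionally identical to one multinomial draw over
  the counts of *distinct per-case contribution profiles* (numerator and
  denominator indicators for both arms — a handful of cells). A replicate
  costs a K-cell multinomial draw rather than an n-case resample, which is
  what lets full-size runs (306 839 cases, 2000 replicates, all subgroups)
  finish in a couple of minutes.
* **BCa critical quantile.** The naive one-sided percentile bound is only
  first-order accurate, and for the skewed detection-ratio statistic at
  realistic event counts (a 5% margin on ~250 detections puts ~12 expected
  "boundary events" in play) it is measurably anticonservative. The package
  therefore uses Efron's bias-corrected and accelerated quantile by default,
  with the acceleration from a stratified jackknife — cheap here, because
  cases sharing a profile share a leave-one-out value. The test suite
  verifies by simulation that the resulting test holds its size at the
  margin boundary; the unadjusted variant remains available via
  `variant = "percentile"`.

Replicates with a zero pooled DR metric are skipped; if more than 1% are
skipped the comparison aborts with a diagnostic rather than reporting a
ratio the data cannot support. `n_boot` defaults to 2000 for reporting runs;
the test suite uses 150–1000 depending on what a check needs.

Workload saving is reported descriptively and never tested — it is a
deterministic consequence of the decision rules, not a sampled proportion —
and a request to test it returns an explicit `not_tested` row.

The cohort-characteristics battery mirrors standard practice: ANOVA for age,
chi-squared without continuity correction for categorical variables, an
overall test at alpha 0.05, and pairwise centre comparisons only after an
overall rejection, each judged at alpha divided by the number of pairs
(three centres, divisor 3).

## Projecting prospective detection uplift

The interval-cancer flag rate converts to an expected prospective CDR uplift
through a proportional model, `uplift = kappa × flag fraction`. The default
`kappa = 1.2 / 0.412 ≈ 2.91` is calibrated so the headline flag rate of
41.2% projects to +1.2 per 1000; published reference pairs from earlier
deployments of the same system (24.7% → 0.7–1.6 per 1000; 34.1% → 1.0 per
1000) ship as annotated calibration data (`ic_calibration_reference()`) for
sensitivity analysis rather than being fitted by default. The published
conversion method itself is not public, so proportionality is an assumption;
whether it adjusts for incomplete interval-cancer follow-up in later cohort
years is unknowable from public sources. The net change of a combination
workflow (sIR+XR or DRT+XR) is the projected uplift minus the simulated CDR
decrease of the independent-reader workflow.

## Numerical and interface choices

* Determinism: every random quantity is a pure function of an explicit
  integer seed; the pipeline derives per-task seeds from the master seed, and
  reruns of one configuration are byte-identical.
* File formats: cohorts are plain CSV with booleans as 0/1 and the token
  `NA` for missing categories; schema violations report the offending column
  and row. Configuration errors name the offending field.
* Degenerate inputs: empty cohorts are valid for I/O but refused by the
  pipeline; zero-trial Wilson intervals raise a dedicated error; single
  centre strata degrade to a simple bootstrap; single-level test variables
  are skipped with a warning.
* The agreed-recall policy defaults to `direct_recall`; site practice
  varies and both options are first-class.

## What the test suite does and does not show

Problem sizes in the suite were chosen to exercise each claim at the
smallest scale that gives it power: exhaustive enumeration (16 opinion
combinations × 2 policies) for the decision logic; 1000 random cohorts for
the subset and read-ordering invariants; 10 000 replicates at n = 1000,
p = 0.008 for Wilson coverage; 500 engineered cohorts of 5000 cases for the
size of the non-inferiority test at the margin boundary; and n = 100 000 for
generator parameter recovery within three binomial standard deviations.

Passing tests demonstrate that the machinery is correct on data satisfying
the generator's assumptions. They do not demonstrate anything about a real
screening programme: real reader correlation is richer than a copy
probability, AI errors correlate with human errors, interval-cancer
ascertainment is incomplete in recent years, and women recur across
episodes. The package evaluates workflows *given* operating characteristics;
it does not validate an AI system.
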