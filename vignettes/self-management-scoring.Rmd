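---
title: "Scoring, banding and concordance of heart-failure self-management instruments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, banding and concordance of heart-failure self-management instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrinhf)
```

## The two instruments

Chronic-disease self-management (CDSM) capability in heart-failure
outpatients can be measured two ways. The long form (LF) is the 12-item
Partners in Health (PIH) questionnaire: each item is a 0--8 Likert
response (0 worst, 8 best), summed into four domains — knowledge `K`
(items 1--2, max 16), partnership in treatment `P` (items 3--6, max 32),
symptom recognition and management `M` (items 7--8, max 16) and coping
`C` (items 9--12, max 32) — for a 96-point total. The short form (SF) is
the SCRinHF one-page triage tool: a nurse scores three self-management
domains in a binary fashion — `ma` self-maintenance, `mx`
self-management/tailoring, `mse` self-efficacy — each 0 (competent) or
1 (poor). Their sum is a 0--3 risk score that doubles as the ordinal
self-management category: 0 good, 1 average, 2 borderline, 3 poor.

`score_pih()` performs the LF summation and refuses missing or
out-of-range items rather than prorating: no imputation rule is defined
for the instrument, and silently rescaling a 12-item instrument changes
what its cut-offs mean.

## Banding and the boundary-overlap resolution

Every LF scale (16-, 32-, 48- and 96-point) is banded into the same
four categories. The published cut-off table prints overlapping bands at
two boundaries (for instance "borderline = 6--8" against "poor <= 6" on
the 16-point scale, and "average >= 17--20" against "good >= 20" on the
32-point scale). `band_score()` resolves the overlaps *best-first*:
good is tested first, then average, borderline, poor. This preserves
every printed lower bound for the better category and produces disjoint
effective intervals that exactly partition `0..scale_max`:

| scale | good | average | borderline | poor |
|-------|------|---------|------------|------|
| 16 | >= 12 | 9--11 | 6--8 | <= 5 |
| 32 | >= 20 | 17--19 | 12--16 | <= 11 |
| 48 | >= 30 | 24--29 | 18--23 | <= 17 |
| 96 | >= 56 | 49--55 | 41--48 | <= 40 |

The partition property (every integer score maps to exactly one
category) is what makes cohort category counts sum to the cohort size,
and it is enforced at scheme construction time. The alternative
resolution (worst-first, e.g. 6 on the 16-point scale scored poor) can
be obtained without code change: the schemes are data, loaded from
`inst/extdata/banding_schemes.yaml`, and any YAML file with the same
shape can be passed to `banding_schemes()`. The "average and above"
upper bounds are treated as closed, which is forced once the best-first
rule fixes the better category's lower bound.

## Mapping the long form onto the short form

The three SF domains overlap the LF domains as `ma ~ K + C`,
`mx ~ P + M`, `mse ~ K + C + P + M`. A domain passes when its LF
counterpart strictly exceeds half its maximum. Two pass rules are
implemented because the instrument documentation supports both
readings:

* **composite** (default): pass on the composite sum — `KC > 24`,
  `PM > 24`, `total > 48`. This is the rule consistent with the
  composite domain definitions used in the scale comparison, and it is
  the default for that reason.
* **conjunctive**: each constituent domain must pass individually
  (`ma = 0` iff `K > 8` and `C > 16`, and so on). Conjunctive is never
  more lenient than composite.

The thresholds are strict: a patient at exactly half marks
(`total = 48`) fails all three domains and maps to SF-equivalent poor.
Construction guarantees one published observation: a patient whose LF
total bands poor (<= 40) can never map to SF good, because 40 < 48.

Cohorts carry both the nurse-scored SF (the instrument as actually
administered) and the LF-derived equivalent; every analysis that needs
an SF category takes `sf_source = "nurse"` or `"derived"` explicitly.

## Concordance and the contingency statistics

`sf_lf_crosstab()` cross-tabulates the two instruments' categories;
`concordance_proportion()` reports exact agreement (the diagonal over
`n`, judged against the pre-specified 80% primary endpoint) and extreme
agreement, computed over the sub-population either scale rates good or
poor — the categories carrying the study's risk contrast.

The category-versus-readmission association uses the uncorrected
Pearson chi-squared on a 2x2 table, `n(ad - bc)^2 / (r1 r2 c1 c2)` at
1 df. Yates' continuity correction is available behind a flag but off
by default: on the good-versus-poor readmission table (events 5/13 vs
31/38) the uncorrected statistic is 8.674 while the corrected one is
6.72, and the uncorrected value is the one consistent with the
published analysis. The companion `exact_test_2x2()` enumerates all
tables with the observed margins and sums hypergeometric probabilities
no larger than the observed table's (relative tie tolerance `1e-7`,
matching common practice). On that same table the exact p is 0.0106 —
significant at 0.05 but, unlike the asymptotic p of 0.0032, not at
0.01; with cells this small the asymptotic test is mildly
anti-conservative, which is why the exact companion is reported
alongside.

`category_distribution_stats()` summarises banded counts as the mean
and *sample* (n-1) standard deviation of the implied score list. On SF
counts (13, 46, 20, 38) the population SD (1.038) and sample SD
(1.043) both round to 1.04; the sample convention is used and stated
rather than silently chosen.

## Outcome definitions

The 12-month composite readmission event is any unplanned
cardiovascular admission (heart-failure admissions included) **or
death**; non-cardiovascular admissions and planned procedures never
count. A flag restores the stricter admissions-only definition.
Worsening renal function is a >= 25% eGFR fall or a creatinine rise;
the rise is unquantified in the outcome definition, so the default
mirrors the eGFR criterion at >= 25% and is configurable. Failure to
attend requires strictly more than 25% of pre-booked appointments
missed, and is undefined (NA) for patients with no bookings.
`mace_summary()` bands total unplanned admissions as 0 / 1 / 2--4 /
>= 5; the middle band's upper edge is set at 4 so the four bands
partition the cohort, which the published "one-to-three" phrasing
(whose neighbouring bands are 1 and >= 5) does not.

## Validity fits

Concurrent validity regresses the LF 96-point total on the SF risk
score adjusting for age, sex and comorbidity count; predictive validity
regresses the 12-month composite event count on the same design. Both
use ordinary least squares via `linear_fit()` — a linear count model is
deliberately chosen for the predictive fit so the coefficient shares
the interpretable "events per SF point" scale; no distributional claim
is made about the count outcome, and the fit is reported with full
inference (SE, t, two-sided p, 95% CI with half-width equal to the
critical t times the SE). Sex is coded male = 1 with female as
reference; comorbidities enter as a raw count. Rank-deficient designs
are rejected naming the collinear column rather than silently dropping
it. The published validity coefficients depend on the study's raw
per-patient data, which are not deposited; what the package guarantees
instead, by simulation, is that `linear_fit()` recovers known
generating coefficients inside its own confidence intervals at the
nominal rate.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analyses
assume, not any real patient. One latent self-management trait
`z ~ N(0, 1)` per patient drives everything:

* **PIH items**: `clamp(round(4 + z + e), 0, 8)` with independent item
  noise `e ~ N(0, 2)`. The intercept 4 is the Likert midpoint (so an
  average patient sits near the 48-point pass boundary, where the
  instrument discriminates); loading 1 against noise SD 2 makes the
  domains correlate through the shared trait without collapsing them
  onto it. A single trait is the simplest structure consistent with
  correlated domains; no per-domain factor structure is claimed.
* **Nurse SF scores**: the LF-derived equivalent with each domain
  independently flipped with probability 0.1 — a modest
  misclassification rate representing nurse judgement on records-based
  scoring. Setting it to 0 makes the nurse SF reproduce the derived SF
  exactly, which is the round-trip identity the tests exploit.
* **Outcomes**: drawn conditional on the nurse SF category. Composite
  readmission probabilities default to 5/13 for good and 31/38 for
  poor — the two published category-conditional rates — with the
  unpublished intermediate categories linearly interpolated; that
  interpolation is an assumption and is flagged as such in the
  configuration. Death probabilities rise linearly from 0 (good) to
  4/38 (poor, the published extreme); death always implies a composite
  event, so the admission-only probability is rescaled to keep the
  composite at its target. Admission counts among event patients are
  `1 + Poisson(1.5)`.
* **Demographics**: age `N(66.8, 13.5)` clamped to 18--100, 75% male,
  and a comorbidity-count distribution matching the published bands
  (25.6% none, 22.3% one, ~50% three or more) with the within-band
  spread chosen uniformly, since only the bands are published.

`calibrate_to_margins()` inverts the latent-trait distribution to give
the three trait thresholds whose expected category proportions equal
any target margin (e.g. the published SF counts 13/46/20/38); the
uniform target lands on the latent quartiles and degenerate targets on
infinite thresholds.

What the generator does **not** emulate: skew in the LF domain-score
distributions (the published per-domain means and SDs imply skew that a
single Gaussian trait cannot reproduce), ethnicity/medication/NYHA
structure, visit-level longitudinal data, and any dependence of nurse
misclassification on the patient (flips are independent of `z`).
Passing tests therefore show that the estimators recover known
generating parameters under this structure — not that the instruments
behave this way in real cohorts.

## Problem sizes and numerical choices

The test suite exercises the scoring oracle on 1,000 random response
vectors, the chi-squared oracle on 200 random tables (agreement to
1e-9), coefficient recovery on 500 replicates of study-sized (n = 117)
designs, and pipeline parameter recovery on a 5,000-patient cohort —
large enough that the binomial 95% interval around each
category-conditional rate is a percentage point or two wide. The
acceptance script reruns the published-table statistics and the
5,000-patient recovery from scratch under a caller-supplied seed. All
randomness flows from one master seed per cohort via R's default
generator.

## Known limitations

* The generator targets marginal category counts and category-
  conditional event rates; joint LF domain-score moments are not
  matched.
* The intermediate-category event rates are interpolations, not data.
* The exact test enumerates a single 2x2 table; it is not a general
  r x c network algorithm.
* Auxiliary instruments (comorbidity indices, depression and
  quality-of-life scores, NYHA class) are carried as covariates or
  labels only; their internal scoring is out of scope.
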