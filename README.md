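# scrinhf

Scoring and concordance analysis for heart-failure self-management
instruments.

Chronic-disease self-management (CDSM) capability predicts hospital
readmission in heart failure, but the gold-standard instrument — the
12-item Partners in Health (PIH) questionnaire of the Flinders Program,
scored 0–8 per item for a 96-point total — takes a trained interviewer
up to 90 minutes. The SCRinHF short form replaces it at triage with
three binary, nurse-scored self-management domains (self-maintenance
*Ma*, self-management/tailoring *Mx*, self-efficacy *Mse*) whose sum is
a 0–3 risk score. This package is for biostatisticians and health-services
researchers evaluating whether the short form can stand in for the long
form: it scores both instruments, bands every long-form scale into the
four ordinal categories (good / average / borderline / poor), maps the
long form onto the short form through strict half-scale pass thresholds
(*Ma*: K+C > 24; *Mx*: P+M > 24; *Mse*: total > 48), and runs the
downstream analyses — categorical concordance against an 80% primary
endpoint, the good-vs-poor readmission contrast

```
chi² = n (ad − bc)² / (r₁ r₂ c₁ c₂),  1 df, no continuity correction
```

with an enumeration-based exact companion, 12-month outcome
classification (composite readmission = unplanned cardiovascular
admission or death; worsening renal function; failure to attend), and
covariate-adjusted OLS validity fits. A latent-trait synthetic cohort
generator reproduces the assumed data structure so every stage runs
without access to patient data.

## Worked example

```r
library(scrinhf)

# a synthetic 117-patient cohort with the default study-structure parameters
cohort <- generate_cohort(cohort_params(n = 117, seed = 42))

# score the long form, band it, and compare against the nurse short form
scores <- score_pih(cohort)
lf_cat <- categorize_lf(scores)$lf_category
sf_cat <- sf_total(cohort)
concordance_proportion(sf_lf_crosstab(sf_cat, lf_cat))
#> Concordance (n = 117)
#>   exact agreement:   0.701
#>   extreme agreement: 0.631
#>   primary endpoint (>= 80%): not met

# the good-vs-poor readmission contrast (events 5/13 vs 31/38)
pearson_chi2_2x2(contingency_2x2(5, 8, 31, 7))
#> $statistic
#> [1] 8.673785
#> $df
#> [1] 1
#> $p_value
#> [1] 0.003228199

# distribution of the short-form risk score from banded counts
category_distribution_stats(c(13, 46, 20, 38))
#> $mean
#> [1] 1.709402
#> $sd
#> [1] 1.042707
#> $range
#> [1] 0 3
```

Exact agreement 0.701 means 70% of the synthetic cohort land in the
same category on both instruments — below the 80% endpoint, as expected
with a 10% nurse-misclassification rate. The chi-squared of 8.67 at
1 df (p = 0.0032) says readmission risk differs sharply between good
and poor self-managers; the score distribution (mean 1.71, SD 1.04 over
0–3) shows the short form spreading patients across its full range.

`render_report()` runs the whole pipeline on a cohort and prints the
banding/distribution, cross-tabulation, concordance, outcome and
contingency sections together; `write_report()` saves them as CSV and
text. A thin command-line wrapper with `simulate`, `score`, `concord`,
`outcomes`, `validity` and `report` subcommands ships at
`system.file("cli", "scrinhf-cli.R", package = "scrinhf")`.

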