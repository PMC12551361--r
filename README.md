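# apcdem

Birth-cohort trends in age-specific dementia prevalence from harmonized
panel surveys.

## What this package is for

Population aging makes it essential to know whether dementia risk *at a
given age* is falling for more recently born generations. Harmonized aging
panels (HRS-, SHARE- and ELSA-style biennial surveys of adults over 70)
could answer this, but two obstacles intervene:

1. surveys carry no clinical dementia diagnosis — status must be **imputed**
   from cognitive test scores, ADL/IADL limitations, demographics and
   informant reports, calibrated against a clinically adjudicated
   gold-standard subsample; and
2. age, period and cohort are exactly collinear (age = year − birth year),
   so their effects are **not jointly identified** in a free regression.

`apcdem` implements a complete, testable pipeline for both problems,
aimed at epidemiologists and health economists working with such panels:

* **Ordered-probit imputation** of three-class cognitive status (dementia /
  CIND / normal), with separate self- and proxy-respondent models,
  between-wave change features, cutoff calibration on the gold standard,
  and out-of-sample validity reporting:
  `P(dementia | x) = Φ(κ₁ + xβ)`, `P(dementia or CIND | x) = Φ(κ₂ + xβ)`.
* A **single-hidden-layer perceptron** (ReLU, early stopping) as a
  robustness backend with the same validity metric.
* A **cohort model**: `dementia~i,t~ = δ₀ + λ₁ agegroup + λ₂ cohort +
  λ₃ period + u~i~ + ε`, where the period block is either survey-year
  dummies or the country's **annual GDP growth rate** — a measured period
  proxy that breaks the APC collinearity. Fitted as a probit/logit GLMM
  with a person-level random intercept by adaptive Gauss–Hermite
  quadrature, with cluster-robust (person-level) 95% CIs; includes an
  explicit rank/null-space diagnostic for the APC identity.
* A **synthetic cohort generator** (known age, cohort and period effects;
  observable test scores; proxy respondents; gold subsample; attrition) so
  every stage is validated by parameter recovery — the real survey
  micro-data are restricted-access.
* **Reporting**: age × cohort prevalence tables, summary-statistics tables,
  and formatted coefficient tables with fixed rounding rules, plus a thin
  command line (`inst/cli/apcdem.R`) with subcommands
  `simulate | classify | fit-apc | report | run-all`.

## Worked example

Simulate the default study conditions (10,000 persons, six biennial waves,
10% gold-standard fraction), impute dementia status, and estimate the
cohort gradient with the GDP-proxy mixed model:

```r
library(apcdem)
cfg <- sim_config(seed = 42)
gdp <- simulate_gdp_series(cfg$survey_years, cfg$countries, seed = 42)
panel <- simulate_panel(cfg, gdp)
observed <- degrade_to_observables(panel, cfg)
gold <- assign_gold_standard(observed, cfg$gold_fraction, seed = 42)

res <- classify_dementia(observed, gold)
print(res$validity)
#> Validity: 95.9% agreement with gold standard (n = 485)
#>   proxy: 91.9%
#>   self: 96.5%
#>              gold
#> predicted     no dementia dementia
#>   no dementia         418       13
#>   dementia              7       47

design <- build_design(res$records, cfg$dialect, mode = "gdp")
fit <- fit_glmm(design, link = "probit")
print(coefficient_table(list(Synthetic = fit)))
#>                cohort                Synthetic
#> 1           1914-1918 -0.10 (-0.16 to -0.03)**
#> 2           1919-1923 -0.23 (-0.31 to -0.15)**
#> 3           1924-1928 -0.38 (-0.49 to -0.28)**
#> 4           1929-1933 -0.49 (-0.62 to -0.36)**
#> 5           1934-1938 -0.45 (-0.61 to -0.29)**
#> 6           1939-1943 -0.65 (-0.84 to -0.46)**
#> 7           1944-1948 -0.70 (-0.94 to -0.46)**
#> 8 No. of observations                    46929
```

Reading the output: validity is the percentage of gold-standard validation
person-waves whose imputed binary status matches the clinical label,
reported out of sample. Each cohort row is the probit-scale shift in
dementia risk relative to the earliest (reference) cohort, net of age group
and the GDP period proxy, with person-clustered 95% CIs; the negative,
steepening gradient is the generational decline the generator was
configured with (`**` marks P < .01). The same pipeline runs from the shell:

```sh
Rscript inst/cli/apcdem.R run-all --config inst/cli/example-config.yaml --outdir out/
```

Methods, parameter meanings and validation design are documented in
`vignettes/cohort-dementia-methods.Rmd`.

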