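---
title: "Computing the burden of conflict-related injury: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing the burden of conflict-related injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(injuryburden)
```

## The model

The package measures the population-health cost of conflict-related
intentional injuries in disability-adjusted life years. For a cohort of
surveyed person-injuries,

$$\mathrm{DALY} = \mathrm{YLL} + \mathrm{YLD},$$

with each record contributing to exactly one of the two terms:

* **Deaths.** A record whose outcome is a *definitive* death from the
  injury contributes $\mathrm{YLL} = e(a_{\text{death}})$, the remaining
  life expectancy at the age of death read from a life table. Deaths only
  *possibly* related, or unrelated, to the injury never enter the YLL term:
  because YLLs dominate totals, mis-promoting an uncertain death would
  inflate the estimate, so such records are routed to the YLD pathway for
  whatever disability duration was documented.
* **Survivors.** Each disabled survivor is classified into one of five
  non-death patterns by two survey questions (did the injury limit normal
  activities; for how long):
  * *short-term* — disability resolved in under one year; YLD =
    DW × duration, with reported months/weeks/days divided by 12/52/365;
  * *long-term recovered*, treated or untreated — duration of one year or
    more; YLD = DW × duration in years;
  * *permanent*, treated or untreated — disability still present at the
    survey; YLD = DW × $e(a_{\text{injury}})$, i.e. the person is assumed
    to live out a full remaining life span (no excess mortality) without
    recovering.

  Any post-injury care (hospital, clinic, workplace) selects the *treated*
  disability-weight variant; explicit "no care" selects *untreated*;
  unknown care defaults to treated (configurable), since most of the
  surveyed injured received some care and the treated weight is the
  conservative choice.

### Life tables

`load_standard_life_table()` returns the bundled standard (aspirational)
reference table — lowest observed age-specific death rates among large
countries, life expectancy 86.02 at birth, 66.35 remaining years at age
20 — so a death is valued identically wherever it occurs. Between tabulated
ages we interpolate linearly (the conventional choice; no interpolation
rule is canonical) and carry the last entry forward beyond age 105.
`make_flat_life_table(69.4)` supports a country-specific sensitivity mode
in which remaining life expectancy is simply life expectancy at birth minus
age. A published country schedule, when available, can be supplied as a
two-column CSV via `read_life_table()`: the flat rule is a deliberately
crude fallback and demonstrably cannot reproduce intermediate sensitivity
results computed from a full country table, which is why the sensitivity
mode is validated only by its closed-form arithmetic.

### Incidence versus prevalence YLDs

Incidence-based YLDs assign all future disability years of an injury to the
injury year — the package's primary convention, because it tracks the ebb
and flow of a conflict. Prevalence-based YLDs spread the same person-years
over the calendar years actually lived with the disability, capped at the
end of observation (`study_end`, default 2014.42 ≈ 1 June 2014, the close
of field work). With an unbounded horizon the two conventions sum to the
same total for every record — a package invariant tested to $10^{-9}$. For
a 20-year-old permanently disabled with DW 0.2, both give
$0.2 \times e(20) \approx 13.3$ YLDs; the incidence convention books them
all in the injury year, the prevalence convention 0.2 per year for life.

Records carry only an injury *year*, so the injury is placed at mid-year
(`injury_offset = 0.5`), the standard demographic convention; the first and
last calendar years receive fractional allocations. Setting
`injury_offset = 0` reproduces the whole-year arithmetic of textbook
examples (0.2 per whole year over a three-year window = 0.6).

## Disability-weight uncertainty

Each registry entry (code × treated/untreated/single variant) has a mean
and 95% interval in [0, 1]. Draw-level uncertainty uses a beta
distribution: `fit_beta_dw()` parameterises Beta($\mu c$, $(1-\mu)c$) so
the analytic mean equals the published mean *exactly* for any
concentration $c$, then chooses $c$ by minimising the squared error of the
2.5th/97.5th percentiles against the published bounds
(`stats::optimize` on $\log c$). A beta family is the natural bounded
choice for a [0, 1] severity; a degenerate interval (lower = mean = upper)
yields a point mass rather than an error. Each entry draws from its own
sub-seed, so draw matrices are reproducible and entries independent.

The bundled starter registry is **synthetic**: illustrative values in the
style of the published injury DW appendix, sufficient to exercise all six
patterns. Real analyses should load the published appendix as a CSV.
Mapping free-text injury descriptions to DW codes is deliberately out of
scope — records must arrive with a `dw_code`, assigned upstream or through
the reader's dialect map.

## Completeness filtering

Burden needs different fields per pathway: age at death for deaths, age at
injury for permanent disabilities, duration for recovered ones, and DW
information for every survivor. `apply_completeness_filter()` partitions
records accordingly and itemises exclusions ("missing age/duration" before
"missing DW info", mirroring the order the reference survey reported); the
reader guarantees every CSV row becomes either a record or a reasoned
exclusion. Survey dialects differ, so a YAML map renames columns and enum
spellings without code changes.

## Bootstrap, causes, extrapolation

`bootstrap_burden()` repeats the whole computation (default 1,000 times):
each iteration resamples the $n$ complete records with replacement and, if
`vary_dws`, substitutes one randomly selected draw *set* — a single draw
index applied to all entries, the simplest reading of mapping "a randomly
selected set of matched DWs" onto each sample; `draw_mode = "per_record"`
gives the finer-grained alternative. Points are iteration means; 95% UIs
are 2.5/97.5 percentile intervals (the convention when no estimator is
named). With resampling and DW variation both off, every iteration is
identical and the result equals the direct single pass exactly — a tested
contract.

Cause-specific decomposition resamples but holds DWs at their means
(varying them cannot change the split of a total across mechanisms);
proportions are taken from the unresampled point estimates so they sum to
one. Per-person means divide totals by all persons surveyed, per-injury
means by complete injury records, per-death YLL means by definitive
deaths. `extrapolate()` multiplies the per-person mean — point and both UI
ends separately — by a target population; it is exactly linear and the
identity at the sample size.

## The synthetic survey generator

`generate_survey()` emulates the structure of a 2014 household survey of a
conflict-affected city: ~900 households of mean size 5.72
(1 + Poisson(4.72)), an age pyramid with 12% under 5, 44.2% under 19 and
7.2% over 60 (uniform within bands), 4.4% of persons suffering a conflict
injury in 2003–2014, 39% case fatality, and a gunshot-dominated mechanism
mix calibrated to the reference sample's cause shares. Survivors split
55/15/30 between short-term, long-term-recovered and permanent patterns
(chosen so that roughly half the disabled carry lasting impairment, as
field reports of weapon injuries suggest; the reference study publishes no
pattern breakdown). Durations are discrete-uniform: 1–90 days, 1–51 weeks
or 1–11 months for short-term (30/40/30 unit mix), 1–10 whole years for
recovered long-term — uniform mixtures are transparent and give exact
closed-form expectations for the oracle. Missingness (default 20% of
injury records, all among survivors, as in the reference survey's
exclusions) is MCAR, masking age + duration for ~63% of affected records
and the DW code for the rest; a ground-truth ledger retains every latent
value, and unmasked fields always agree with it.

What the generator does **not** emulate: household clustering effects on
variance (clusters exist only structurally), recall decay over the survey
window, non-uniform injury-year intensity, correlation between mechanism
and severity, and informative (non-MCAR) missingness. A green pipeline test
therefore establishes computational correctness under a known data-
generating process, not robustness to those real-data features.

`analytic_expected_burden()` is the matching oracle: the closed-form
expected per-person DALY implied by the configuration — injury rate ×
[CFR × E$e(A)$ + (1 − CFR) × retention × E(DW × duration)] — with the age
expectation evaluated exactly on the integer-age distribution.

## Numerical and edge-case choices

* Exactly one year of disability is *long-term* (the rule is "short term"
  strictly under one year); reported durations are taken at face value.
* Ages beyond the life table carry the final entry forward, floored at 0.
* Negative ages/durations and incoherent life tables (age + remaining LE
  decreasing) are hard errors; unknown enum spellings are per-row
  exclusions, never silent drops.
* `quantile()` type 7 (R default) for percentile intervals.
* Empty cohorts: `direct_burden()` reports zero totals with NA (flagged)
  intervals; `bootstrap_burden()` refuses to resample nothing.
* Seeds are plain 32-bit integers; every stochastic entry point
  (`generate_draws`, `generate_survey`, `bootstrap_burden`,
  `cause_specific_burden`) is deterministic given its seed.

## Known limitations

* **Bootstrap SE understates survey-to-survey variance of per-person
  means.** The bootstrap resamples the *fixed* set of complete injury
  records, conditioning on how many injuries the survey found. Across
  independent surveys the per-person mean also varies with the binomial
  injury count, inflating the true sampling SD by roughly
  $\sqrt{E[X^2]/\mathrm{Var}(X)}$ (≈1.4 here, where $X$ is a record's DALY
  contribution: deaths ≈ 57 years, survivors ≈ 3). A nominal ±2-SE band
  from the records bootstrap therefore covers the generator's analytic
  expectation in only ~85% of replicate surveys, not 95% — a property of
  the records-bootstrap design itself, visible in the package's own
  parameter-recovery experiment, and worth remembering when reading the
  survey-level uncertainty intervals.
* Permanent disability assumes full remaining life expectancy and no
  recovery after the survey — both conservative in opposite directions.
* No comorbidity adjustment (one pattern per record), no age weighting, no
  time discounting, no survey design-effect weighting.
* The per-injury mean's denominator is ambiguous in the reference
  reporting; the package uses complete records.
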