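---
title: "Assessing population health performance from insurance claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing population health performance from insurance claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healthperf)
```

## The problem

Regions that pay medical communities by capitation — a fixed budget per
enrolled person per year — need two things the raw payment mechanism does
not provide: a way to price the budget to each person's health risk, and a
way to tell whether the community is actually keeping its population
healthy rather than just treating disease. Diagnosis-based case-mix
systems (such as ICD-driven clinical grouping) assume coding practices and
primary-care structures that many claims systems do not have. `healthperf`
implements an assessment model that needs only enrollment and claims flow
data: who is enrolled, whether they contracted with a family doctor, how
often they used which consultation category, and what it cost.

This vignette describes the model, the defaults, the numerical
conventions, and what the bundled synthetic generator does and does not
demonstrate.

## Step 1: health-risk grouping

The grouping unit is the *enrollee-year*: one enrolled person's
demographics plus per-category visit counts and costs for one calendar
year (`aggregate_claims()`). Enrollees with no claim lines appear with
zero visits and zero cost — the non-attenders, who matter throughout: they
anchor class 0 and dilute the per-capita reference mean.

A taxonomy is an ordered rule list (first match wins) over four
indicators: family-doctor contract status, age band, sex, and visit type
(consultation-category pattern × annual visit level). The shipped default
enumerates 214 groups:

| rule (precedence order) | condition | axes crossed | groups |
|---|---|---|---|
| `hosp` | any hospitalization | contract × 6 age bands × sex × 4 visit levels | 96 |
| `spchron` | special- and chronic-disease outpatient | — | 1 |
| `special` | special-disease outpatient, no chronic | — | 1 |
| `childchron` | chronic outpatient, age 0–6 | — | 1 |
| `chronic` | chronic outpatient, age 7+ | contract × 3 coarse age bands × 3 coarse visit levels | 18 |
| `gop` | general outpatient only | contract × 6 age bands × sex × 4 visit levels | 96 |
| `nonatt` | no visits | — | 1 |

Design points worth making explicit:

* **The 214-group composition is a reconstruction.** The count, the axes,
  the age bands (0–6, 7–17, 18–45, 46–59, 60–79, 80+), the visit levels
  (0, 1, 2–3, 4–5, 6+) and the named carve-outs (non-attenders; special
  without chronic; special with chronic; early-childhood chronic) are
  fixed constraints; how the remaining cells are coarsened to reach
  exactly 214 is this package's documented choice (two full
  96-cell crosses for hospitalization and general-outpatient-only
  patterns, and a coarsened 18-cell cross for adult chronic-only
  patients). Any other composition can be supplied as a YAML
  configuration (`read_taxonomy()`); exact replication of any particular
  deployed scheme is not claimed.
* **Precedence.** Hospitalization outranks special outranks chronic
  outranks general outpatient, mirroring definitions by exclusion
  ("special *without* chronic"). A person is assigned by the first rule
  they match, so rules need not be mutually exclusive.
* **Visit level uses total visits across categories**, since the visit
  axis is a severity proxy, not a per-category tally.
* Validity is checked at configuration time: bands must partition their
  ranges and an exhaustive probe population must be fully covered, so
  `assign_group()` is total by construction.

## Step 2: cost weights and utilization classes

A group's cost weight is its mean annual cost divided by the per-capita
reference mean of the same population-year. The default reference is **all
enrollees including non-attenders**, because capitation is priced per
enrollee; `reference = "attendees_only"` is available, and an explicit
numeric `reference_mean` supports cross-year and planted-scale analyses.

Classes are cut at weights 0.2, 1, 4 and 8 with **lower-exclusive /
upper-inclusive** bands and {0} alone in class 0. The convention is forced
at the class-2/3 boundary: class 3 is "above-average consumption", so it
must open strictly above 1; the other cuts follow the same convention.
Exactly-on-cut weights (0.2, 1, 4, 8) therefore belong to the class below.
`classify_weight()` is non-decreasing, and class 0 is exactly the
zero-weight groups — the non-attender group, plus any pathological
zero-cost attending group.

Shares are computed on exact totals and reported rounded **half away from
zero** to 2 decimals (the convention of published distribution tables;
base R's `round()` rounds halves to even and would disagree on boundary
cases).

## Step 3: the year-over-year verdict

`assess_trend()` compares two class tables. With low block L = classes
0+1 and high block H = classes 4+5, and deltas Δ in percentage points
(later minus earlier):

* improving: ΔL > ε and ΔH < −ε
* worsening: ΔL < −ε and ΔH > ε
* unchanged: |ΔL| ≤ ε and |ΔH| ≤ ε
* mixed: otherwise

computed independently for headcount and expense shares. The tolerance ε
defaults to 0 (strict signs) since the source framework states none;
positive ε is for small noisy populations. The combined verdict when
headcount and expense disagree is deliberately `mixed` — the framework
defines conclusions only for the concordant cases, and inventing a
weighting would overstate what the data say. Multi-year series are
assessed pairwise against a base year; no trend regression is fitted.

### Comparing years on a constant basis

`assess_years()` offers two bases:

* `basis = "per_year"` classifies each year against its own reference
  mean — the style of a published per-year distribution table.
* `basis = "fixed"` (default) holds the **base year's reference mean and
  group-to-class map** fixed when tallying the comparison year.

The fixed basis exists because relative weights re-centre themselves: if
health improves, the per-capita mean falls, every surviving group's weight
inflates, and large groups near a cut point can cross upward *en masse* —
a composition artifact that can mask or fake real movement (the analogue
of constant-price deflation in economics, or a Laspeyres index holding the
basket fixed). On simulated populations the fixed basis recovers the
planted direction of health change far more reliably; the per-year basis
remains available for table-style reporting.

## Step 4: budgets and settlement

Per-enrollee budget = base rate × the cost weight of the enrollee's
health-risk group, where the base rate defaults to the reference
population's per-capita mean cost and the weights come from an explicitly
chosen reference year (using last year's weights to price this year's
budget is the typical arrangement; the package does not guess). With the
all-enrollee reference and base rate equal to the reference mean, the
total budget reproduces the reference year's total cost exactly, and the
scheme reduces to pure capitation when all weights are 1. Non-attender
groups get weight 0, hence zero budget; `floor_weight` (off by default)
imposes a minimum weight if zero budgets for never-attenders are
undesirable.

Settlement per community is budget versus actual with balance retention:
payment = min(actual, budget), retained balance = max(budget − actual, 0),
overrun informational. Settlement arithmetic is done in integer cents, so
payment + retained = budget holds exactly.

## The synthetic generator

`simulate_population()` draws a fixed cohort (no churn; ages increment
yearly) with a county-style demography — 7/12/36/20/20/5% across the six
age bands, even sex split, family-doctor contracting rising from 30% in
childhood to 75% at 80+ — and evolves a latent five-state morbidity chain
(healthy, mild, moderate, severe, very severe) across years.

Per state and year: a zero-inflation draw decides attendance (p of no
visit: 60/25/10/3/1%), attenders make 1 + negative-binomial extra visits
(means 0.8/2/4/7/10), each visit gets a category from a state-specific
mix (severity shifts mass from general outpatient toward chronic, special
and hospital care) and a lognormal cost (shared log-sd 0.8,
hospitalization ×8). Two calibration choices deserve emphasis:

* **State cost scales target the class mid-bands.** Each state's expected
  annual cost is solved to be 0.1, 0.5, 2, 6 and 12 times the per-capita
  mean (2000 currency units at default prevalences 50/30/13/5/2%, which
  make the weighted multipliers average 1). Groups dominated by one state
  then sit well inside one class band, so class membership reflects
  morbidity rather than cut-point luck.
* **The default transition matrix is stationary at the default initial
  distribution.** It is a birth–death chain (one severity step per year)
  whose deterioration rates are derived from the recovery rates by
  detailed balance, so the `"stable"` scenario holds the state mix flat
  and scenario tilts act against a flat baseline. `scenario_shift()`
  moves a fraction (default 0.2) of every destination probability one
  state toward the healthy (or sick) end, preserving row sums.

The defaults reproduce the qualitative structure of real county data:
a non-attender fraction around 39% (within the 25–40% band seen in
enrolled populations), zero expense in class 0, and a heavy tail in which
the two sickest classes hold a far larger expense share than headcount
share.

What the generator does **not** emulate: enrollment churn (available as a
config option in spirit but off — real rosters drift by under a percent a
year), within-year seasonality, prices varying by institution tier,
diagnosis structure, and family-level correlation. Passing the bundled
tests therefore shows the *pipeline* is correct and directionally
sensitive under a plausible claims-generating process; it does not
validate the taxonomy's clinical homogeneity on any real population.

## Numerical conventions and degenerate inputs

* Money is held to 2 decimals; all aggregation sums integer cents, so
  cost conservation, class partition and fund conservation are exact
  identities, not approximate ones.
* Empty groups are retained with n = 0 and undefined (NA) mean cost;
  weights for them are NA and they are excluded from class tallies.
* A year whose reference population has zero total cost is a degenerate
  population error, not a division by zero.
* Duplicate (enrollee, year) roster rows, orphan claims (claims whose
  enrollee is not on the roster — hard error by default, droppable with a
  warning), unparseable fields, uncovered taxonomy configurations and
  non-stochastic transition matrices are all rejected with informative
  errors rather than repaired silently.
* Group ids are stable pipe-delimited cell descriptors
  (`pattern|contract|ageband|sex|visitlevel`), so group tables join
  across years and configurations by string equality.

## Problem sizes used in the test suite

Structural and arithmetic checks run on hand-built micro-fixtures and
populations of 1,000–10,000 enrollees. The stochastic recovery checks use
the sizes at which their guarantees are stated: six planted cohorts of
5,000 enrollees across 20 replicates for class recovery, and 20 replicates
of 50,000 enrollees × 2 years per scenario for verdict directionality.
The full suite completes in well under a minute per 10^5 simulated
enrollee-years; `simulate_population()` is vectorized and handles
10^6-enrollee county scale in seconds.

## Known limitations

* The taxonomy is a behaviour-based severity proxy: it cannot separate
  high use from high need, and carve-out groups (special/chronic) are
  single cells with heterogeneous costs.
* Verdicts are point comparisons of shares; no sampling uncertainty is
  attached (the source framework performs none), so small populations
  should use a positive ε or the fixed basis rather than nominal signs.
* Cost weights inherit whatever the cost column means (billed vs
  fund-paid); the package takes costs as given and applies no
  adjudication, deflation or price standardization.
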