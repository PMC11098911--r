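---
title: "Age-stratified disproportionality screening: model, assumptions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-stratified disproportionality screening: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous-report databases collect individual case safety reports (ICSRs):
one report describes one patient, the drugs they received, and the adverse
reactions observed, coded as dictionary preferred terms (PTs). Because there
is no denominator of exposed patients, association screening works by
*disproportionality*: a drug-reaction pair is suspicious when reports
carrying both are over-represented relative to what the rest of the database
would predict. pvsignal implements this screening with a pediatric focus —
drug exposure and the clinical presentation of syndromes such as catatonia
change radically between infancy and adolescence, so every analysis in the
package is stratified into three age bands: infants (0-23 months), children
(2-11 years) and adolescents (12-17 years). The bands are half-open in
months, `[0,24)`, `[24,144)` and `[144,216)`, so they partition the
pediatric range without gaps; the colloquial phrasing "under 23 months"
would leave month 23-24 unassigned, so the infant band runs to the 24-month
boundary.

## The statistics

For one drug, one PT query and one stratum, the case/non-case 2x2 table is

|            | query PT | no query PT |
|------------|---------:|------------:|
| drug       | a        | b           |
| no drug    | c        | d           |

with `N = a + b + c + d` reports in the comparison pool.

**Reporting odds ratio.** `ROR = ad / bc`, with the Woolf confidence
interval `exp(log ROR ± z sqrt(1/a + 1/b + 1/c + 1/d))`, `z = 1.96` at 95%.
If any cell is zero, 0.5 is added to all four cells (Haldane-Anscombe) and
the result is flagged `corrected`; with `a = c = 0` the query PT is absent
from the pool and the statistic is refused rather than corrected.

**Information component.** With observed count `O = a` and expected count
under independence `E = (a+b)(a+c)/N`,

`IC = log2((O + 0.5) / (E + 0.5))`.

The half-count shrinkage pulls small-count pairs toward zero, damping
false positives when `E` is small. The lower 95% credibility bound uses the
closed-form approximation

`IC025 = IC − 3.3 (O+0.5)^(−1/2) − 2 (O+0.5)^(−3/2)`,

which tracks the exact 2.5% quantile of the Gamma(O+0.5, E+0.5) posterior
of the reporting-rate ratio; `compute_ic(..., method = "exact")` exposes
that quantile directly, and the test suite holds the two within 0.15 bits
of each other whenever `a >= 5`. The literature this methodology descends
from gives the shrinkage IC without printing a closed form for the bound,
so the approximation/exact pairing is a design choice made here and kept
cross-checked rather than assumed.

**Signal criterion.** A pair is flagged if and only if all three hold:
`a >= 5` cases, `IC025 > 0`, and the ROR CI lower bound exceeds 1. The
threshold applies to the case count with the drug, per PT query and per
band. No multiple-testing adjustment is applied — disproportionality
screening conventionally reports all nominal signals and defers error
control to clinical review; the null-calibration test below measures the
actual false-flag rate of the dual criterion.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_cases` | 5 | minimum case count for a drug to enter a scan |
| `roles` | suspect, interacting | drug roles counted as exposure; concomitant medication is context, not exposure. Whether published per-drug counts include concomitants is usually unstated, so this is configurable |
| `background` | stratum | comparator pool. `stratum` draws non-cases from the case band (conservative, removes age-driven confounding by design); `global` uses the whole database while keeping cases band-restricted |
| `z` | 1.96 | normal quantile of the ROR interval |

Ages are always normalized to months (days / 30.4375, years x 12) before
banding. Reports aged 18 years or older are out of scope and excluded from
banded analyses; the pipeline log records how many.

## The synthetic world

Real pharmacovigilance databases are access-restricted, so the package
ships a generator whose output has the *statistical structure* the analysis
assumes, with known ground truth:

- **Age bands** are drawn with mix 18% infants / 22% children / 25%
  adolescents / 35% adults, ages uniform in months within band, recorded in
  days, months or whole years depending on age to exercise unit handling.
  The adult background exists so that band restriction has something to
  exclude; the pediatric share is deliberately large compared with a real
  database so that pediatric cells are informative at 50,000 reports.
- **Drugs**: each report carries `1 + Poisson(0.7)` distinct drugs drawn
  without replacement with band-specific catalog weights — vaccines dominate
  infant exposure, immunosuppressants and corticosteroids child exposure,
  antipsychotics and other psychotropics adolescent exposure. The catalog
  values act as sampling weights under a fixed drugs-per-report
  distribution; the marginal exposure probability of a drug is therefore
  approximately `E[k] * w / sum(w)` within its band rather than `w` itself.
- **Reactions**: each catalog PT fires independently with baseline
  probability `p0`, multiplied by the rate ratio `lambda` of every planted
  association whose drug is present and whose band matches (capped at 1).
  If nothing fires, one PT is drawn proportional to the report's PT
  probabilities, so every report has at least one reaction.
- **Demographics** (sex, country, reporter qualification, seriousness,
  outcome) follow fixed categorical mixes with explicit `unknown` levels;
  a fatal outcome forces the death seriousness criterion so the schema
  invariants hold by construction. The mixes are fixture choices shaped
  like real report tabulations, not estimates of any particular database.

Two generator choices deserve justification. First, the PT catalog contains
a dozen common background reactions whose baseline probabilities sum to
about 1. This is realistic (every spontaneous report has at least one coded
reaction, usually a common one), and it is also what keeps the planted
`lambda` interpretable: the guaranteed-reaction rule redistributes
probability proportionally, so when it fires rarely the realized
case/non-case odds ratio stays within a few percent of `lambda`. With a
rare-PT-only catalog the rule would dominate reaction generation and
attenuate every planted association; calibration is therefore asserted
empirically over replicates, not claimed analytically. Second, `lambda` and
the ROR estimand coincide only because all reaction probabilities are small
(odds ratio ≈ risk ratio); this approximation is part of the stated world
and is what the coverage test actually measures. When several planted
associations share a report (e.g. two antipsychotics on one adolescent
report), their multipliers compound — the default configuration shows this
deliberately, and the recovery tests use one planted pair per band to keep
the estimand clean.

Determinism: one seed, one dataset, byte for byte. The generator pins the
RNG (`Mersenne-Twister`, `Inversion`, `Rejection`) and draws in a fixed
documented order, so results reproduce across platforms and R versions
from 3.6 on.

## What a green test does and does not establish

The generator does *not* emulate co-prescription correlation structure,
secular reporting trends, country reporting cultures, masking/competition
bias, or duplicate reports. A passing recovery test establishes that the
scan finds associations of the planted form at the planted strength in a
database with this structure — it says nothing about confounding patterns
the generator cannot produce. Conversely the published per-stratum signal
tables from the real database cannot be reproduced numerically here at
all: their non-case background is the full database of tens of millions of
reports. What the package reproduces from print is exact: every published
row satisfies the dual signal criterion as implemented, and every printed
cohort percentage recomputes from its printed numerator and denominator
under the package's rounding rule.

## Numerical choices and edge cases

- **Rounding**: all printed percentages use round-half-up at one decimal
  (`floor(10x + 0.5)/10`), not banker's rounding. Published cohort tables
  are internally inconsistent about this in two cells (the same 242/421
  printed as both 57.5% and 57.4%); the package fixes one rule and applies
  it everywhere.
- **Ties** in every ranked output break alphabetically after count
  descending, so rankings are deterministic.
- **Empty case sets**: percentage-producing operations refuse them
  (undefined denominators) rather than returning NaN; scans return an empty
  table and log it.
- **Zero cells**: Haldane-Anscombe correction applies to the ROR only; the
  IC's shrinkage already handles zeros, and mixing corrections would
  double-shrink.
- **Seriousness**: the schema makes `serious` a mandatory boolean tied to
  its criteria list, so seriousness percentages use the full column
  denominator. Real databases have unknown seriousness; published counts
  implying an unstated denominator cannot be reconstructed, and the package
  always prints its denominators explicitly.
- **Age is mandatory**: the entire analysis is age-stratified, so reports
  without age are rejected at ingest. Whether the source database excluded
  age-missing reports before its published totals is unknowable from print;
  this package makes the exclusion explicit and auditable.

## Limitations

Single-PT exact matching (no dictionary hierarchy, no standardized query
expansion); no duplicate detection; no PRR/EBGM or Bayesian hierarchical
alternatives to the IC; no time-to-onset analytics. These are scope
decisions, not oversights: the package is the measurement core an
age-stratified screening study needs, with its statistical behaviour
verified against ground truth.
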