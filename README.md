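# pvsignal

Age-stratified disproportionality screening of spontaneous adverse-event
reports, in R.

Pharmacovigilance databases hold individual case safety reports (ICSRs):
one patient, the drugs received, the adverse reactions coded as dictionary
preferred terms (PTs), plus demographics and reporter metadata. With no
exposure denominator, association screening relies on *disproportionality*
— a drug–reaction pair stands out when reports carrying both are
over-represented against the rest of the database. pvsignal implements the
full case/non-case workflow with pediatric age stratification (infants
0–23 months, children 2–11 years, adolescents 12–17 years), for analysts
studying age-dependent safety profiles of syndromes such as drug-related
catatonia, where infant exposure (vaccines), child exposure
(immunosuppressants, corticosteroids) and adolescent exposure
(antipsychotics) differ completely.

For a drug *D* and PT query *Q* in one age stratum, the 2×2 case/non-case
table (a = D∧Q, b = D∧¬Q, c = ¬D∧Q, d = neither, N = a+b+c+d) yields:

- **Reporting odds ratio** ROR = ad/bc with Woolf 95% CI
  exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d)); Haldane–Anscombe +0.5 on all
  cells when any cell is zero.
- **Information component** IC = log₂((O+0.5)/(E+0.5)) with O = a,
  E = (a+b)(a+c)/N, and credibility bound
  IC₀₂₅ = IC − 3.3(O+0.5)^(−1/2) − 2(O+0.5)^(−3/2)
  (exact Gamma-posterior quantile available as a cross-check).
- **Dual signal criterion**: flagged iff a ≥ 5, IC₀₂₅ > 0 and the ROR CI
  lower bound exceeds 1.

Because real report databases are access-restricted, the package includes a
synthetic ICSR generator with age-band-dependent exposure, baseline PT
reporting rates and *planted* drug–PT associations of known strength, so
that the scan's calibration (false-flag rate under the null) and recovery
(power and CI coverage at a planted rate ratio) are tested against ground
truth rather than assumed.

## Worked example

```r
library(pvsignal)

gen <- generate_report_set(default_pediatric_config(1), seed = 42)
rs  <- gen$reports
summary(rs)
#> <report_set> 50000 reports, 25 distinct drugs, 28 distinct PTs
#>   serious: 22939 (45.9%)
#>       infant        child   adolescent out_of_scope
#>         9178        10881        12488        17453

run_signal_scan(rs, pt_query("catatonia", "catatonia"), band = "child")
#> Disproportionality scan: 'catatonia' | band child | background stratum
#>   10881 reports in pool, 152 cases; drugs with >= 5 cases: 14
#>                   drug  n  pct   ROR       95%CI    IC IC025 signal
#>           prednisolone 82 53.9  8.42  6.09-11.65  2.05  1.68      *
#>            ciclosporin 72 47.4  8.58  6.20-11.87  2.20  1.81      *
#>            haloperidol 35 23.0 16.50 11.02-24.72  3.28  2.72      *
#>            paracetamol 24 15.8  0.96   0.62-1.50 -0.04 -0.73
#>            amoxicillin 19 12.5  0.95   0.58-1.54 -0.06 -0.84
#>   pneumococcal vaccine 13  8.6  1.03   0.58-1.83  0.04 -0.90
#>   ...
```

Reading the output: among the 10,881 child-band reports, 152 carry the
catatonia PT. Fourteen drugs reach the 5-case threshold; the three planted
child-band associations of the default configuration (prednisolone,
ciclosporin, haloperidol) are flagged — each has at least 5 cases, a
positive IC₀₂₅ and an ROR interval excluding 1 — while background drugs
like paracetamol sit at ROR ≈ 1 and are not. `n` is the case count with
the drug, `pct` its share of the 152 cases.

Reports travel as JSON Lines (`read_report_set()` / `write_report_set()`,
one report per line, fixed key order, byte-stable round trip).
`run_pipeline("config.json")` drives the whole study — cohort
characteristics, top drugs, outcomes, per-band signal tables for the
catatonia-family PT queries, co-occurrence counts, and a
healthcare-professional-only sensitivity rerun — into deterministic TSV
outputs; `inst/exec/pvsignal` wraps simulate/scan/pipeline for shell use.
See the vignette in `vignettes/` for the model, its assumptions, and the
design decisions.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the default 50,000-report synthetic database at the given
seed, runs the full pipeline end to end plus per-band catatonia scans, and
writes the result JSON to `--out`.
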