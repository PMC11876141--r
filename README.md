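# faersignal

Pharmacovigilance signal detection for FAERS-style spontaneous-report data,
built around the safety analysis of the polatuzumab vedotin + bendamustine +
rituximab (pola+BR) regimen for relapsed/refractory diffuse large B-cell
lymphoma.

Spontaneous-report databases such as the FDA Adverse Event Reporting System
(FAERS) distribute quarterly extracts as five dollar-delimited ASCII tables
(DEMO, DRUG, REAC, OUTC, INDI). A disproportionality analysis over these
data asks whether an adverse event (a MedDRA Preferred Term, PT) is reported
more often with a drug regimen than with everything else. `faersignal`
implements that workflow end to end:

1. **Ingestion** — typed, validated readers and writers for the quarterly
   five-table bundles plus a PT → System Organ Class (SOC) map.
2. **Deduplication** — one report per case, keeping the version with the
   most recent FDA acceptance date (ties broken by larger `primaryid`).
3. **Cohort construction** — a report joins the regimen cohort when every
   regimen component is present as a primary or secondary suspect drug.
4. **Signal detection** — for each PT with at least 10 cohort reports, the
   reporting odds ratio over the 2×2 table (a, b, c, d) of cohort/comparator
   × with/without the PT:

   ROR = (a·d)/(b·c),  95% CI = exp( ln ROR ± 1.96·√(1/a + 1/b + 1/c + 1/d) )

   A signal is *significant* when the interval's lower bound (ROR₀₂₅)
   exceeds 1.
5. **Clinical priority** — a semi-quantitative 0–10 score per significant
   signal from five components (report volume, ROR₀₂₅, fatal-report burden,
   designated/important-medical-event status, evidence grade), binned as
   low (0–4), moderate (5–7), high (8–10).
6. **Severity comparison** — serious vs non-serious cohort reports compared
   per PT by uncorrected Pearson χ² (Fisher's exact test when an expected
   cell is below 5) and by Welch t-tests for age and weight.
7. **Sensitivity analysis** — cumulative-by-year ROR series for the top
   signals, tracking how intervals tighten as reports accumulate.
8. **Synthetic data** — a generator that emulates the five-table schema with
   injected drug–event associations at exact target RORs (via the exposure
   odds transform p₁ = ρp₀ / (1 − p₀ + ρp₀)), planted duplicate case
   versions, suspect roles and outcome codes, so every stage is testable
   without downloading the real database.

The package ships the published pola+BR signal table (58 significant PTs
with their scoring inputs) and the published severity stratum counts as
plain-text fixtures, and reproduces the published statistics from them.

## Worked example

```r
library(faersignal)

# a synthetic world: 30,000 reports, 2% pola+BR cohort, pancytopenia
# injected at a true reporting odds ratio of 5
cfg <- generator_config(n_reports = 30000, cohort_fraction = 0.02,
                        injected_signals = tibble::tibble(
                          pt = "Pancytopenia", p0 = 0.01, rho = 5),
                        seed = 20251)
world  <- generate_faers(cfg)
cohort <- build_cohort(deduplicate(world$bundles))
cohort
#> <faers_cases> 30000 deduplicated reports (1790 versions removed)
#>   cohort: 567 reports

signals <- detect_signals(cohort, min_count = 10)
signals[signals$pt == "Pancytopenia", c("pt", "n", "ror", "ror_lo", "ror_hi")]
#> 1 Pancytopenia    23  4.69   3.04   7.24
```

The injected association is recovered: 23 of the 567 cohort reports carry
pancytopenia, the ROR estimate is 4.69, and the 95% interval [3.04, 7.24]
covers the true value 5 and stays above 1, so the PT is flagged. Scoring
the 58 published pola+BR signals with the default rubric:

```r
ann <- pola_br_signal_annotations()
st  <- score_table(tibble::tibble(pt = ann$pt, n = ann$n, ror025 = ann$ror025), ann)
st$level_counts
#>      low moderate     high
#>       30       27        1
```

Pancytopenia (score 8) is the single high-priority signal, matching the
published classification for all 58 rows.

The numbered scripts under `analysis/` run the same pipeline as a narrative
sequence (simulate → ingest/dedup → signals → priority → severity → trend)
and write their tables under `results/`.

## Scope notes

Reproducing the database-level published numbers (the 8-million-report
denominator, the 1,597-patient cohort, the published ROR point estimates)
requires the full FAERS download and is out of scope; those quantities are
exercised on synthetic data with known truth instead. Two published severity
rows (febrile neutropenia, pancytopenia) print test statistics inconsistent
with their own printed counts under any standard 2×2 formula; they are
carried in the fixture flagged `print_consistent = FALSE` and excluded from
checks. See the methods vignette (`vignettes/methods.Rmd`) for the full
modelling rationale.
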