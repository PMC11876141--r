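---
title: "Disproportionality signal detection for spontaneous-report data: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for spontaneous-report data: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous adverse-event reporting systems like FAERS collect unsolicited
reports of suspected drug harms. They have no denominator — nobody knows how
many patients took a drug without filing a report — so incidence cannot be
estimated. What can be estimated is *disproportionality*: whether an event
is reported together with a drug regimen more often than the rest of the
database would predict. This package implements that analysis for a
multi-drug regimen (the shipped configuration targets polatuzumab vedotin +
bendamustine + rituximab, pola+BR), from raw quarterly extracts to scored,
prioritized signals.

## Data model and cleaning

A quarterly extract is five dollar-delimited tables keyed by `primaryid`:
DEMO (demographics, case identity, FDA acceptance date), DRUG (one row per
drug with a role code PS/SS/C/I), REAC (MedDRA Preferred Terms), OUTC
(outcome codes DE/LT/HO/DS/CA/RI/OT) and INDI (indications). Parsing is
*total*: every row is either typed and validated or counted as a reasoned
rejection, so record count + rejection count always equals the input row
count. Child rows whose `primaryid` is absent from DEMO are dropped with a
logged count — silently including them would corrupt the denominators of
every downstream 2×2 table.

Cases arrive in versions as follow-up information accrues. Deduplication
keeps, per `caseid`, the version with the latest FDA acceptance date; exact
date ties keep the larger `primaryid` (the later database insertion). The
tie-break is arbitrary in substance but necessary for reproducibility: the
operation is idempotent and invariant to the order bundles are supplied in,
which the test suite checks by permutation.

A report joins the regimen cohort when *every* synonym set of the regimen is
matched by some drug row whose role is primary or secondary suspect.
Matching is case-insensitive exact matching on `drugname` or `prod_ai`
against user-extensible synonym lists — deliberately no fuzzy matching,
since MedDRA-coded drug strings are a controlled vocabulary and silent
fuzzy hits are worse than misses that a synonym entry can fix. An
`require_k` argument relaxes the all-of-n rule to any-k-of-n for
sensitivity analyses. Seriousness is defined from the outcome codes
{DE, LT, HO, DS}; congenital anomaly (CA) and required intervention (RI)
are treated as non-serious to match the definition the analysis was built
against, and the code set is a configurable argument because regulatory
practice differs on this point.

## The reporting odds ratio

For a Preferred Term, let `a`/`b` be cohort reports with/without the term
and `c`/`d` the same split among all other deduplicated reports. The
reporting odds ratio is ROR = (a·d)/(b·c) with the Woolf (log-normal)
interval exp(ln ROR ± z·√(1/a + 1/b + 1/c + 1/d)), z = 1.96 at the 95%
level. The counting unit is the deduplicated report with set semantics — a
report listing a term twice counts once. A term is evaluated only when
a ≥ 10 (the conventional volume filter against spurious small-count
signals) and flagged significant when the interval's lower bound, ROR₀₂₅,
exceeds 1. This is a one-sided 2.5% test per term; no multiplicity
adjustment is applied, matching standard pharmacovigilance practice where
signals are hypotheses for clinical review, not confirmed findings.

Zero cells: `ror_ci()` errors by default (the volume filter makes a = 0
impossible in the scan, so a zero cell signals a caller bug), with an
optional Haldane–Anscombe +0.5 correction applied per affected table.
`detect_signals()` uses the correction so that terms reported exclusively
in the cohort (c = 0) still yield a finite, conservative interval.

## Clinical priority scoring

Significant signals are triaged with a five-component additive score:

| component | points |
|---|---|
| 10–49 cohort reports / ≥50 | 1 / 2 |
| ROR₀₂₅ < 2 / in [2, 5] / > 5 | 0 / 1 / 2 |
| ≥100 fatal reports | 1 |
| designated medical event (DME) / important medical event (IME) | 2 / 1 |
| evidence grade ++ / + / − | 2 / 1 / 0 |

Totals of 0–4, 5–7 and 8–10 map to low, moderate and high priority. The
component thresholds are configuration, not constants: `default_rubric()`
returns a plain list that alternative score sheets can replace. The default
thresholds were chosen so that the scored output reproduces the published
pola+BR priority table exactly — all 58 (score, level) pairs, including the
boundary-pinning rows (ROR₀₂₅ of exactly 2.00 earns the middle point; 4.90
stays at 1 point while 5.40 earns 2, fixing the upper boundary strictly
above 5) and the two rows whose scores require the fatal-burden component
(death: 109 fatal reports; disease progression: 120). Evidence grading is
literature appraisal — human work — so grades are a user-supplied
annotation; a signal without an annotation is listed as unannotated rather
than scored with a silent default. The shipped DME/IME lists are synthetic
subsets seeded from the published flags (marked as such in their file
names); real analyses should substitute the full EMA lists.

## Severity comparisons

Serious vs non-serious cohort reports are compared per term on the 2×2
table of stratum × term presence. The statistic is the Pearson χ² *without*
Yates continuity correction — the uncorrected form is what published
pharmacovigilance severity tables print, and it reproduces the packaged
published statistics to the third decimal, which the corrected form does
not. When any expected cell under independence is below 5 the test switches
to Fisher's exact test (two-sided, by summing table probabilities no larger
than the observed one); an expected count of exactly 5 stays with Pearson.
Continuous demographics (age in years, weight in kg) use Welch's
unequal-variance t-test, with missing values dropped pairwise rather than
imputed — spontaneous reports are missing demographics half the time and
any imputation model would dominate the comparison. Two rows of the
published severity table print statistics that cannot be produced from
their own printed counts by any standard 2×2 formula; the fixture flags
them `print_consistent = FALSE` and no check asserts them.

## Cumulative sensitivity analysis

For each top signal (largest report counts, ties lexicographic), the 2×2
table is rebuilt from all reports with acceptance year ≤ t for each year t,
giving a series of ROR estimates and intervals. Years whose cumulative
table still has a zero cell are skipped and reported — early years may lack
comparator events for rare terms — and the final point reproduces the
all-data signal exactly, which ties the module to the main scan. A stable
signal shows intervals that narrow on the log scale as volume accumulates;
the suite checks this as a median over simulated worlds rather than per
seed, because single trajectories fluctuate.

## The synthetic world

The generator emulates the structure the pipeline consumes: quarterly
five-table bundles over 2019Q1–2023Q3 with report volume growing linearly
across quarters (mirroring the uptake pattern of a recently approved
regimen), a cohort fraction carrying the full regimen as PS/SS suspects, a
partial-regimen fraction carrying a strict subset (these must *not* enter
the cohort and exist to exercise the membership rule), background drugs on
everything else, an outcome-code distribution giving ≈28% serious reports
(near the published cohort's 29.7%), demographics with realistic
missingness (ages ≈N(60, 14) years with 50% missing, weights ≈N(73, 15) kg
with 60% missing, sex 31/44/25% F/M/unknown), and 5% of cases duplicated
into extra versions that differ only in `primaryid`, `caseversion` and a
later acceptance date — so deduplication correctness is checkable as
identity of retained clinical content.

Associations are injected on the odds scale: a term with background
per-report probability p₀ occurs in cohort reports with probability
p₁ = ρp₀ / (1 − p₀ + ρp₀), the unique value that makes the true exposure
odds ratio exactly ρ. Injecting a rate ratio instead would bias the
recovered ROR upward for common terms; the estimand is an odds ratio, so
the injection is one. The default catalog carries 50 null terms (ρ = 1)
with p₀ spread over [0.002, 0.02], letting false-positive-rate checks run
alongside power checks in the same world.

What the generator does *not* emulate: correlated term co-occurrence,
drug-name misspellings and trade-name noise, reporting waves after media
attention, and country-specific reporting cultures. Passing tests therefore
demonstrate that the machinery is correct under the stated sampling model,
not that real FAERS data meet that model.

## Verification strategy and problem sizes

Every statistic has an independent oracle in the test suite: the Woolf
interval against a hand-frozen evaluation and a binomial-GLM Wald fit; the
χ² against its closed form; Fisher's p against exhaustive hypergeometric
enumeration; contingency counts against the generator's own bookkeeping;
and the published severity and priority tables against the packaged printed
inputs. The Monte-Carlo recovery study uses 100 worlds of 2×10⁵ reports
(cohort fraction 1%, pancytopenia injected at ρ = 5 on p₀ = 0.01) and
checks 95% interval coverage within ±4 points, near-zero bias of the mean
log-ROR, and the null-term false-positive rate against its binomial error
bound; the interval-narrowing property uses 50 worlds of 2×10⁴ reports.
Module-level property tests run scaled-down versions of the same
configurations so the routine suite stays fast while the acceptance file
carries the full study conditions.

## Known limitations

- Drug-name normalization is delegated to user-supplied synonym sets; no
  built-in dictionary of trade names exists, so cohort recall on real data
  depends on the quality of those lists.
- The comparator is all non-cohort reports. Restricted (active-comparator)
  designs, stratified or adjusted RORs, and Bayesian shrinkage methods
  (BCPNN, MGPS) are out of scope.
- The priority rubric reproduces the published table but the published
  score sheet itself was not available; the rubric is a faithful
  reconstruction and is swappable via configuration.
- With ~50 terms tested per severity run at α = 0.05 and no multiplicity
  adjustment, a handful of null terms per run are expected to cross the
  threshold; the package reports α rather than enforcing an adjustment.
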