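---
title: "Methods: disproportionality signal detection on spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection on spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The setting and the model

Spontaneous reporting databases (FAERS and its siblings) are collections
of voluntary case reports, each naming one or more suspect drugs and one
or more MedDRA-coded adverse events. Because nobody observes the exposed
population, absolute risks are unidentifiable; what can be estimated is
*reporting disproportionality*: whether a drug–event pair occurs more
often among reports than independence within the database would predict.

`faersignal` counts at the level of (report, term) pairs. For a target
drug D (restricted to reports where D is the *primary suspect*, role code
`PS`) and an event term E, the 2×2 table is

|              | event E | other events |
|--------------|---------|--------------|
| reports with D (PS) | a | b |
| all other reports   | c | d |

with N = a+b+c+d the total number of pairs. Counting pairs rather than
reports makes PT-level and SOC-level tables share one denominator
definition; at SOC level each report contributes at most one pair per
organ class, and preferred terms missing from the user's hierarchy are
retained under an `UNMAPPED` pseudo-SOC so SOC counts conserve PT counts.

Four estimators of the observed/expected departure are computed per term:

* **ROR** = ad/bc with the Woolf log-scale interval
  `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`;
* **PRR** = `[a/(a+b)]/[c/(c+d)]` with the Pearson χ² on the fixed
  margins (no Yates correction unless requested);
* **BCPNN information component**, point estimate
  `IC = log2(aN/((a+b)(a+c)))`, with the closed-form posterior
  credibility bound `IC025 = E(IC) − 2√V(IC)` under the standard priors
  α₁ = β₁ = 1, α = β = 2, γ₁₁ = 1;
* **EBGM** in its simplified closed form `aN/((a+b)(a+c))` — identical to
  the argument of the IC's log2 — with
  `EB05 = exp(ln EBGM − 1.64·√(1/a+1/b+1/c+1/d))`.

A term is screened out before any statistic is computed unless a ≥ 3
(`min_a` in `signal_thresholds()`), and flagged per algorithm by the
conventional cutoffs: ROR lower bound > 1; PRR ≥ 2 with χ² ≥ 4;
IC025 > 0; EB05 > 2. Published analyses in this family defer their exact
supplementary formulas; these are the canonical literature versions, and
each rule can be disabled or re-thresholded individually.

## Numerical and degenerate-input choices

* **Zero cells.** The default policy reports ROR/PRR/EB05 as missing with
  a `degenerate` flag rather than silently applying a Haldane +0.5
  correction, because smoothing changes values that users will compare
  against published tables. `zero_policy = "haldane"` opts in to +0.5 on
  all four cells. The χ² is always computed on the raw cells. The BCPNN
  moments are finite at a = 0 through the prior, so no policy is needed
  there.
* **Ties in deduplication.** "Latest report per case" is judged by
  `FDA_DT` (receipt date — always populated, unlike the event date), with
  ties broken by the larger numeric `primaryid`. The rule is
  deterministic, so reruns are byte-identical.
* **Ages.** Unit codes DEC/YR/MON/WK/DY/HR are converted with divisors
  10⁻¹, 1, 12, 52.143, 365.25, 8766; blank codes are read as years.
  Results outside [0, 120] years and unparsable values become missing —
  anomalies are censored, not corrected, and never propagate.
* **Rounding.** Summary percentages are rounded half-up to two decimals,
  matching how published tables round (base R's `round()` is half-even).
* **Ranking.** Signal tables sort by descending ROR with missing
  (degenerate) RORs last, the ordering used in published PT tables.

## Denominator conventions in the demographic summary

Age, sex, reporter and country percentages use the number of reports as
denominator. Outcome percentages use the number of *outcome entries*: a
report can carry several outcome codes, and published cohort tables in
this field are arithmetically consistent only with the entry
denominator (e.g. a death share of 10.61% = 366 printed death entries
over 3,449 printed outcome entries, in a cohort of 3,904 reports). The
"Unknown" outcome row is the `OT` ("other serious outcome") code: a
model in which "Unknown" meant reports-without-outcome cannot reproduce
those printed percentages for any assignment of entries to reports, since
it would require more specific-outcome entries than are printed.
`reports_from_marginals()` rebuilds a report-level table from printed
marginal counts precisely so this convention is testable against
published numbers.

## What the synthetic generator emulates — and what it does not

`synth_generate()` produces corpora in the exact ASCII dialect the reader
consumes, with known ground truth (`truth_table()` returns the realized
2×2 cells from the generator's own bookkeeping, an independent oracle for
the pipeline's counting). It emulates the features the pipeline must
survive:

* multinomial background event reporting (default: 50 PTs over 5 organ
  classes with Zipf-like baseline probabilities);
* planted drug–event relative risks ρ, optionally sex-specific, applied
  by multiplying the event's unnormalized probability by ρ (and the sex
  multiplier) and renormalizing — a configuration is rejected as
  infeasible if the adjusted mass reaches 0.5;
* duplicate case submissions (default 10% of cases in 2–3 versions
  sharing `caseid`, differing only in `primaryid`, version and date);
* missing demographics (defaults: 30% age, 12% sex, 5% country — the
  order of magnitude seen in real FAERS cohort tables);
* per-drug marketing start quarters, a 2% target-drug share, 55% female
  reports.

It does **not** simulate reporting-delay dynamics, pharmacologic
plausibility, country-specific reporting cultures, masking/competition
between drugs, or correlated event co-reporting. A green synthetic test
therefore establishes that the machinery (parsing, deduplication,
joining, counting, estimation, stratification) is correct under a known
generative model — it does not establish that any particular real-world
signal is true, nor calibrate the estimators against FAERS biases such as
under-reporting or stimulated reporting.

When one event is drawn per report, the renormalized multinomial gives
the target cohort odds ρp/(1−p) against background odds p/(1−p), so the
reporting odds ratio equals ρ exactly; the parameter-recovery suite
exploits this to check both point accuracy and interval coverage at
their nominal levels. With several draws per report and within-report
de-duplication of terms, high-probability events are slightly dampened,
which is a property of the generative model, not an estimator bias.

## Design choices where the design was open

* **Duplicate-era schemas.** Quarters from the legacy era name their keys
  `ISR`/`CASE`; a shim renames them to `PRIMARYID`/`CASEID` and passes
  all other columns through. How the original study harmonized the two
  eras is undocumented; this is the package's own choice.
* **Country.** `OCCR_COUNTRY` (where the event occurred) is used, falling
  back to `REPORTER_COUNTRY`, matching the "reported countries" semantics
  of published cohort tables.
* **Sex scans.** Strata are rebuilt from scratch within each sex (tables,
  N and all), reports of unknown sex are excluded from both strata, and
  ROR is the comparison metric. Cellwise, F + M + UNK partitions the
  pooled table — an exact invariant the tests assert.
* **MGPS.** The full DuMouchel gamma-mixture EBGM (fit by marginal
  likelihood over all tables of a run) is available as an alternative
  backend but is off by default: the simplified closed form is what this
  family of published analyses reports.
* **Weight.** Weight anomalies are acknowledged in cleaning but weight is
  not carried into the data model; no downstream output uses it.

## Known limitations

* The ROR/PRR variances ignore duplicate-report correlation beyond caseid
  deduplication; no masking or competition-bias adjustment is applied.
* The IC point estimate is −∞ at a = 0 (the IC025 stays finite); such
  terms are screened out by `min_a` ≥ 3 in any default run.
* EBGM/IC monotonicity in a holds in the sparse-reporting regime
  (a ≪ b, c, d) but provably reverses once a rivals the margins; the
  package computes the statistics regardless and leaves interpretation
  to the analyst.
* `read_quarter()` requires all four member files per quarter — silent
  gaps would bias the quarterly series — so partially downloaded quarters
  must be repaired, not skipped.
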