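# faersignal

Disproportionality signal detection for spontaneous adverse-event report
databases in the FAERS quarterly ASCII dialect.

## What problem this solves

Spontaneous reporting systems such as the FDA Adverse Event Reporting
System (FAERS) collect voluntary reports of suspected drug adverse events.
There is no denominator of exposed patients, so drug safety signals are
found by *disproportionality analysis*: for a drug–event pair, compare how
often the pair is reported against what independence within the database
would predict. `faersignal` is for pharmacoepidemiologists and
biostatisticians who want that whole workflow — raw quarterly ASCII files
to ranked signal tables — as reproducible, testable R code rather than ad
hoc SQL plus spreadsheets.

The pipeline:

1. **Read** the `$`-delimited quarterly `DEMO`/`DRUG`/`REAC`/`OUTC` files
   (modern `primaryid` schema; legacy `ISR`/`CASE` columns are shimmed).
2. **Deduplicate**: cases are resubmitted as follow-up versions sharing
   `caseid`; only the latest version (by `FDA_DT`, ties by `primaryid`)
   is kept.
3. **Clean** demographics (age unit codes, sex, reporter occupation,
   country) and **standardize** verbatim drug names through a user-supplied
   synonym dictionary.
4. **Count**: for a target drug taken as *primary suspect* (role `PS`),
   build per-event 2×2 contingency tables over (report, term) pairs, at
   MedDRA preferred-term (PT) or system-organ-class (SOC) level.
5. **Score** each term with the four standard estimators and flag signals.
6. **Summarize**: demographic/outcome tables, quarterly report series, and
   sex-stratified signal scans.

## The statistics

For a 2×2 table with cells *a* (target drug & target event), *b* (target
drug, other events), *c* (other drugs, target event), *d* (rest),
N = a+b+c+d:

| Estimator | Definition | Signal rule (defaults) |
|---|---|---|
| ROR | ad / bc, Woolf CI `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))` | lower 95% bound > 1 |
| PRR | `[a/(a+b)] / [c/(c+d)]` with Pearson χ² | PRR ≥ 2 and χ² ≥ 4 |
| BCPNN IC | `log2(aN/((a+b)(a+c)))`, closed-form posterior IC025 | IC025 > 0 |
| EBGM | `aN/((a+b)(a+c))`, EB05 = `exp(ln EBGM − 1.64·√(1/a+1/b+1/c+1/d))` | EB05 > 2 |

All rules apply only to terms with reported count a ≥ 3. An optional
DuMouchel MGPS gamma-mixture backend (`ebgm_mgps()`) is available for the
EBGM column. Zero cells are reported as degenerate by default; a Haldane
+0.5 switch exists.

## Worked example

Simulate a FAERS-like corpus with a planted relative risk of 8 on one
event, then run the full pipeline:

```r
library(faersignal)

cfg <- synthetic_config(seed = 61, n_reports = 4000,
                        quarter_start = "2016Q1", quarter_end = "2017Q4",
                        planted = data.frame(drug = "drugx",
                                             pt = "Synthetic event 15",
                                             rho = 8))
synth <- synth_generate(cfg)
write_synthetic(synth, "corpus")

run <- run_pipeline(run_config(
  "corpus", "2016Q1", "2017Q4", target_drugs = "drugx",
  synonyms = "corpus/synonyms.tsv",
  hierarchy = "corpus/meddra_hierarchy.tsv", output_dir = "out"))

head(run$signals[run$signals$level == "PT",
                 c("term", "a", "ror", "ror_lo", "ic025", "eb05", "n_positive")], 3)
```

```
                 term     a      ror    ror_lo      ic025      eb05 n_positive
1: Synthetic event 15    16 6.436090 3.7420699  1.3195433 3.4309311          4
2: Synthetic event 26     6 3.892956 1.6731467  0.2204546 1.7723159          3
3: Synthetic event 10     7 1.978447 0.9153177 -0.3015118 0.9985389          0
```

The planted event tops the ranking with all four algorithms positive
(`n_positive = 4`): 16 of the target drug's reports mention it, its
reporting odds ratio is ~6.4 with a lower 95% bound well above 1, and
both Bayesian lower bounds clear their cutoffs. The runner-up is a
chance fluctuation on a background event — at this corpus size one
false co-elevation is unremarkable, which is exactly why the test suite
judges recovery over hundreds of replicates rather than one run.
`out/` additionally contains `demographics.tsv`,
`quarter_series.tsv`, `sex_scan.tsv` and a `run_log.tsv` with row counts
for every stage. The same stages are scriptable through the CLI wrapper
(`inst/cli/faersignal`): subcommands `simulate`, `run`, `signals`,
`summary`, `sexscan`.

## Data notes

MedDRA is licensed and is not bundled: supply your own PT→SOC table
(tab-separated, header `pt<TAB>soc`). The bundled
`nk1ra_meddra_subset.tsv` fixture covers only the terms used in tests and
examples. All bundled fixtures are plain text; synthetic corpora are
generated in code.
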