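Package: faersignal
Title: Disproportionality Signal Detection for FAERS-Style Spontaneous Report Data
Version: 0.1.0
Authors@R:
    person("FAERS Signal", "Maintainers", email = "maintainers@faersignal.org",
           role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for spontaneous adverse-event report
    databases in the FDA Adverse Event Reporting System (FAERS) quarterly
    ASCII dialect. Reads DEMO/DRUG/REAC/OUTC quarter files, deduplicates case
    reports (latest version per case), cleans demographics, standardizes drug
    names via a synonym dictionary, maps MedDRA preferred terms to system
    organ classes from a user-supplied hierarchy, builds drug-event 2x2
    contingency tables, and computes four disproportionality statistics with
    their conventional signal thresholds: reporting odds ratio (ROR),
    proportional reporting ratio (PRR) with chi-squared, the Bayesian
    confidence propagation neural network information component (BCPNN/IC),
    and the empirical Bayes geometric mean (EBGM). Also produces demographic
    summaries, quarterly report time series, and sex-stratified signal scans,
    and includes a synthetic FAERS-like corpus generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
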