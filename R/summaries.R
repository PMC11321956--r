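# Descriptive outputs: demographics, quarterly series, sex-stratified scans.

OUTCOME_LABELS <- c(HO = "Hospitalization", DE = "Death",
                    LT = "Life-threatening", DS = "Disability",
                    RI = "Required intervention to prevent permanent impairment/damage",
                    CA = "Congenital anomaly", OT = "Unknown")

# Half-up rounding to `digits` decimals; base round() is half-even, but
# published percentage tables use half-up.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Demographic and outcome summary for one drug cohort
#'
#' Long-format counts and percentages for age bands, sex, reporter
#' occupation, country (top-`k` plus `"Other"`), and outcome categories.
#' Age/sex/reporter/country percentages use the number of reports as
#' denominator. Outcome percentages use the total number of outcome entries
#' (a report can carry several outcome codes; the `OT` "other serious" code
#' is displayed as `"Unknown"`): this entry denominator, not the report
#' count, is what published FAERS summary tables are consistent with.
#' Percentages are rounded half-up to two decimals.
#'
#' @param reports case-report table (rows already restricted to the drug's
#'   cohort), as in `assemble()$reports`; needs `age_years`, `sex`,
#'   `reporter`, `country` and the `outcomes` list-column.
#' @param top_k_countries countries listed individually before pooling into
#'   `"Other"`.
#' @param drug label copied into the output.
#' @return data.table with columns `drug`, `section`, `category`, `count`,
#'   `pct`. Empty (with a warning) when the cohort has no report.
#' @export
summarize_demographics <- function(reports, top_k_countries = 4,
                                   drug = NA_character_) {
  reports <- as.data.table(reports)
  n <- nrow(reports)
  if (n == 0L) {
    warning("no reports in cohort; empty summary")
    return(data.table(drug = character(0), section = character(0),
                      category = character(0), count = integer(0),
                      pct = numeric(0)))
  }
  row_block <- function(section, categories, counts, denom) {
    data.table(drug = drug, section = section, category = categories,
               count = as.integer(counts),
               pct = round_half_up(100 * counts / denom))
  }
  ab <- factor(age_band(reports$age_years), levels = AGE_BANDS)
  age_tab <- table(ab)
  sex_lv <- c("F", "M", "UNK")
  sex_tab <- table(factor(reports$sex, levels = sex_lv))
  rep_lv <- c(unname(REPORTER_MAP), "unknown")
  rep_tab <- table(factor(reports$reporter, levels = rep_lv))
  ctry <- reports$country
  ctab <- sort(table(ctry[ctry != "UNK"]), decreasing = TRUE)
  top <- names(ctab)[seq_len(min(top_k_countries, length(ctab)))]
  ctry_cat <- ifelse(ctry %in% top, ctry, "Other")
  ctry_tab <- table(factor(ctry_cat, levels = c(top, "Other")))

  oc <- unlist(reports$outcomes, use.names = FALSE)
  oc_tab <- table(factor(oc, levels = names(OUTCOME_LABELS)))
  n_entries <- sum(oc_tab)

  out <- rbind(
    row_block("age", names(age_tab), as.vector(age_tab), n),
    row_block("sex", c("Female", "Male", "Unknown"), as.vector(sex_tab), n),
    row_block("reporter", names(rep_tab), as.vector(rep_tab), n),
    row_block("country", names(ctry_tab), as.vector(ctry_tab), n),
    if (n_entries > 0) {
      row_block("outcomes", unname(OUTCOME_LABELS[names(oc_tab)]),
                as.vector(oc_tab), n_entries)
    }
  )
  out[]
}

#' Quarterly report counts for one drug cohort
#'
#' One count per quarter over the range, zeros filled, so annual totals are
#' derivable by summing quarters and gaps are visible.
#'
#' @param reports case-report table for the cohort (needs `quarter`).
#' @param range a [quarter_range()] (or start label with `end`).
#' @param end optional end label when `range` is a start label.
#' @param drug label copied into the output.
#' @return data.table with columns `drug`, `quarter`, `count`.
#' @export
quarter_series <- function(reports, range, end = NULL, drug = NA_character_) {
  qs <- iterate_quarters(range, end)
  reports <- as.data.table(reports)
  tab <- table(factor(reports$quarter, levels = qs))
  data.table(drug = drug, quarter = qs, count = as.integer(tab))
}

#' Sex-stratified signal scan for one target drug
#'
#' Partitions the corpus by patient sex (reports of unknown sex are
#' excluded), rebuilds the contingency tables inside each stratum, and
#' recomputes all four statistics, enabling side-by-side F vs M comparison
#' per term.
#'
#' @inheritParams build_tables
#' @param thresholds a [signal_thresholds()].
#' @param ... passed on to [evaluate_signals()] (zero_policy, yates, ...).
#' @return data.table of signal rows with `stratum` in `{"F","M"}`.
#' @export
sex_stratified_signals <- function(corpus, target_drug,
                                   thresholds = signal_thresholds(),
                                   level = c("PT", "SOC"), hierarchy = NULL,
                                   ...) {
  level <- match.arg(level)
  out <- list()
  for (s in c("F", "M")) {
    sub <- subset_corpus(corpus, corpus$reports$primaryid[
      corpus$reports$sex == s])
    tgt <- ps_report_ids(sub, target_drug)
    if (!length(tgt)) {
      warning("stratum ", s, ": no primary-suspect report for '",
              target_drug, "'")
      next
    }
    tab <- build_tables(sub, target_drug, level = level,
                        hierarchy = hierarchy)
    out[[s]] <- evaluate_signals(tab, thresholds, drug = target_drug,
                                 level = level, stratum = s, ...)
  }
  rbindlist(out, use.names = TRUE)
}

#' Restrict a corpus to a set of report ids
#'
#' @param corpus a `"faers_corpus"`.
#' @param primaryids character vector of report keys to keep.
#' @return a `"faers_corpus"` containing only those reports and their
#'   mentions.
#' @export
subset_corpus <- function(corpus, primaryids) {
  stopifnot(inherits(corpus, "faers_corpus"))
  keep <- function(dt) dt[dt$primaryid %chin% primaryids]
  structure(list(reports = keep(corpus$reports),
                 drugs = keep(corpus$drugs),
                 reactions = keep(corpus$reactions),
                 outcomes = keep(corpus$outcomes),
                 rejects = corpus$rejects),
            class = "faers_corpus")
}
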