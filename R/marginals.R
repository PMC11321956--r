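# Expanding a published summary table back into a report-level corpus.

AGE_BAND_REPRESENTATIVE <- c("<18" = 10, "18-45" = 30, "45-65" = 55,
                             "65-75" = 70, ">=75" = 80, "Unknown" = NA)

#' Expand marginal summary counts into a report-level table
#'
#' Published cohort summaries report marginal counts per section (age bands,
#' sex, reporter, country, outcome categories). This utility rebuilds a
#' report-level table with those exact marginals — each demographic column
#' filled independently, since a summary constrains only the margins — so
#' that [summarize_demographics()] can be exercised against printed tables.
#' Outcome entries are dealt out round-robin over the reports (so a report
#' receives a second outcome code only once every report has one); reports
#' beyond the entry total carry none.
#'
#' @param counts data.frame with columns `section`
#'   (`age`/`sex`/`reporter`/`country`/`outcomes`), `category` (package
#'   vocabulary: age bands as in [age_band()]; `Female`/`Male`/`Unknown`;
#'   reporter categories; country codes with `Other`; outcome codes
#'   `DE`/`LT`/`HO`/`DS`/`CA`/`RI`/`OT`) and `count`. Age, sex and
#'   reporter sections must each sum to the same report total.
#' @param n_other_countries the `Other` country count is split over this
#'   many dummy country names so pooled countries never outrank the named
#'   ones.
#' @return data.table compatible with [summarize_demographics()].
#' @export
reports_from_marginals <- function(counts, n_other_countries = 20L) {
  counts <- as.data.table(counts)
  stopifnot(all(c("section", "category", "count") %in% names(counts)))
  sec <- function(s) counts[counts$section == s]
  n <- sum(sec("sex")$count)
  stopifnot(n > 0, sum(sec("age")$count) == n,
            sum(sec("reporter")$count) == n)

  expand <- function(s, pad = NULL) {
    x <- sec(s)
    v <- rep(x$category, x$count)
    if (length(v) < n) v <- c(v, rep(pad, n - length(v)))
    stopifnot(length(v) == n)
    v
  }
  age_cat <- expand("age")
  sexes <- c(Female = "F", Male = "M", Unknown = "UNK")
  sex <- unname(sexes[expand("sex")])
  reporter <- expand("reporter")
  ctry <- sec("country")
  ctry_v <- character(0)
  for (i in seq_len(nrow(ctry))) {
    if (ctry$category[i] == "Other") {
      split_n <- rep(ctry$count[i] %/% n_other_countries, n_other_countries)
      split_n[seq_len(ctry$count[i] %% n_other_countries)] <-
        split_n[seq_len(ctry$count[i] %% n_other_countries)] + 1L
      ctry_v <- c(ctry_v, rep(sprintf("other %02d", seq_len(n_other_countries)),
                              split_n))
    } else {
      ctry_v <- c(ctry_v, rep(ctry$category[i], ctry$count[i]))
    }
  }
  if (length(ctry_v) < n) ctry_v <- c(ctry_v, rep("UNK", n - length(ctry_v)))

  oc <- sec("outcomes")
  # entries may outnumber reports (a report can carry several outcome
  # codes): deal them out round-robin, so no report repeats a code as long
  # as total entries <= n * number of codes
  oc_entries <- rep(oc$category, oc$count)
  outcomes <- vector("list", n)
  if (length(oc_entries)) {
    slot <- ((seq_along(oc_entries) - 1L) %% n) + 1L
    dealt <- split(oc_entries, slot)
    if (any(vapply(dealt, anyDuplicated, 0L) > 0)) {
      stop("cannot expand outcome marginals without repeating a code ",
           "within a report", call. = FALSE)
    }
    outcomes[as.integer(names(dealt))] <- dealt
  }

  data.table(
    primaryid = as.character(seq_len(n)),
    caseid = as.character(seq_len(n)),
    age_years = unname(AGE_BAND_REPRESENTATIVE[age_cat]),
    sex = sex,
    reporter = reporter,
    country = ctry_v,
    quarter = "2017Q3",
    outcomes = outcomes
  )
}
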