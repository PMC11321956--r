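# Synthetic FAERS-like corpus generator with known ground truth.
#
# The generator emulates the structural features the pipeline must survive:
# multinomial background event reporting, planted drug-event relative risks
# (optionally sex-specific), duplicate case submissions (same caseid, k
# versions with incremented dates), missing demographics, and per-drug
# marketing start quarters. It does NOT attempt pharmacologic plausibility,
# reporting-delay dynamics, or country-specific reporting cultures.

#' Configuration of the synthetic corpus generator
#'
#' Defaults describe a desk-scale FAERS-like world: 20,000 reports over
#' 2015Q1--2019Q4, one 2%-share target drug plus background drugs, 50
#' preferred terms across 5 organ classes with a Zipf-like baseline
#' multinomial, 10% duplicated cases, 55% female reports, and missingness
#' echoing the unknown-age/sex fractions typical of FAERS cohorts.
#'
#' @param seed integer RNG seed; the same seed reproduces the corpus and its
#'   ground truth exactly.
#' @param n_reports number of (deduplicated) case reports to simulate.
#' @param quarter_start,quarter_end analysis window (quarter labels).
#' @param drugs data.frame(name, start_quarter, share): target drugs. Shares
#'   must sum to <= 1; the remainder is split over background drugs.
#' @param n_background number of background drugs sharing the remainder.
#' @param events data.frame(pt, soc, p): baseline event multinomial;
#'   probabilities must sum to 1.
#' @param planted data.frame(drug, pt, rho, f_mult, m_mult): planted
#'   relative risks. On a planted drug's reports the event's unnormalized
#'   probability becomes `p * rho * mult(sex)` before renormalization.
#' @param duplicate_rate fraction of cases submitted in >= 2 versions.
#' @param max_versions maximum versions per duplicated case (>= 2).
#' @param missing named numeric: per-field missingness for `age`, `sex`,
#'   `country`.
#' @param pts_per_report probability vector over 1..6 distinct event draws
#'   per report.
#' @param female_share probability a report's patient is female.
#' @return list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_reports = 20000L,
                             quarter_start = "2015Q1",
                             quarter_end = "2019Q4",
                             drugs = data.frame(name = "drugx",
                                                start_quarter = "2015Q1",
                                                share = 0.02),
                             n_background = 10L,
                             events = default_events(),
                             planted = NULL,
                             duplicate_rate = 0.10,
                             max_versions = 3L,
                             missing = c(age = 0.30, sex = 0.12,
                                         country = 0.05),
                             pts_per_report = c(0.35, 0.30, 0.15, 0.10,
                                                0.06, 0.04),
                             female_share = 0.55) {
  rng <- quarter_range(quarter_start, quarter_end)
  drugs <- as.data.frame(drugs)
  stopifnot(all(c("name", "start_quarter", "share") %in% names(drugs)))
  if (sum(drugs$share) > 1 + 1e-12) {
    stop("drug shares must sum to <= 1", call. = FALSE)
  }
  events <- as.data.frame(events)
  stopifnot(all(c("pt", "soc", "p") %in% names(events)))
  if (abs(sum(events$p) - 1) > 1e-8) {
    stop("baseline event probabilities must sum to 1", call. = FALSE)
  }
  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    if (!"f_mult" %in% names(planted)) planted$f_mult <- 1
    if (!"m_mult" %in% names(planted)) planted$m_mult <- 1
    stopifnot(all(c("drug", "pt", "rho") %in% names(planted)),
              all(planted$rho > 0),
              all(planted$drug %in% drugs$name),
              all(planted$pt %in% events$pt))
    p0 <- events$p[match(planted$pt, events$pt)]
    peak <- p0 * planted$rho * pmax(planted$f_mult, planted$m_mult)
    if (any(peak >= 0.5)) {
      stop("infeasible config: planted rho * p exceeds the renormalization ",
           "bound (0.5)", call. = FALSE)
    }
  }
  stopifnot(duplicate_rate >= 0, duplicate_rate <= 1, max_versions >= 2,
            all(missing >= 0 & missing <= 1),
            length(pts_per_report) == 6L,
            abs(sum(pts_per_report) - 1) < 1e-8,
            female_share >= 0, female_share <= 1)
  structure(list(seed = as.integer(seed), n_reports = as.integer(n_reports),
                 quarter_range = rng, drugs = drugs,
                 n_background = as.integer(n_background), events = events,
                 planted = planted, duplicate_rate = duplicate_rate,
                 max_versions = as.integer(max_versions), missing = missing,
                 pts_per_report = pts_per_report,
                 female_share = female_share),
            class = "synthetic_config")
}

#' Default baseline event multinomial: 50 PTs over 5 SOCs, Zipf-like
#' @return data.frame(pt, soc, p)
#' @export
default_events <- function() {
  n <- 50L
  w <- 1 / seq_len(n)
  data.frame(pt = sprintf("Synthetic event %02d", seq_len(n)),
             soc = sprintf("Synthetic organ class %d",
                           rep_len(1:5, n)),
             p = w / sum(w))
}

quarter_start_date <- function(quarter) {
  p <- parse_quarter(quarter)
  as.Date(sprintf("%04d-%02d-01", p$year, 3L * (p$q - 1L) + 1L))
}

#' Generate a synthetic FAERS-like corpus
#'
#' Reports are assigned a quarter uniformly within their drug's
#' post-marketing window, a primary-suspect (PS) drug by the configured
#' shares, 0--2 concomitant drugs, and 1--6 distinct preferred terms drawn
#' from the (possibly planted) event multinomial. A configurable fraction of
#' cases is emitted in several versions sharing `caseid` with earlier dates
#' and distinct `primaryid`s; duplicate versions never change clinical
#' content. Output is in the exact dialect [read_quarter()] consumes.
#'
#' @param config a [synthetic_config()].
#' @return list of class `"synthetic_corpus"` with elements
#'   `quarters` (named list of [raw_table_set()]s covering the full range),
#'   `pooled` (the same rows pre-stacked with a `QUARTER` column, as
#'   [stack_quarters()] would return them),
#'   `truth` (class `"synth_truth"`: `reports`, `pairs`, `versions`,
#'   `planted`, `config`), `dict` (identity [synonym_dictionary()] over the
#'   simulated drug names) and `hierarchy` (a [meddra_hierarchy()] over the
#'   simulated events).
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_reports
  rng <- config$quarter_range

  drugs <- config$drugs
  rem <- 1 - sum(drugs$share)
  if (rem > 1e-12 && config$n_background > 0L) {
    bg <- data.frame(name = sprintf("background drug %02d",
                                    seq_len(config$n_background)),
                     start_quarter = rng$start,
                     share = rem / config$n_background)
    drugs <- rbind(drugs, bg)
  }
  drugs$name <- tolower(drugs$name)

  # --- report-level draws -------------------------------------------------
  drug_idx <- sample.int(nrow(drugs), n, replace = TRUE,
                         prob = drugs$share / sum(drugs$share))
  drug <- drugs$name[drug_idx]
  sex_true <- ifelse(stats::runif(n) < config$female_share, "F", "M")
  q_lo <- pmax(quarter_index(drugs$start_quarter[drug_idx]),
               quarter_index(rng$start))
  q_hi <- quarter_index(rng$end)
  qidx <- q_lo + floor(stats::runif(n) * (q_hi - q_lo + 1))
  quarter <- quarter_label(qidx)
  age <- round(pmin(pmax(stats::rnorm(n, 55, 18), 0), 100))
  countries <- c("US", "FR", "KR", "JP", "DE", "GB")
  country <- sample(countries, n, replace = TRUE,
                    prob = c(0.45, 0.12, 0.09, 0.07, 0.05, 0.22))
  occp <- sample(c("MD", "CN", "OT", "PH", "", "LW", "RN"), n,
                 replace = TRUE,
                 prob = c(0.30, 0.25, 0.20, 0.18, 0.05, 0.01, 0.01))
  miss <- config$missing
  age_missing <- stats::runif(n) < miss[["age"]]
  sex_missing <- stats::runif(n) < miss[["sex"]]
  country_missing <- stats::runif(n) < miss[["country"]]
  sex_rec <- ifelse(sex_missing, "UNK", sex_true)

  # --- event draws per (planted-drug, sex) class --------------------------
  k <- sample.int(6L, n, replace = TRUE, prob = config$pts_per_report)
  ev <- config$events
  planted <- config$planted
  planted_drugs <- if (is.null(planted)) character(0) else unique(planted$drug)
  cls_drug <- ifelse(drug %in% planted_drugs, drug, ".bg")
  cls <- paste(cls_drug, ifelse(cls_drug == ".bg", ".", sex_true), sep = "|")
  report_of_draw <- rep.int(seq_len(n), k)
  pt_of_draw <- integer(sum(k))
  for (cl in unique(cls)) {
    in_cls <- cls[report_of_draw] == cl
    p <- ev$p
    parts <- strsplit(cl, "|", fixed = TRUE)[[1]]
    if (parts[1] != ".bg" && !is.null(planted)) {
      rows <- planted[planted$drug == parts[1], , drop = FALSE]
      mult <- if (parts[2] == "F") rows$f_mult else rows$m_mult
      j <- match(rows$pt, ev$pt)
      p[j] <- p[j] * rows$rho * mult
      p <- p / sum(p)
    }
    pt_of_draw[in_cls] <- sample.int(nrow(ev), sum(in_cls),
                                     replace = TRUE, prob = p)
  }
  mentions <- unique(data.table(report = report_of_draw,
                                pt = ev$pt[pt_of_draw]))

  # --- concomitant drugs --------------------------------------------------
  n_con <- sample(0:2, n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  con_report <- rep.int(seq_len(n), n_con)
  con_drug <- drugs$name[sample.int(nrow(drugs), length(con_report),
                                    replace = TRUE,
                                    prob = drugs$share / sum(drugs$share))]
  keep_con <- con_drug != drug[con_report]
  con <- unique(data.table(report = con_report[keep_con],
                           name = con_drug[keep_con]))

  # --- outcomes -----------------------------------------------------------
  k_o <- sample(0:2, n, replace = TRUE, prob = c(0.15, 0.70, 0.15))
  oc_report <- rep.int(seq_len(n), k_o)
  oc_code <- sample(FAERS_OUTCOME_CODES, length(oc_report), replace = TRUE,
                    prob = c(0.10, 0.08, 0.30, 0.03, 0.004, 0.006, 0.48))
  oc <- unique(data.table(report = oc_report, code = oc_code))

  # --- case versions (duplicates) -----------------------------------------
  caseid <- 10000000L + seq_len(n)
  dup <- stats::runif(n) < config$duplicate_rate
  extra <- 2L + floor(stats::runif(n) * (config$max_versions - 1L))
  n_ver <- ifelse(dup, extra, 1L)
  base_off <- 45L + floor(stats::runif(n) * 45)  # day offset in quarter
  qstart <- quarter_start_date(quarter)
  ver_report <- rep.int(seq_len(n), n_ver)
  ver_no <- sequence(n_ver)
  is_last <- ver_no == n_ver[ver_report]
  # earlier versions recede 20 days per step, still within the quarter
  fda <- qstart[ver_report] + base_off[ver_report] -
    20L * (n_ver[ver_report] - ver_no)
  event_dt <- qstart[ver_report] + pmax(base_off[ver_report] - 60L, 0L)
  primaryid <- caseid[ver_report] * 10L + ver_no

  fmt <- function(d) format(d, "%Y%m%d")
  demo <- data.table(
    PRIMARYID = as.character(primaryid),
    CASEID = as.character(caseid[ver_report]),
    CASEVERSION = as.character(ver_no),
    FDA_DT = fmt(fda),
    EVENT_DT = fmt(event_dt),
    AGE = ifelse(age_missing[ver_report], "",
                 as.character(age[ver_report])),
    AGE_COD = ifelse(age_missing[ver_report], "", "YR"),
    SEX = ifelse(sex_missing[ver_report], "", sex_true[ver_report]),
    OCCP_COD = occp[ver_report],
    REPORTER_COUNTRY = ifelse(country_missing[ver_report], "",
                              country[ver_report]),
    OCCR_COUNTRY = ifelse(country_missing[ver_report], "",
                          country[ver_report]),
    report = ver_report
  )
  # child rows replicated for every version of the case
  expand_children <- function(dt) {
    idx <- data.table(report = ver_report, PRIMARYID = as.character(primaryid),
                      CASEID = as.character(caseid[ver_report]))
    merge(idx, dt, by = "report", allow.cartesian = TRUE, sort = FALSE)
  }
  ps_rows <- data.table(report = seq_len(n), name = drug, role = "PS",
                        seq = 1L)
  con_rows <- data.table(report = integer(0), name = character(0),
                         role = character(0), seq = integer(0))
  if (nrow(con)) {
    con_rows <- copy(con)
    con_rows[, role := "C"]
    con_rows[, seq := 1L + seq_len(.N), by = "report"]
  }
  drows <- rbind(ps_rows, con_rows, use.names = TRUE)
  drug_tab <- expand_children(drows)
  drug_tab <- data.table(PRIMARYID = drug_tab$PRIMARYID,
                         CASEID = drug_tab$CASEID,
                         DRUG_SEQ = as.character(drug_tab$seq),
                         ROLE_COD = drug_tab$role,
                         DRUGNAME = toupper(drug_tab$name),
                         report = drug_tab$report)
  reac_tab <- expand_children(mentions)
  reac_tab <- data.table(PRIMARYID = reac_tab$PRIMARYID,
                         CASEID = reac_tab$CASEID, PT = reac_tab$pt,
                         report = reac_tab$report)
  outc_tab <- expand_children(oc)
  outc_tab <- data.table(PRIMARYID = outc_tab$PRIMARYID,
                         CASEID = outc_tab$CASEID, OUTC_COD = outc_tab$code,
                         report = outc_tab$report)

  # --- split by quarter into raw table sets -------------------------------
  all_q <- iterate_quarters(rng)
  demo[, QUARTER := quarter[report]]
  drug_tab[, QUARTER := quarter[report]]
  reac_tab[, QUARTER := quarter[report]]
  outc_tab[, QUARTER := quarter[report]]
  pooled <- list(demo = copy(demo)[, report := NULL],
                 drug = copy(drug_tab)[, report := NULL],
                 reac = copy(reac_tab)[, report := NULL],
                 outc = copy(outc_tab)[, report := NULL])
  quarters <- lapply(all_q, function(qq) {
    strip <- function(dt) {
      out <- dt[dt$QUARTER == qq]
      out[, c("report", "QUARTER") := NULL]
      out
    }
    raw_table_set(qq, strip(demo), strip(drug_tab), strip(reac_tab),
                  strip(outc_tab))
  })
  names(quarters) <- all_q

  # --- ground truth -------------------------------------------------------
  final_pid <- as.character(caseid * 10L + n_ver)
  truth_reports <- data.table(
    caseid = as.character(caseid), primaryid = final_pid, drug = drug,
    sex_true = sex_true, sex = sex_rec,
    age = ifelse(age_missing, NA_real_, age), quarter = quarter,
    n_versions = n_ver)
  truth_pairs <- data.table(primaryid = final_pid[mentions$report],
                            drug = drug[mentions$report],
                            sex = sex_rec[mentions$report],
                            pt = mentions$pt)
  versions <- data.table(caseid = as.character(caseid[ver_report]),
                         primaryid = as.character(primaryid),
                         version = ver_no, fda_dt = fmt(fda))
  truth <- structure(list(reports = truth_reports, pairs = truth_pairs,
                          versions = versions, planted = planted,
                          config = config),
                     class = "synth_truth")
  dict <- synonym_dictionary(toupper(drugs$name), drugs$name)
  hier <- meddra_hierarchy(ev$pt, ev$soc, version_label = "synthetic")
  structure(list(quarters = quarters, pooled = pooled, truth = truth,
                 dict = dict, hierarchy = hier),
            class = "synthetic_corpus")
}

#' Ground-truth contingency table for a (drug, PT) pair
#'
#' Tabulates the generator's own bookkeeping of distinct (report, term)
#' pairs on the deduplicated corpus — an independent cross-check for
#' [build_tables()].
#'
#' @param truth the `truth` element of a [synth_generate()] result.
#' @param drug,pt the pair to tabulate (drug standardized/lower case).
#' @return a [contingency_table()].
#' @export
truth_table <- function(truth, drug, pt) {
  stopifnot(inherits(truth, "synth_truth"))
  pairs <- truth$pairs
  if (nrow(pairs) == 0L) stop("empty corpus", call. = FALSE)
  known_drugs <- unique(truth$reports$drug)
  if (!(drug %in% known_drugs) || !(pt %in% truth$config$events$pt)) {
    stop("unknown (drug, pt) pair: ", drug, " / ", pt, call. = FALSE)
  }
  a <- sum(pairs$drug == drug & pairs$pt == pt)
  b <- sum(pairs$drug == drug) - a
  cc <- sum(pairs$pt == pt) - a
  d <- nrow(pairs) - a - b - cc
  contingency_table(a, b, cc, d)
}

#' Write a synthetic corpus to disk in the FAERS dialect
#'
#' Emits every quarter's four ASCII files plus `synonyms.tsv`,
#' `meddra_hierarchy.tsv` and tab-separated ground-truth sidecars
#' (`truth_reports.tsv`, `truth_pairs.tsv`, `truth_versions.tsv`).
#'
#' @param synth a [synth_generate()] result.
#' @param directory target directory.
#' @return invisibly, the directory.
#' @export
write_synthetic <- function(synth, directory) {
  stopifnot(inherits(synth, "synthetic_corpus"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  for (q in names(synth$quarters)) write_quarter(synth$quarters[[q]], directory)
  dict <- synth$dict
  writeLines(paste(names(dict), unname(dict), sep = "\t"),
             file.path(directory, "synonyms.tsv"))
  h <- synth$hierarchy$pt_to_soc
  writeLines(c("pt\tsoc", paste(names(h), unname(h), sep = "\t")),
             file.path(directory, "meddra_hierarchy.tsv"))
  fwrite(synth$truth$reports, file.path(directory, "truth_reports.tsv"),
         sep = "\t")
  fwrite(synth$truth$pairs, file.path(directory, "truth_pairs.tsv"),
         sep = "\t")
  fwrite(synth$truth$versions, file.path(directory, "truth_versions.tsv"),
         sep = "\t")
  invisible(directory)
}
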