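table1_counts <- function(drug_name) {
  path <- system.file("extdata", "nk1ra_table1_counts.tsv",
                      package = "faersignal")
  counts <- data.table::fread(path, sep = "\t")
  counts[counts$drug == drug_name, ]
}

test_that("published female share reproduces from printed counts", {
  reports <- reports_from_marginals(table1_counts("aprepitant"))
  expect_identical(nrow(reports), 3904L)
  s <- summarize_demographics(reports, drug = "aprepitant")
  expect_equal(s[s$section == "sex" & s$category == "Female", ]$pct, 53.46)
  expect_equal(s[s$section == "sex" & s$category == "Male", ]$pct, 32.68)
})

test_that("outcome percentages use the outcome-entry denominator", {
  s <- summarize_demographics(reports_from_marginals(
    table1_counts("aprepitant")))
  death <- s[s$section == "outcomes" & s$category == "Death", ]
  expect_identical(death$count, 366L)
  expect_equal(death$pct, 10.61)  # 366/3449, not 366/3904
})

test_that("degenerate cohorts summarize sanely", {
  one_sex <- data.table::data.table(
    primaryid = c("1", "2"), caseid = c("1", "2"), age_years = c(50, NA),
    sex = c("F", "F"), reporter = "physician", country = "US",
    quarter = "2020Q1", outcomes = list("HO", NULL))
  s <- summarize_demographics(one_sex)
  expect_equal(s[s$section == "sex" & s$category == "Female", ]$pct, 100)
  expect_equal(s[s$section == "outcomes", ]$pct, c(100, 0, 0, 0, 0, 0, 0))
  expect_warning(summarize_demographics(one_sex[0]), "no reports")
})

test_that("every percentage satisfies the stated denominator rules", {
  for (drg in c("aprepitant", "fosaprepitant", "netupitant")) {
    reports <- reports_from_marginals(table1_counts(drg))
    s <- summarize_demographics(reports, drug = drg)
    n <- nrow(reports)
    n_entries <- sum(s[s$section == "outcomes", ]$count)
    for (i in seq_len(nrow(s))) {
      denom <- if (s$section[i] == "outcomes") n_entries else n
      expect_equal(s$pct[i], floor(100 * s$count[i] / denom * 100 + 0.5) / 100,
                   label = paste(drg, s$section[i], s$category[i]))
    }
    # age, sex sections account for every report
    expect_identical(sum(s[s$section == "age", ]$count), n)
    expect_identical(sum(s[s$section == "sex", ]$count), n)
  }
})

test_that("quarter_series zero-fills and conserves report totals", {
  reports <- data.table::data.table(
    primaryid = as.character(1:5), caseid = as.character(1:5),
    age_years = 50, sex = "F", reporter = "physician", country = "US",
    quarter = c("2017Q3", "2017Q3", "2017Q3", "2018Q1", "2017Q3"),
    outcomes = list(NULL, NULL, NULL, NULL, NULL))
  qs <- quarter_series(reports, quarter_range("2017Q1", "2018Q2"))
  expect_identical(qs$count, c(0L, 0L, 4L, 0L, 1L, 0L))
  expect_identical(sum(qs$count), nrow(reports))
})

test_that("quarter_series matches the generator's per-quarter bookkeeping", {
  cfg <- synthetic_config(seed = 17, n_reports = 800)
  s <- synth_generate(cfg)
  demo <- deduplicate(s$pooled$demo)
  corpus <- assemble(demo, s$pooled$drug, s$pooled$reac, s$pooled$outc,
                     s$dict, all_demo_ids = unique(s$pooled$demo$PRIMARYID))
  ids <- corpus$drugs$primaryid[corpus$drugs$role == "PS" &
                                  corpus$drugs$standard_name == "drugx"]
  cohort <- corpus$reports[corpus$reports$primaryid %in% ids, ]
  qs <- quarter_series(cohort, cfg$quarter_range, drug = "drugx")
  truth <- s$truth$reports[s$truth$reports$drug == "drugx", ]
  want <- table(factor(truth$quarter, levels = qs$quarter))
  expect_identical(qs$count, as.integer(want))
})

test_that("sex strata partition the pooled table cellwise", {
  cfg <- synthetic_config(
    seed = 23, n_reports = 3000,
    planted = data.frame(drug = "drugx", pt = "Synthetic event 12",
                         rho = 6, f_mult = 2, m_mult = 0.5))
  s <- synth_generate(cfg)
  demo <- deduplicate(s$pooled$demo)
  corpus <- assemble(demo, s$pooled$drug, s$pooled$reac, s$pooled$outc,
                     s$dict, all_demo_ids = unique(s$pooled$demo$PRIMARYID))
  pooled <- build_tables(corpus, "drugx", "PT")
  by_sex <- lapply(c("F", "M", "UNK"), function(sx) {
    sub <- subset_corpus(corpus,
                         corpus$reports$primaryid[corpus$reports$sex == sx])
    suppressWarnings(build_tables(sub, "drugx", "PT", terms = pooled$term))
  })
  for (term in pooled$term) {
    cells <- sapply(by_sex, function(tb) {
      x <- tb[tb$term == term, ]
      if (nrow(x)) c(x$a, x$b, x$c, x$d) else c(0L, 0L, 0L, 0L)
    })
    p <- pooled[pooled$term == term, ]
    expect_identical(rowSums(cells), as.numeric(c(p$a, p$b, p$c, p$d)),
                     label = term)
  }
})

test_that("a female-only event shows up only in the F stratum", {
  demo <- data.frame(PRIMARYID = c("1", "2"), CASEID = c("1", "2"),
                     FDA_DT = "20200101", SEX = c("F", "M"),
                     QUARTER = "2020Q1")
  drug <- data.frame(PRIMARYID = c("1", "2"), ROLE_COD = "PS",
                     DRUGNAME = "X", DRUG_SEQ = "1")
  reac <- data.frame(PRIMARYID = c("1", "2"), PT = c("Flushing", "Nausea"))
  outc <- data.frame(PRIMARYID = character(0), OUTC_COD = character(0))
  corpus <- assemble(deduplicate(demo), drug, reac, outc,
                     synonym_dictionary("X", "x"))
  th <- signal_thresholds(min_a = 1)
  res <- sex_stratified_signals(corpus, "x", th)
  f <- res[res$stratum == "F", ]
  expect_true("Flushing" %in% f$term)
  m <- res[res$stratum == "M", ]
  expect_false("Flushing" %in% m$term[m$a > 0])
})
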