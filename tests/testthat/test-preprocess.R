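test_that("deduplicate keeps the latest version per case", {
  demo <- data.frame(PRIMARYID = c("1", "2"), CASEID = c("7", "7"),
                     FDA_DT = c("20230101", "20230301"))
  out <- deduplicate(demo)
  expect_identical(out$PRIMARYID, "2")

  one <- deduplicate(demo[1, ])
  expect_identical(one$PRIMARYID, "1")

  # tie on date -> larger numeric primaryid wins
  tie <- data.frame(PRIMARYID = c("10", "9"), CASEID = c("7", "7"),
                    FDA_DT = c("20230301", "20230301"))
  expect_identical(deduplicate(tie)$PRIMARYID, "10")
})

test_that("deduplicate: brute-force max per group, idempotence, cardinality", {
  for (seed in c(1, 2, 3)) {
    demo <- random_demo_versions(seed)
    out <- deduplicate(demo)
    # independent oracle: split by case, pick lexicographic (date, pid) max
    expected <- do.call(rbind, lapply(split(demo, demo$CASEID), function(g) {
      g[order(as.numeric(g$FDA_DT), as.numeric(g$PRIMARYID)), ][nrow(g), ]
    }))
    expected <- expected[order(expected$CASEID), ]
    expect_identical(out$PRIMARYID, expected$PRIMARYID)
    expect_identical(nrow(out), length(unique(demo$CASEID)))
    again <- deduplicate(out)
    expect_identical(as.data.frame(again), as.data.frame(out))
  }
})

test_that("rows without caseid go to the rejects, not the floor", {
  demo <- data.frame(PRIMARYID = c("1", "2", "3"),
                     CASEID = c("7", "", "8"),
                     FDA_DT = c("20230101", "20230201", "20230301"))
  out <- deduplicate(demo)
  expect_identical(sort(out$CASEID), c("7", "8"))
  expect_identical(attr(out, "rejects")$PRIMARYID, "2")
})

test_that("clean_age converts unit codes and censors anomalies", {
  expect_equal(clean_age("65", "YR"), 65)
  expect_equal(clean_age("6", "DEC"), 60)
  expect_true(is.na(clean_age("250", "YR")))
  expect_true(is.na(clean_age("junk", "YR")))
  expect_true(is.na(clean_age("5", "NOPE")))
  expect_equal(clean_age("18", "MON"), 1.5)
  expect_equal(clean_age("45", ""), 45)  # blank code treated as years

  # unit consistency: v months == v/12 years
  v <- seq(0, 1440, by = 37)
  expect_equal(clean_age(as.character(v), "MON"),
               clean_age(as.character(v / 12), "YR"), tolerance = 1e-9)
})

test_that("age_band boundaries follow the stated convention", {
  expect_identical(age_band(c(64.9, 75, 17.99, 18, 45, 65, 0, NA)),
                   c("45-65", ">=75", "<18", "18-45", "45-65", "65-75",
                     "<18", "Unknown"))
})

test_that("standardize_drug normalizes, strips dose tokens, flags misses", {
  dict <- tiny_dict()
  expect_identical(standardize_drug("EMEND", dict), "aprepitant")
  expect_identical(standardize_drug("aprepitant", dict), "aprepitant")
  expect_identical(standardize_drug("Aprepitant 125 MG", dict), "aprepitant")
  expect_identical(standardize_drug("  EMEND. ", dict), "aprepitant")
  expect_identical(standardize_drug("MYSTERYDRUG", dict), "UNMAPPED")
})

test_that("assemble enforces referential integrity and rejects orphans", {
  raw <- stack_quarters(list(tiny_rts()))
  # a drug row for a primaryid never seen in DEMO -> orphan
  drug <- rbind(raw$drug,
                data.frame(PRIMARYID = "999", CASEID = "99", DRUG_SEQ = "1",
                           ROLE_COD = "PS", DRUGNAME = "EMEND",
                           QUARTER = "2017Q3"))
  demo <- deduplicate(raw$demo)
  corpus <- assemble(demo, drug, raw$reac, raw$outc, tiny_dict())
  expect_identical(nrow(corpus$rejects$drug_orphans), 1L)
  expect_true(all(corpus$drugs$primaryid %in% corpus$reports$primaryid))
  expect_identical(nrow(corpus$reports), 2L)
  expect_identical(nrow(corpus$drugs), 2L)  # orphan excluded

  # duplicate-version children are dropped silently, not counted as orphans
  demo2 <- rbind(raw$demo,
                 data.frame(PRIMARYID = "103", CASEID = "11",
                            FDA_DT = "20170901", AGE = "65", AGE_COD = "YR",
                            SEX = "F", OCCP_COD = "MD", OCCR_COUNTRY = "US",
                            REPORTER_COUNTRY = "US", QUARTER = "2017Q3"),
                 fill = TRUE)
  surv <- deduplicate(demo2)
  corpus2 <- assemble(surv, raw$drug, raw$reac, raw$outc, tiny_dict(),
                      all_demo_ids = unique(demo2$PRIMARYID))
  expect_identical(nrow(corpus2$rejects$drug_orphans), 0L)
  # report 101 lost to the newer version 103, its mentions excluded
  expect_false("101" %in% corpus2$drugs$primaryid)
})

test_that("assemble never increases row counts and builds case fields", {
  corpus <- tiny_corpus()
  raw <- stack_quarters(list(tiny_rts()))
  expect_lte(nrow(corpus$drugs), nrow(raw$drug))
  expect_lte(nrow(corpus$reactions), nrow(raw$reac))
  expect_lte(nrow(corpus$outcomes), nrow(raw$outc))
  r <- corpus$reports
  expect_identical(r$sex, c("F", "M"))
  expect_identical(r$reporter, c("physician", "consumer"))
  expect_identical(r$country, c("US", "FR"))  # fallback to REPORTER_COUNTRY
  expect_equal(r$age_years, c(65, NA))
  expect_identical(r$outcomes[[1]], "HO")
})
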