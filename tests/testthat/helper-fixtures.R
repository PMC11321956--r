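# Shared fixtures, built in code.

# A minimal two-report quarter: report 101 has aprepitant as primary
# suspect with Hiccups; report 102 has another drug with Nausea.
tiny_rts <- function() {
  demo <- data.frame(
    PRIMARYID = c("101", "102"),
    CASEID = c("11", "12"),
    FDA_DT = c("20170801", "20170815"),
    AGE = c("65", ""),
    AGE_COD = c("YR", ""),
    SEX = c("F", "M"),
    OCCP_COD = c("MD", "CN"),
    OCCR_COUNTRY = c("US", ""),
    REPORTER_COUNTRY = c("US", "FR")
  )
  drug <- data.frame(
    PRIMARYID = c("101", "102"),
    CASEID = c("11", "12"),
    DRUG_SEQ = c("1", "1"),
    ROLE_COD = c("PS", "PS"),
    DRUGNAME = c("EMEND", "OTHERDRUG")
  )
  reac <- data.frame(
    PRIMARYID = c("101", "102"),
    CASEID = c("11", "12"),
    PT = c("Hiccups", "Nausea")
  )
  outc <- data.frame(
    PRIMARYID = c("101", "102"),
    CASEID = c("11", "12"),
    OUTC_COD = c("HO", "DE")
  )
  raw_table_set("2017Q3", demo, drug, reac, outc)
}

tiny_dict <- function() {
  synonym_dictionary(c("EMEND", "APREPITANT", "OTHERDRUG"),
                     c("aprepitant", "aprepitant", "otherdrug"))
}

tiny_corpus <- function() {
  raw <- stack_quarters(list(tiny_rts()))
  demo <- deduplicate(raw$demo)
  assemble(demo, raw$drug, raw$reac, raw$outc, tiny_dict())
}

fixture_hierarchy_path <- function() {
  system.file("extdata", "nk1ra_meddra_subset.tsv", package = "faersignal")
}

# Random raw table set with arbitrary printable fields (no "$").
random_rts <- function(seed, n = 8) {
  set.seed(seed)
  rand_field <- function(n) {
    vapply(seq_len(n), function(i) {
      chars <- c(letters, LETTERS, 0:9, " ", "-", ".", ",", ";", "'")
      paste(sample(chars, sample(0:12, 1), replace = TRUE), collapse = "")
    }, "")
  }
  demo <- data.frame(PRIMARYID = as.character(seq_len(n)),
                     CASEID = as.character(100 + seq_len(n)),
                     FDA_DT = rand_field(n), FREETEXT = rand_field(n))
  drug <- data.frame(PRIMARYID = as.character(seq_len(n)),
                     DRUGNAME = rand_field(n), ROLE_COD = rand_field(n))
  reac <- data.frame(PRIMARYID = as.character(seq_len(n)),
                     PT = rand_field(n))
  outc <- data.frame(PRIMARYID = as.character(seq_len(n)),
                     OUTC_COD = rand_field(n))
  raw_table_set("2019Q2", demo, drug, reac, outc)
}

# Shuffled DEMO rows for dedup tests: n_cases cases, 1..max_versions
# versions each; the intended survivor is the highest version.
random_demo_versions <- function(seed, n_cases = 50, max_versions = 5) {
  set.seed(seed)
  n_ver <- sample.int(max_versions, n_cases, replace = TRUE)
  caseid <- rep(sprintf("c%04d", seq_len(n_cases)), n_ver)
  ver <- sequence(n_ver)
  demo <- data.frame(
    PRIMARYID = as.character(seq_along(caseid) * 7L),
    CASEID = caseid,
    FDA_DT = sprintf("%d", 20200101L + ver * 100L),
    PAYLOAD = sprintf("v%d", ver)
  )
  demo[sample.int(nrow(demo)), ]
}
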