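# Case-level cleaning: deduplication, demographics, drug-name standardization.

FAERS_OUTCOME_CODES <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
FAERS_ROLE_CODES <- c("PS", "SS", "C", "I")

REPORTER_MAP <- c(MD = "physician", PH = "pharmacist",
                  OT = "other-health-professional", CN = "consumer",
                  LW = "lawyer", RN = "registered-nurse")

#' Deduplicate DEMO rows: one surviving version per case
#'
#' FAERS cases are resubmitted as follow-ups; all versions share `CASEID`.
#' Only the latest report per case is retained, judged by `FDA_DT` (receipt
#' date, always populated), ties broken by the larger numeric `PRIMARYID`.
#' Rows with a blank/absent `CASEID` are routed to a rejects table, never
#' silently dropped.
#'
#' The function maps surviving raw rows to surviving raw rows, so it is
#' idempotent: `deduplicate(deduplicate(x))` equals `deduplicate(x)`.
#'
#' @param demo data.table of raw DEMO rows (character columns, upper-case
#'   names, `PRIMARYID`/`CASEID`/`FDA_DT` present).
#' @return the surviving DEMO rows, sorted by `CASEID`, with the rejected
#'   rows attached as `attr(, "rejects")`.
#' @export
deduplicate <- function(demo) {
  demo <- as.data.table(demo)
  if (!all(c("CASEID", "FDA_DT", "PRIMARYID") %in% names(demo))) {
    stop("DEMO rows must carry PRIMARYID, CASEID and FDA_DT", call. = FALSE)
  }
  bad <- is.na(demo$CASEID) | demo$CASEID == ""
  rejects <- demo[bad]
  keep <- demo[!bad]
  # subsetting copies custom attributes; drop any stale rejects attr so
  # deduplicate(deduplicate(x)) is exactly deduplicate(x)
  setattr(rejects, "rejects", NULL)
  setattr(keep, "rejects", NULL)
  if (nrow(keep)) {
    fda <- suppressWarnings(as.numeric(keep$FDA_DT))
    fda[is.na(fda)] <- -Inf
    pid <- suppressWarnings(as.numeric(keep$PRIMARYID))
    pid[is.na(pid)] <- -Inf
    keep <- keep[order(keep$CASEID, -fda, -pid)]
    keep <- keep[!duplicated(keep$CASEID)]
    keep <- keep[order(keep$CASEID)]
  }
  setattr(keep, "rejects", rejects)
  keep[]
}

#' Convert a raw age to years
#'
#' FAERS ages carry a unit code: `DEC` (decades), `YR`, `MON`, `WK`, `DY`,
#' `HR`; blank codes are taken as years. Unparsable values, unknown codes and
#' results outside \[0, 120\] years become missing (`NA`), so anomalies are
#' censored rather than propagated.
#'
#' @param raw_age character vector of raw AGE field values.
#' @param age_code character vector of AGE_COD values, recycled if length 1.
#' @return numeric vector of ages in years, `NA` where missing/anomalous.
#' @export
clean_age <- function(raw_age, age_code = "YR") {
  if (length(age_code) == 1L) age_code <- rep(age_code, length(raw_age))
  stopifnot(length(age_code) == length(raw_age))
  v <- suppressWarnings(as.numeric(raw_age))
  code <- toupper(trimws(age_code))
  code[is.na(code) | code == ""] <- "YR"
  factor_map <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.143,
                  DY = 1 / 365.25, HR = 1 / 8766)
  f <- factor_map[code]
  age <- v * f
  age[is.na(age) | age < 0 | age > 120] <- NA_real_
  unname(age)
}

#' Assign an age band
#'
#' Bands follow the conventional pharmacovigilance grouping: `[0,18)`,
#' `[18,45)`, `[45,65)`, `[65,75)`, `[75,Inf)`; missing ages go to
#' `"Unknown"`.
#'
#' @param age_years numeric vector of ages in years (NA = missing).
#' @return character vector over `{"<18","18-45","45-65","65-75",">=75","Unknown"}`.
#' @export
age_band <- function(age_years) {
  bands <- as.character(cut(age_years,
                            breaks = c(0, 18, 45, 65, 75, Inf),
                            labels = c("<18", "18-45", "45-65", "65-75", ">=75"),
                            right = FALSE, include.lowest = TRUE))
  bands[is.na(bands)] <- "Unknown"
  bands
}

AGE_BANDS <- c("<18", "18-45", "45-65", "65-75", ">=75", "Unknown")

normalize_drug_name <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:punct:]]", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Load a drug synonym dictionary
#'
#' Two-column tab-separated file mapping verbatim drug names to standardized
#' generic names; lines starting with `#` are comments. Keys are normalized
#' (case-folded, punctuation stripped, whitespace collapsed) on load.
#'
#' @param path path to the dictionary file.
#' @return an object of class `"synonym_dictionary"`: a named character
#'   vector, normalized verbatim -> standard generic name (lower case).
#' @export
load_synonyms <- function(path) {
  lines <- readLines(path, encoding = "latin1", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(structure(character(0), class = "synonym_dictionary"))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) {
    stop("malformed synonym line(s): ", paste(lines[bad], collapse = "; "),
         call. = FALSE)
  }
  keys <- normalize_drug_name(vapply(parts, `[`, "", 1L))
  vals <- tolower(trimws(vapply(parts, `[`, "", 2L)))
  if (any(!nzchar(vals))) stop("empty standard name in dictionary", call. = FALSE)
  dict <- vals[!duplicated(keys)]
  names(dict) <- keys[!duplicated(keys)]
  structure(dict, class = "synonym_dictionary")
}

#' Build a synonym dictionary from vectors (mostly for tests/simulation)
#' @param verbatim,standard character vectors of equal length.
#' @return a `"synonym_dictionary"`.
#' @export
synonym_dictionary <- function(verbatim, standard) {
  stopifnot(length(verbatim) == length(standard), all(nzchar(standard)))
  dict <- tolower(trimws(standard))
  names(dict) <- normalize_drug_name(verbatim)
  structure(dict, class = "synonym_dictionary")
}

# Tokens dropped on the second lookup attempt: doses and routes.
DOSE_ROUTE_TOKENS <- c("mg", "ml", "tablet", "tablets", "capsule", "capsules",
                       "injection", "oral", "iv")

#' Standardize a verbatim drug name against the dictionary
#'
#' Lookup is on the normalized form (case-folded, punctuation stripped,
#' whitespace collapsed). If that misses, dose/route suffix tokens (pure
#' numbers, `MG`, `ML`, `TABLET`, `INJECTION`, ...) are stripped and the
#' lookup retried. Names still unmapped return `"UNMAPPED"`.
#'
#' @param verbatim character vector of verbatim drug names.
#' @param dict a [synonym_dictionary()] / [load_synonyms()] object.
#' @return character vector of standard names (lower case) or `"UNMAPPED"`.
#' @export
standardize_drug <- function(verbatim, dict) {
  key <- normalize_drug_name(verbatim)
  hit <- unname(dict[key])
  miss <- is.na(hit)
  if (any(miss)) {
    stripped <- vapply(strsplit(key[miss], " ", fixed = TRUE), function(tok) {
      tok <- tok[!(grepl("^[0-9.]+$", tok) | tok %in% DOSE_ROUTE_TOKENS)]
      paste(tok, collapse = " ")
    }, "")
    hit2 <- unname(dict[stripped])
    hit[miss] <- hit2
  }
  hit[is.na(hit)] <- "UNMAPPED"
  hit
}

#' Build clean case reports from surviving DEMO rows
#'
#' Maps the raw DEMO fields of deduplicated rows into the canonical
#' per-report data model: age in years (cleaned), sex in `{F, M, UNK}`,
#' reporter occupation category, country (`OCCR_COUNTRY` falling back to
#' `REPORTER_COUNTRY`), and the source quarter.
#'
#' @param demo surviving DEMO rows as returned by [deduplicate()]; must
#'   carry a `QUARTER` column (see [stack_quarters()]).
#' @return data.table with columns `primaryid`, `caseid`, `fda_date`,
#'   `event_date`, `age_years`, `sex`, `reporter`, `country`, `quarter`.
#' @export
case_reports <- function(demo) {
  demo <- as.data.table(demo)
  getcol <- function(nm) {
    if (nm %in% names(demo)) demo[[nm]] else rep("", nrow(demo))
  }
  sex <- toupper(trimws(getcol("SEX")))
  sex[!(sex %in% c("F", "M"))] <- "UNK"
  occp <- toupper(trimws(getcol("OCCP_COD")))
  reporter <- unname(REPORTER_MAP[occp])
  reporter[is.na(reporter)] <- "unknown"
  country <- trimws(getcol("OCCR_COUNTRY"))
  fallback <- trimws(getcol("REPORTER_COUNTRY"))
  country[country == ""] <- fallback[country == ""]
  country[country == ""] <- "UNK"
  data.table(
    primaryid = getcol("PRIMARYID"),
    caseid = getcol("CASEID"),
    fda_date = getcol("FDA_DT"),
    event_date = getcol("EVENT_DT"),
    age_years = clean_age(getcol("AGE"), getcol("AGE_COD")),
    sex = sex,
    reporter = reporter,
    country = country,
    quarter = getcol("QUARTER")
  )
}

#' Assemble the canonical per-report corpus
#'
#' Restricts DRUG/REAC/OUTC rows to the primaryids surviving deduplication,
#' standardizes drug names, and enforces referential integrity. Mentions
#' whose primaryid never appeared in DEMO at all are orphans and are routed
#' to the rejects list with counts; mentions of non-surviving duplicate
#' versions are simply excluded.
#'
#' @param demo surviving DEMO rows (from [deduplicate()]), with `QUARTER`.
#' @param drug,reac,outc raw tables (from [stack_quarters()]).
#' @param dict a synonym dictionary for [standardize_drug()].
#' @param all_demo_ids primaryids present in DEMO before deduplication; used
#'   to tell true orphans from children of dropped duplicate versions.
#'   Defaults to the surviving ids (every non-surviving mention then counts
#'   as an orphan).
#' @return an object of class `"faers_corpus"`: list with `reports`
#'   (case-report table, incl. list-column `outcomes`), `drugs`
#'   (primaryid, seq, role, verbatim_name, standard_name), `reactions`
#'   (primaryid, pt), `outcomes` (primaryid, code) and `rejects` (named list
#'   of reject tables with an orphan count per table).
#' @export
assemble <- function(demo, drug, reac, outc, dict,
                     all_demo_ids = unique(demo$PRIMARYID)) {
  demo <- as.data.table(demo)
  drug <- as.data.table(drug); reac <- as.data.table(reac)
  outc <- as.data.table(outc)
  surviving <- unique(demo$PRIMARYID)  # demo is already deduplicated
  rejects <- list()

  restrict <- function(dt, nm) {
    orphan <- !(dt$PRIMARYID %chin% all_demo_ids)
    rejects[[nm]] <<- dt[orphan]
    dt[dt$PRIMARYID %chin% surviving]
  }
  drug <- restrict(drug, "drug_orphans")
  reac <- restrict(reac, "reac_orphans")
  outc <- restrict(outc, "outc_orphans")

  reports <- case_reports(demo)

  getcol <- function(dt, nm, default = "") {
    if (nm %in% names(dt)) dt[[nm]] else rep(default, nrow(dt))
  }
  role <- toupper(trimws(getcol(drug, "ROLE_COD")))
  role[!(role %in% FAERS_ROLE_CODES)] <- NA_character_
  drugs <- data.table(
    primaryid = drug$PRIMARYID,
    seq = suppressWarnings(as.integer(getcol(drug, "DRUG_SEQ", "0"))),
    role = role,
    verbatim_name = getcol(drug, "DRUGNAME"),
    standard_name = standardize_drug(getcol(drug, "DRUGNAME"), dict)
  )
  reactions <- data.table(primaryid = reac$PRIMARYID,
                          pt = trimws(getcol(reac, "PT")))
  reactions <- reactions[nzchar(reactions$pt)]
  code <- toupper(trimws(getcol(outc, "OUTC_COD")))
  outcomes <- data.table(primaryid = outc$PRIMARYID, code = code)
  outcomes <- outcomes[outcomes$code %chin% FAERS_OUTCOME_CODES]

  oc <- outcomes[, list(codes = list(sort(unique(code)))), by = "primaryid"]
  reports <- merge(reports, oc, by = "primaryid", all.x = TRUE, sort = FALSE)
  setnames(reports, "codes", "outcomes")
  setorderv(reports, "caseid")

  structure(list(reports = reports, drugs = drugs, reactions = reactions,
                 outcomes = outcomes, rejects = rejects),
            class = "faers_corpus")
}

#' @export
print.faers_corpus <- function(x, ...) {
  cat("<faers_corpus>", nrow(x$reports), "reports,",
      nrow(x$drugs), "drug mentions,", nrow(x$reactions), "reactions,",
      nrow(x$outcomes), "outcome entries\n")
  n_orph <- sum(vapply(x$rejects, nrow, 0L))
  if (n_orph) cat("  orphan mentions rejected:", n_orph, "\n")
  invisible(x)
}
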