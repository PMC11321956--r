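#' @importFrom data.table data.table fread fwrite setnames setcolorder :=
#'   .N .SD rbindlist as.data.table setorder setorderv copy fifelse %chin%
#'   setattr
NULL

# The four quarterly member tables of a FAERS ASCII release used here.
FAERS_TABLES <- c("demo", "drug", "reac", "outc")

faers_file_name <- function(table, quarter) {
  p <- parse_quarter(quarter)
  sprintf("%s%02dQ%d.txt", toupper(table), p$year %% 100L, p$q)
}

# Legacy (pre-2012 ISR-era) column shim: ISR -> PRIMARYID, CASE -> CASEID.
# All other legacy columns pass through unchanged.
apply_legacy_shim <- function(dt) {
  nm <- names(dt)
  nm[nm == "ISR"] <- "PRIMARYID"
  nm[nm == "CASE"] <- "CASEID"
  setnames(dt, nm)
  dt
}

#' A raw FAERS quarter: the four member tables
#'
#' Container for one quarter's DEMO/DRUG/REAC/OUTC tables as read from the
#' `$`-delimited ASCII dialect. All fields are character; empty strings mark
#' missing values. Column names are upper-cased; the legacy `ISR`/`CASE`
#' columns are renamed to `PRIMARYID`/`CASEID`.
#'
#' @param quarter quarter label (`"YYYYQq"`).
#' @param demo,drug,reac,outc data.frames (coerced to data.table) of raw
#'   rows; may be empty but must carry a `PRIMARYID` column.
#' @return an object of class `"raw_table_set"`: a list with elements
#'   `quarter`, `demo`, `drug`, `reac`, `outc`.
#' @export
raw_table_set <- function(quarter, demo, drug, reac, outc) {
  parse_quarter(quarter)
  tabs <- list(demo = demo, drug = drug, reac = reac, outc = outc)
  tabs <- lapply(tabs, function(x) {
    x <- as.data.table(x)
    setnames(x, toupper(names(x)))
    apply_legacy_shim(x)
    if (!"PRIMARYID" %in% names(x)) {
      stop("malformed table: no primaryid column", call. = FALSE)
    }
    for (j in names(x)) {
      if (!is.character(x[[j]])) x[[j]] <- as.character(x[[j]])
    }
    x
  })
  structure(c(list(quarter = quarter), tabs), class = "raw_table_set")
}

#' @export
print.raw_table_set <- function(x, ...) {
  cat("<raw_table_set>", x$quarter, "-",
      paste(sprintf("%s:%d", FAERS_TABLES,
                    vapply(x[FAERS_TABLES], nrow, 0L)), collapse = " "),
      "\n")
  invisible(x)
}

read_faers_file <- function(path) {
  dt <- fread(path, sep = "$", header = TRUE, colClasses = "character",
              quote = "", na.strings = NULL, encoding = "Latin-1",
              fill = TRUE, blank.lines.skip = FALSE, strip.white = FALSE)
  setnames(dt, toupper(names(dt)))
  apply_legacy_shim(dt)
  if (!"PRIMARYID" %in% names(dt)) {
    stop("malformed header in ", basename(path),
         ": no primaryid (or legacy ISR) column", call. = FALSE)
  }
  for (j in names(dt)) {
    if (!is.character(dt[[j]])) dt[[j]] <- as.character(dt[[j]])
    if (anyNA(dt[[j]])) dt[is.na(dt[[j]]), (j) := ""]
  }
  dt
}

#' Read one FAERS quarter from disk
#'
#' Expects the four files `DEMOyyQq.txt`, `DRUGyyQq.txt`, `REACyyQq.txt`,
#' `OUTCyyQq.txt` in `directory`: `$`-delimited, first line the header.
#' Fields are read as character with Latin-1 decoding; empty strings are
#' preserved as the missing marker. A missing file is an error (silent gaps
#' would bias downstream time series).
#'
#' @param directory path containing the quarter's files.
#' @param quarter quarter label (`"YYYYQq"`).
#' @return a [raw_table_set()].
#' @export
read_quarter <- function(directory, quarter) {
  parse_quarter(quarter)
  tabs <- list()
  for (tb in FAERS_TABLES) {
    fn <- faers_file_name(tb, quarter)
    path <- file.path(directory, fn)
    if (!file.exists(path)) {
      stop("table absent: expected file ", fn, " for quarter ", quarter,
           " in ", directory, call. = FALSE)
    }
    tabs[[tb]] <- read_faers_file(path)
  }
  raw_table_set(quarter, tabs$demo, tabs$drug, tabs$reac, tabs$outc)
}

#' Write one FAERS quarter to disk
#'
#' Emits the four `$`-delimited files in the dialect [read_quarter()]
#' consumes; `read_quarter(write_quarter(x))` is the identity on field
#' values. A field containing a literal `$` is unrepresentable in the
#' dialect and is rejected.
#'
#' @param tables a [raw_table_set()].
#' @param directory target directory (created if absent).
#' @return invisibly, the paths of the four files written.
#' @export
write_quarter <- function(tables, directory) {
  stopifnot(inherits(tables, "raw_table_set"))
  if (!dir.exists(directory)) {
    dir.create(directory, recursive = TRUE)
  }
  paths <- character(0)
  for (tb in FAERS_TABLES) {
    dt <- tables[[tb]]
    for (j in names(dt)) {
      if (any(grepl("$", dt[[j]], fixed = TRUE))) {
        stop("dialect error: field ", j, " in ", toupper(tb),
             " contains the '$' delimiter", call. = FALSE)
      }
    }
    path <- file.path(directory, faers_file_name(tb, tables$quarter))
    if (nrow(dt) == 0L) {
      writeLines(paste(names(dt), collapse = "$"), path)
    } else {
      fwrite(dt, path, sep = "$", quote = FALSE, col.names = TRUE)
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Stack several quarters into pooled raw tables
#'
#' Concatenates the member tables of a list of [raw_table_set()]s, adding a
#' `QUARTER` column so each row remembers its source quarter.
#'
#' @param rts_list list of `raw_table_set` objects.
#' @return list with elements `demo`, `drug`, `reac`, `outc` (data.tables).
#' @export
stack_quarters <- function(rts_list) {
  stopifnot(length(rts_list) > 0L,
            all(vapply(rts_list, inherits, TRUE, "raw_table_set")))
  out <- list()
  for (tb in FAERS_TABLES) {
    parts <- lapply(rts_list, function(r) {
      dt <- copy(r[[tb]])
      dt[, QUARTER := r$quarter]
      dt
    })
    out[[tb]] <- rbindlist(parts, use.names = TRUE, fill = TRUE)
  }
  out
}
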