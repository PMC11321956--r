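#' Calendar-quarter labels
#'
#' FAERS data are published one file set per calendar quarter. Quarters are
#' labelled `"YYYYQq"`, e.g. `"2017Q3"`. These helpers parse, validate and
#' enumerate quarter labels.
#'
#' @param x character vector of quarter labels.
#' @return `parse_quarter()` returns a data.frame with columns `year` and
#'   `q`; `quarter_index()` an integer vector suitable for chronological
#'   comparison; `quarter_label()` the inverse of `quarter_index()`.
#' @examples
#' parse_quarter("2017Q3")
#' iterate_quarters("2019Q4", "2020Q2")
#' @name quarters
NULL

#' @rdname quarters
#' @export
parse_quarter <- function(x) {
  ok <- grepl("^[0-9]{4}Q[1-4]$", x)
  if (!all(ok)) {
    stop("invalid quarter label(s): ", paste(x[!ok], collapse = ", "),
         " (expected YYYYQ[1-4])", call. = FALSE)
  }
  data.frame(year = as.integer(substr(x, 1, 4)),
             q    = as.integer(substr(x, 6, 6)))
}

#' @rdname quarters
#' @export
quarter_index <- function(x) {
  p <- parse_quarter(x)
  p$year * 4L + (p$q - 1L)
}

#' @param i integer vector as returned by [quarter_index()].
#' @rdname quarters
#' @export
quarter_label <- function(i) {
  sprintf("%04dQ%d", i %/% 4L, i %% 4L + 1L)
}

#' Inclusive range of calendar quarters
#'
#' Validates a `(start, end)` pair of quarter labels. Both endpoints must lie
#' within 2004Q1--2099Q4 (the modern FAERS era) and `start` must not be after
#' `end`.
#'
#' @param start,end quarter labels (`"YYYYQq"`).
#' @return a list of class `"quarter_range"` with elements `start` and `end`.
#' @export
quarter_range <- function(start, end) {
  is <- quarter_index(start)
  ie <- quarter_index(end)
  lo <- quarter_index("2004Q1")
  hi <- quarter_index("2099Q4")
  if (is < lo || ie > hi) {
    stop("quarter range must lie within 2004Q1..2099Q4", call. = FALSE)
  }
  if (is > ie) {
    stop("invalid quarter range: start ", start, " is after end ", end,
         call. = FALSE)
  }
  structure(list(start = start, end = end), class = "quarter_range")
}

#' Enumerate the quarters of a range, in chronological order
#'
#' @param start a quarter label or a [quarter_range()].
#' @param end a quarter label; ignored when `start` is a `quarter_range`.
#' @return character vector of quarter labels, inclusive of both endpoints.
#'   2004Q1--2023Q4 yields exactly 80 labels.
#' @export
iterate_quarters <- function(start, end = NULL) {
  if (inherits(start, "quarter_range")) {
    r <- start
  } else {
    r <- quarter_range(start, end)
  }
  quarter_label(seq.int(quarter_index(r$start), quarter_index(r$end)))
}
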