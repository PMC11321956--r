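# MedDRA preferred term -> system organ class mapping.
#
# MedDRA itself is licensed and must be supplied by the user as a
# tab-separated table; the package only ships a small fixture covering the
# terms used in its tests.

normalize_pt <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Load a PT -> SOC hierarchy table
#'
#' Tab-separated file with header columns `pt` and `soc` (case-insensitive;
#' extra columns such as `hlt`/`hlgt` are ignored). Each preferred term must
#' map to exactly one primary SOC; duplicate identical rows are collapsed,
#' conflicting rows are an error.
#'
#' @param path path to the hierarchy file.
#' @param version_label free-text label stored on the object.
#' @return an object of class `"meddra_hierarchy"`.
#' @export
load_hierarchy <- function(path, version_label = basename(path)) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
              quote = "", na.strings = NULL)
  setnames(dt, tolower(names(dt)))
  if (!all(c("pt", "soc") %in% names(dt))) {
    stop("hierarchy file must have 'pt' and 'soc' columns", call. = FALSE)
  }
  key <- normalize_pt(dt$pt)
  soc <- trimws(dt$soc)
  dup <- !duplicated(paste(key, soc, sep = "\r"))
  key <- key[dup]; soc <- soc[dup]
  conflict <- key[duplicated(key)]
  if (length(conflict)) {
    stop("hierarchy conflict: PT(s) mapped to more than one SOC: ",
         paste(unique(conflict), collapse = ", "), call. = FALSE)
  }
  map <- soc
  names(map) <- key
  structure(list(pt_to_soc = map, version_label = version_label),
            class = "meddra_hierarchy")
}

#' Build a hierarchy from vectors (tests/simulation)
#' @param pt,soc character vectors of equal length.
#' @param version_label free-text label.
#' @return a `"meddra_hierarchy"`.
#' @export
meddra_hierarchy <- function(pt, soc, version_label = "inline") {
  stopifnot(length(pt) == length(soc))
  key <- normalize_pt(pt)
  if (anyDuplicated(key[!duplicated(paste(key, soc, sep = "\r"))])) {
    stop("hierarchy conflict: a PT maps to more than one SOC", call. = FALSE)
  }
  map <- trimws(soc)[!duplicated(key)]
  names(map) <- key[!duplicated(key)]
  structure(list(pt_to_soc = map, version_label = version_label),
            class = "meddra_hierarchy")
}

#' Look up the system organ class of preferred terms
#'
#' Case-insensitive exact match after whitespace collapsing; no fuzzy
#' matching. Misses return `"UNMAPPED"`.
#'
#' @param pt character vector of preferred terms.
#' @param h a [load_hierarchy()] object.
#' @return character vector of SOC names or `"UNMAPPED"`.
#' @export
soc_of <- function(pt, h) {
  stopifnot(inherits(h, "meddra_hierarchy"))
  hit <- unname(h$pt_to_soc[normalize_pt(pt)])
  hit[is.na(hit)] <- "UNMAPPED"
  hit
}
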