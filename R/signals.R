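# Contingency-table construction and signal evaluation over a corpus.

distinct_pairs <- function(reactions, level, hierarchy) {
  pairs <- unique(reactions[, c("primaryid", "pt"), with = FALSE])
  if (level == "SOC") {
    if (is.null(hierarchy)) {
      stop("SOC-level tables need a MedDRA hierarchy", call. = FALSE)
    }
    pairs[, term := soc_of(pt, hierarchy)]
    pairs <- unique(pairs[, c("primaryid", "term"), with = FALSE])
  } else {
    setnames(pairs, "pt", "term")
  }
  pairs
}

ps_report_ids <- function(corpus, target_drug) {
  d <- corpus$drugs
  unique(d$primaryid[!is.na(d$role) & d$role == "PS" &
                       d$standard_name == tolower(target_drug)])
}

#' Build drug-event 2x2 tables for one target drug
#'
#' The counting unit is the (report, term) pair. A report belongs to the
#' target cohort when the target drug appears on it with role `PS` (primary
#' suspect). For each term: `a` = pairs on target reports mentioning the
#' term, `b` = other pairs on target reports, `c` = pairs with the term on
#' non-target reports, `d` = the rest; `N` = total pairs in the corpus. At
#' `level = "SOC"` each PT is first mapped through the hierarchy and a
#' report contributes at most one pair per SOC; unmapped PTs are kept under
#' the term `"UNMAPPED"` so SOC-level counts conserve PT-level counts.
#'
#' @param corpus a `"faers_corpus"` from [assemble()].
#' @param target_drug standardized drug name.
#' @param level `"PT"` or `"SOC"`.
#' @param hierarchy a [load_hierarchy()] object; required for SOC level,
#'   optional at PT level (adds a `soc` column).
#' @param terms optional character vector imposing the term universe: terms
#'   absent from the corpus get a zero-count row (a = 0, c = 0), so tables
#'   built on corpus partitions stay cellwise summable.
#' @return data.table with columns `term`, `soc` (PT level), `a`, `b`, `c`,
#'   `d`, `N`, one row per term observed anywhere in the corpus (plus any
#'   imposed by `terms`). Empty with a warning when the target drug has no
#'   PS report.
#' @export
build_tables <- function(corpus, target_drug, level = c("PT", "SOC"),
                         hierarchy = NULL, terms = NULL) {
  level <- match.arg(level)
  stopifnot(inherits(corpus, "faers_corpus"))
  pairs <- distinct_pairs(corpus$reactions, level, hierarchy)
  tgt_ids <- ps_report_ids(corpus, target_drug)
  if (!length(tgt_ids)) {
    warning("target drug '", target_drug,
            "' has no primary-suspect report in the corpus")
  }
  pairs[, target := primaryid %chin% tgt_ids]
  N <- nrow(pairs)
  n_target <- sum(pairs$target)
  tab <- pairs[, list(a = sum(target), ac = .N), by = "term"]
  tab[, b := n_target - a]
  tab[, c := ac - a]
  tab[, d := N - a - b - c]
  tab[, ac := NULL]
  tab[, N := N]
  if (!is.null(terms)) {
    absent <- setdiff(terms, tab$term)
    if (length(absent)) {
      tab <- rbind(tab, data.table(term = absent, a = 0L, b = n_target,
                                   c = 0L, d = N - n_target, N = N))
    }
  }
  if (level == "PT" && !is.null(hierarchy)) {
    tab[, soc := soc_of(term, hierarchy)]
    setcolorder(tab, c("term", "soc"))
  }
  setorderv(tab, "term")
  tab[]
}

#' Evaluate signal statistics and threshold flags over built tables
#'
#' Terms with `a < min_a` are excluded before any statistic is computed
#' (initial screening at reported counts >= 3 by default). Each surviving
#' term receives all four statistics, per-algorithm boolean flags, and the
#' number of positive algorithms; rows are sorted by descending ROR (the
#' conventional ranking for published PT tables), NA RORs last.
#'
#' @param tables output of [build_tables()].
#' @param thresholds a [signal_thresholds()].
#' @param zero_policy passed to the estimators: `"degenerate"` or
#'   `"haldane"`.
#' @param yates use the Yates-corrected chi-squared.
#' @param ebgm_backend `"simple"` (closed form, default) or `"mgps"`
#'   (DuMouchel gamma-mixture fit over the whole table set).
#' @param drug,stratum labels copied into the result.
#' @param level `"PT"` or `"SOC"` label for the result.
#' @return data.table of signal rows: drug, level, term, soc, a, b, c, d,
#'   ror, ror_lo, ror_hi, prr, chi2, ic, ic025, ebgm, eb05, flag_ror,
#'   flag_prr, flag_bcpnn, flag_ebgm, n_positive, stratum.
#' @export
evaluate_signals <- function(tables, thresholds = signal_thresholds(),
                             zero_policy = c("degenerate", "haldane"),
                             yates = FALSE,
                             ebgm_backend = c("simple", "mgps"),
                             drug = NA_character_, level = "PT",
                             stratum = NA_character_) {
  zero_policy <- match.arg(zero_policy)
  ebgm_backend <- match.arg(ebgm_backend)
  stopifnot(inherits(thresholds, "signal_thresholds"))
  tab <- as.data.table(tables)
  tab <- tab[a >= thresholds$min_a]
  if (!nrow(tab)) {
    return(empty_signal_table())
  }
  r <- ror(tab, zero_policy = zero_policy)
  p <- prr(tab, zero_policy = zero_policy, yates = yates)
  bc <- bcpnn_ic(tab)
  eb <- if (ebgm_backend == "mgps") {
    E <- (tab$a + tab$b) * (tab$a + tab$c) / tab$N
    m <- ebgm_mgps(tab$a, E)
    data.frame(ebgm = m$ebgm, eb05 = m$eb05, degenerate = FALSE)
  } else {
    ebgm(tab, zero_policy = zero_policy)
  }
  use <- thresholds$use
  res <- data.table(
    drug = drug, level = level, term = tab$term,
    soc = if ("soc" %in% names(tab)) tab$soc else NA_character_,
    a = tab$a, b = tab$b, c = tab$c, d = tab$d,
    ror = r$ror, ror_lo = r$ror_lo, ror_hi = r$ror_hi,
    prr = p$prr, chi2 = p$chi2,
    ic = bc$ic, ic025 = bc$ic025,
    ebgm = eb$ebgm, eb05 = eb$eb05,
    flag_ror = isTRUE(use[["ror"]]) & !is.na(r$ror_lo) &
      r$ror_lo > thresholds$ror_lo_gt,
    flag_prr = isTRUE(use[["prr"]]) & !is.na(p$prr) &
      p$prr >= thresholds$prr_ge & p$chi2 >= thresholds$chi2_ge,
    flag_bcpnn = isTRUE(use[["bcpnn"]]) & bc$ic025 > thresholds$bcpnn_ic025_gt,
    flag_ebgm = isTRUE(use[["ebgm"]]) & !is.na(eb$eb05) &
      eb$eb05 > thresholds$ebgm_eb05_gt,
    stratum = stratum
  )
  res[, n_positive := flag_ror + flag_prr + flag_bcpnn + flag_ebgm]
  setorderv(res, "ror", order = -1L, na.last = TRUE)
  setcolorder(res, c("drug", "level", "term", "soc", "a", "b", "c", "d",
                     "ror", "ror_lo", "ror_hi", "prr", "chi2", "ic", "ic025",
                     "ebgm", "eb05", "flag_ror", "flag_prr", "flag_bcpnn",
                     "flag_ebgm", "n_positive", "stratum"))
  res[]
}

empty_signal_table <- function() {
  data.table(drug = character(0), level = character(0), term = character(0),
             soc = character(0), a = integer(0), b = integer(0),
             c = integer(0), d = integer(0), ror = numeric(0),
             ror_lo = numeric(0), ror_hi = numeric(0), prr = numeric(0),
             chi2 = numeric(0), ic = numeric(0), ic025 = numeric(0),
             ebgm = numeric(0), eb05 = numeric(0), flag_ror = logical(0),
             flag_prr = logical(0), flag_bcpnn = logical(0),
             flag_ebgm = logical(0), n_positive = integer(0),
             stratum = character(0))
}
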