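# End-to-end orchestration: raw quarters -> signal tables and summaries.

#' Pipeline run configuration
#'
#' @param input_dir directory holding the quarterly ASCII files.
#' @param quarter_start,quarter_end analysis window.
#' @param target_drugs character vector of standardized drug names (>= 1).
#' @param synonyms path to the drug synonym dictionary.
#' @param hierarchy path to the PT->SOC hierarchy table.
#' @param output_dir where tab-separated outputs are written.
#' @param thresholds a [signal_thresholds()].
#' @param zero_policy `"degenerate"` or `"haldane"` zero-cell handling.
#' @param yates Yates-corrected chi-squared.
#' @param ebgm_backend `"simple"` or `"mgps"`.
#' @param strata `"none"` or `"sex"` (adds the sex-stratified scan).
#' @return list of class `"run_config"`.
#' @export
run_config <- function(input_dir, quarter_start, quarter_end, target_drugs,
                       synonyms, hierarchy, output_dir,
                       thresholds = signal_thresholds(),
                       zero_policy = "degenerate", yates = FALSE,
                       ebgm_backend = "simple", strata = c("sex", "none")) {
  strata <- match.arg(strata)
  if (length(target_drugs) < 1L) {
    stop("config error: at least one target drug is required", call. = FALSE)
  }
  structure(list(input_dir = input_dir,
                 range = quarter_range(quarter_start, quarter_end),
                 target_drugs = tolower(target_drugs), synonyms = synonyms,
                 hierarchy = hierarchy, output_dir = output_dir,
                 thresholds = thresholds, zero_policy = zero_policy,
                 yates = yates, ebgm_backend = ebgm_backend,
                 strata = strata),
            class = "run_config")
}

#' Run the full signal-detection pipeline
#'
#' Executes read -> deduplicate -> assemble -> build tables (PT and SOC) ->
#' evaluate signals -> demographic summaries -> quarterly series -> sex
#' scans, writing tab-separated outputs and a structured run log
#' (stage, metric, value) that records row counts at every stage.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with the output paths, the run `log`
#'   (data.table), the assembled `corpus` and the signal tables.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  log <- list()
  note <- function(stage, metric, value) {
    log[[length(log) + 1L]] <<- data.table(stage = stage, metric = metric,
                                           value = as.numeric(value))
  }
  qs <- iterate_quarters(cfg$range)
  rts <- lapply(qs, function(q) read_quarter(cfg$input_dir, q))
  raw <- stack_quarters(rts)
  note("read", "quarters", length(qs))
  note("read", "demo_rows", nrow(raw$demo))
  note("read", "drug_rows", nrow(raw$drug))
  note("read", "reac_rows", nrow(raw$reac))
  note("read", "outc_rows", nrow(raw$outc))

  demo <- deduplicate(raw$demo)
  note("dedup", "surviving_cases", nrow(demo))
  note("dedup", "rejected_rows", nrow(attr(demo, "rejects")))

  dict <- load_synonyms(cfg$synonyms)
  hier <- load_hierarchy(cfg$hierarchy)
  corpus <- assemble(demo, raw$drug, raw$reac, raw$outc, dict,
                     all_demo_ids = unique(raw$demo$PRIMARYID))
  note("assemble", "reports", nrow(corpus$reports))
  note("assemble", "drug_mentions", nrow(corpus$drugs))
  note("assemble", "reactions", nrow(corpus$reactions))
  note("assemble", "outcome_entries", nrow(corpus$outcomes))
  note("assemble", "orphans_rejected",
       sum(vapply(corpus$rejects, nrow, 0L)))

  if (!dir.exists(cfg$output_dir)) dir.create(cfg$output_dir, recursive = TRUE)
  paths <- character(0)
  emit <- function(dt, name) {
    path <- file.path(cfg$output_dir, name)
    fwrite(dt, path, sep = "\t")
    paths <<- c(paths, path)
    path
  }

  signals <- list(); demos <- list(); series <- list(); scans <- list()
  for (drg in cfg$target_drugs) {
    ids <- ps_report_ids(corpus, drg)
    note(paste0("cohort:", drg), "ps_reports", length(ids))
    for (lvl in c("PT", "SOC")) {
      tab <- build_tables(corpus, drg, level = lvl, hierarchy = hier)
      sig <- evaluate_signals(tab, cfg$thresholds,
                              zero_policy = cfg$zero_policy,
                              yates = cfg$yates,
                              ebgm_backend = cfg$ebgm_backend,
                              drug = drg, level = lvl)
      note(paste0("signals:", drg), paste0(tolower(lvl), "_terms"), nrow(sig))
      signals[[paste(drg, lvl)]] <- sig
    }
    cohort <- subset_corpus(corpus, ids)$reports
    demos[[drg]] <- summarize_demographics(cohort, drug = drg)
    series[[drg]] <- quarter_series(cohort, cfg$range, drug = drg)
    if (cfg$strata == "sex") {
      scans[[drg]] <- sex_stratified_signals(corpus, drg, cfg$thresholds,
                                             level = "PT", hierarchy = hier,
                                             zero_policy = cfg$zero_policy,
                                             yates = cfg$yates,
                                             ebgm_backend = cfg$ebgm_backend)
    }
  }
  sig_all <- rbindlist(signals, use.names = TRUE)
  emit(sig_all, "signals.tsv")
  emit(rbindlist(demos, use.names = TRUE), "demographics.tsv")
  emit(rbindlist(series, use.names = TRUE), "quarter_series.tsv")
  if (cfg$strata == "sex" && length(scans)) {
    emit(rbindlist(scans, use.names = TRUE), "sex_scan.tsv")
  }
  log_dt <- rbindlist(log)
  emit(log_dt, "run_log.tsv")
  invisible(list(paths = paths, log = log_dt, corpus = corpus,
                 signals = sig_all))
}
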