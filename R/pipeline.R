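# End-to-end orchestration: ingest -> dedup -> cohort -> characteristics ->
# signals -> priority -> severity -> cumulative trend, with stage-count
# logging and CSV exports.

#' Assemble a pipeline configuration
#'
#' Either pass the fields directly or point `yaml` at a YAML file with the
#' same keys. Regimen synonym sets may be given as a named list of
#' character vectors.
#'
#' @param input_dir Directory of quarterly ASCII files (one subdirectory
#'   per quarter, or flat with quarter-tagged names); ignored when
#'   `bundles` is supplied.
#' @param bundles Optional list of `faers_bundle`s to analyze directly.
#' @param out_dir Output directory for the exported tables and run log.
#' @param regimen List of drug-synonym sets defining the combination.
#' @param roles Qualifying suspect role codes.
#' @param min_count Minimum report count for signal evaluation.
#' @param conf_level Confidence level for ROR intervals.
#' @param annotations Data frame of per-PT annotations (or path to a CSV
#'   with columns `pt`, `evidence`, `ime`/`dme` or `medical_event`,
#'   optionally `deaths`); `NULL` skips the priority stage.
#' @param soc_map A `meddra_map`, or path to a two-column mapping file;
#'   `NULL` leaves signals unmapped.
#' @param trend_k Number of top signals for the cumulative ROR series.
#' @param yaml Optional path to a YAML config file; fields in the file
#'   override the defaults, and explicit arguments override the file.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, bundles = NULL, out_dir = NULL,
                            regimen = pola_br_regimen(),
                            roles = c("PS", "SS"), min_count = 10,
                            conf_level = 0.95, annotations = NULL,
                            soc_map = NULL, trend_k = 10, yaml = NULL) {
  cfg <- list(input_dir = input_dir, bundles = bundles, out_dir = out_dir,
              regimen = regimen, roles = roles, min_count = min_count,
              conf_level = conf_level, annotations = annotations,
              soc_map = soc_map, trend_k = trend_k)
  if (!is.null(yaml)) {
    file_cfg <- yaml::read_yaml(yaml)
    supplied <- names(match.call())[-1]
    for (k in intersect(names(file_cfg), names(cfg))) {
      if (!(k %in% supplied)) cfg[[k]] <- file_cfg[[k]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Collects every problem (missing inputs, invalid thresholds, unreadable
#' annotation files) without running any stage.
#'
#' @param config A `pipeline_config`.
#' @return Character vector of problems; empty when the config is valid.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  if (is.null(config$bundles) && is.null(config$input_dir)) {
    problems <- c(problems, "either 'bundles' or 'input_dir' must be supplied")
  }
  if (!is.null(config$input_dir) && is.null(config$bundles) &&
      !dir.exists(config$input_dir)) {
    problems <- c(problems, sprintf("input_dir '%s' does not exist", config$input_dir))
  }
  if (!is.null(config$min_count) &&
      (!is.numeric(config$min_count) || config$min_count < 1)) {
    problems <- c(problems, "min_count must be >= 1")
  }
  if (!is.null(config$conf_level) &&
      (config$conf_level <= 0 || config$conf_level >= 1)) {
    problems <- c(problems, "conf_level must lie in (0, 1)")
  }
  if (length(config$regimen) == 0) {
    problems <- c(problems, "regimen must contain at least one synonym set")
  }
  if (is.character(config$annotations) && !file.exists(config$annotations)) {
    problems <- c(problems, sprintf("annotations file '%s' does not exist",
                                    config$annotations))
  }
  if (is.character(config$soc_map) && !file.exists(config$soc_map)) {
    problems <- c(problems, sprintf("soc_map file '%s' does not exist",
                                    config$soc_map))
  }
  problems
}

ingest_bundles <- function(config) {
  if (!is.null(config$bundles)) return(config$bundles)
  subdirs <- list.dirs(config$input_dir, recursive = FALSE)
  if (length(subdirs) > 0) {
    lapply(subdirs, function(d) read_quarter(d, label = basename(d)))
  } else {
    files <- list.files(config$input_dir, pattern = "^DEMO.*\\.txt")
    if (length(files) == 0) {
      stop(sprintf("no quarterly files found in '%s'", config$input_dir),
           call. = FALSE)
    }
    labels <- sub("^DEMO(.*)\\.txt(\\.gz)?$", "\\1", files)
    lapply(labels, function(lab) read_quarter(config$input_dir, label = lab))
  }
}

# per-PT death counts among cohort reports, for the priority stage
cohort_pt_deaths <- function(cohort) {
  demo <- cohort$demo[cohort$demo$in_cohort, , drop = FALSE]
  death_ids <- unique(cohort$outc$primaryid[cohort$outc$outc_cod == "DE"])
  reac <- cohort$reac[cohort$reac$primaryid %in% demo$primaryid, , drop = FALSE]
  reac$pt_key <- tolower(trimws(reac$pt))
  pairs <- dplyr::distinct(reac, .data$primaryid, .data$pt_key, .keep_all = TRUE)
  pairs |>
    dplyr::group_by(.data$pt_key) |>
    dplyr::summarise(pt = dplyr::first(.data$pt),
                     deaths = sum(.data$primaryid %in% death_ids),
                     .groups = "drop") |>
    dplyr::select("pt", "deaths")
}

#' Run the full signal-detection pipeline
#'
#' Executes every stage on the configured inputs and, when `out_dir` is
#' set, writes `characteristics.csv`, `signals.csv`, `priority.csv`,
#' `severity.csv`, `trend.csv` and a plain-text `run_log.txt` with the
#' stage-by-stage report counts. The run is deterministic given its
#' inputs. Any stage failure aborts with the stage name in the error.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the stage outputs (`cases`, `cohort`,
#'   `characteristics`, `signals`, `priority`, `severity`, `trend`) and
#'   the `counts` log tibble.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  problems <- validate_config(config)
  if (length(problems) > 0) {
    stop(paste(c("invalid pipeline configuration:", problems), collapse = "\n  "),
         call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  counts <- list()

  bundles <- stage("ingest", ingest_bundles(config))
  n_read <- sum(vapply(bundles, function(b) nrow(b$demo), 1L))
  counts$reports_read <- n_read

  cases <- stage("deduplicate", deduplicate(bundles))
  counts$duplicates_removed <- cases$n_removed
  counts$reports_deduplicated <- nrow(cases$demo)

  cohort <- stage("cohort", build_cohort(cases, regimen = config$regimen,
                                         roles = config$roles))
  counts$cohort_reports <- cohort$n_cohort

  characteristics <- stage("characteristics", demographics_summary(cohort))

  soc_map <- config$soc_map
  if (is.character(soc_map)) soc_map <- read_soc_map(soc_map)
  signals <- stage("signals", detect_signals(
    cohort, soc_map = soc_map, min_count = config$min_count,
    conf_level = config$conf_level))
  counts$pts_evaluated <- nrow(signals)
  counts$significant_signals <- sum(signals$significant)

  priority <- NULL
  if (!is.null(config$annotations)) {
    ann <- config$annotations
    if (is.character(ann)) {
      ann <- readr::read_csv(ann, show_col_types = FALSE, progress = FALSE)
    }
    sig <- signals[signals$significant, , drop = FALSE]
    deaths <- cohort_pt_deaths(cohort)
    sig <- dplyr::left_join(sig, deaths, by = "pt")
    sig$deaths[is.na(sig$deaths)] <- 0L
    priority <- stage("priority", score_table(sig, ann))
    counts$priority_low <- priority$level_counts[["low"]]
    counts$priority_moderate <- priority$level_counts[["moderate"]]
    counts$priority_high <- priority$level_counts[["high"]]
  }

  severity <- stage("severity", compare_all(cohort, min_count = config$min_count))

  trend <- NULL
  sig <- signals[signals$significant, , drop = FALSE]
  if (nrow(sig) > 0) {
    top <- top_signals_by_count(sig, k = min(config$trend_k, nrow(sig)))
    trend <- stage("trend", dplyr::bind_rows(lapply(top, function(pt) {
      s <- cumulative_series(cohort, pt, conf_level = config$conf_level)
      if (nrow(s) > 0) dplyr::bind_cols(tibble::tibble(pt = pt), s) else NULL
    })))
  }

  counts_df <- tibble::tibble(stage = names(counts),
                              n = as.integer(unlist(counts)))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(characteristics, file.path(config$out_dir, "characteristics.csv"))
    readr::write_csv(signals, file.path(config$out_dir, "signals.csv"))
    if (!is.null(priority)) {
      readr::write_csv(priority$results, file.path(config$out_dir, "priority.csv"))
    }
    readr::write_csv(severity, file.path(config$out_dir, "severity.csv"))
    if (!is.null(trend)) {
      readr::write_csv(trend, file.path(config$out_dir, "trend.csv"))
    }
    writeLines(sprintf("%-22s %d", counts_df$stage, counts_df$n),
               file.path(config$out_dir, "run_log.txt"))
  }
  invisible(list(cases = cases, cohort = cohort,
                 characteristics = characteristics, signals = signals,
                 priority = priority, severity = severity, trend = trend,
                 counts = counts_df))
}
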