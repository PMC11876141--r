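# Semi-quantitative clinical-priority scoring of significant signals.
#
# Five additive components: report volume, ROR CI lower bound, fatal-report
# burden, designated/important medical event status, and an evidence grade
# from literature appraisal. Scores 0-4 are low, 5-7 moderate, 8-10 high
# priority.

#' Default clinical-priority rubric
#'
#' Component points: 10-49 cohort reports score 1, 50 or more score 2;
#' ROR CI lower bound below 2 scores 0, in \[2, 5\] scores 1, above 5
#' scores 2; 100 or more fatal reports score 1; a designated medical event
#' (DME) scores 2, otherwise an important medical event (IME) scores 1;
#' evidence grade `++` scores 2, `+` scores 1, `-` scores 0. Level bins:
#' low for totals up to 4, moderate for 5-7, high for 8 and above. All
#' thresholds are plain list entries so an alternative score sheet can be
#' swapped in.
#'
#' @return A `priority_rubric` list.
#' @export
default_rubric <- function() {
  structure(list(
    min_n = 10,
    case_points = list(breaks = c(10, 50), points = c(1, 2)),
    ror_points = list(lower = 2, upper = 5, points = c(0, 1, 2)),
    death_threshold = 100, death_points = 1,
    dme_points = 2, ime_points = 1,
    evidence_points = c("++" = 2, "+" = 1, "-" = 0),
    level_bins = c(low = 4, moderate = 7)
  ), class = "priority_rubric")
}

normalize_evidence <- function(evidence) {
  e <- trimws(as.character(evidence))
  # em-dash / minus variants in published tables all mean "no evidence"
  e[e %in% c("—", "−", "–", "-", "")] <- "-"
  e
}

score_level <- function(score, rubric) {
  dplyr::case_when(
    score <= rubric$level_bins[["low"]] ~ "low",
    score <= rubric$level_bins[["moderate"]] ~ "moderate",
    TRUE ~ "high"
  )
}

#' Score one or more signals with the priority rubric
#'
#' Vectorized over its inputs. Scoring is only defined for significant
#' signals, so any `n` below the rubric's minimum report count errors.
#'
#' @param n Cohort report count(s) for the signal.
#' @param ror025 Lower bound(s) of the 95% ROR confidence interval.
#' @param deaths Count(s) of the signal's reports with a death outcome.
#' @param dme,ime Logical flag(s): designated / important medical event.
#'   DME dominates when both are set.
#' @param evidence Evidence grade(s): `"++"`, `"+"` or `"-"` (em-dash
#'   accepted as `"-"`).
#' @param rubric A `priority_rubric`; see [default_rubric()].
#' @return Tibble with one row per signal: component points
#'   (`pts_cases`, `pts_ror`, `pts_deaths`, `pts_event`, `pts_evidence`),
#'   the integer `score`, and the `level`.
#' @examples
#' priority_score(54, 11.12, 17, dme = TRUE, evidence = "++") # score 8, high
#' @export
priority_score <- function(n, ror025, deaths, dme = FALSE, ime = FALSE,
                           evidence = "-", rubric = default_rubric()) {
  stopifnot(inherits(rubric, "priority_rubric"))
  if (any(is.na(n)) || any(n < rubric$min_n)) {
    stop(sprintf("priority scores apply only to significant signals (n >= %d)",
                 rubric$min_n), call. = FALSE)
  }
  if (any(deaths > n)) stop("deaths cannot exceed the report count", call. = FALSE)
  evidence <- normalize_evidence(evidence)
  if (!all(evidence %in% names(rubric$evidence_points))) {
    bad <- unique(evidence[!evidence %in% names(rubric$evidence_points)])
    stop(sprintf("unknown evidence grade(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  cp <- rubric$case_points
  pts_cases <- ifelse(n >= cp$breaks[2], cp$points[2], cp$points[1])
  rp <- rubric$ror_points
  pts_ror <- ifelse(ror025 < rp$lower, rp$points[1],
                    ifelse(ror025 <= rp$upper, rp$points[2], rp$points[3]))
  pts_deaths <- ifelse(deaths >= rubric$death_threshold, rubric$death_points, 0)
  pts_event <- ifelse(dme, rubric$dme_points, ifelse(ime, rubric$ime_points, 0))
  pts_evidence <- unname(rubric$evidence_points[evidence])
  score <- pts_cases + pts_ror + pts_deaths + pts_event + pts_evidence
  tibble::tibble(
    pts_cases = pts_cases, pts_ror = pts_ror, pts_deaths = pts_deaths,
    pts_event = pts_event, pts_evidence = pts_evidence,
    score = as.integer(score), level = score_level(score, rubric)
  )
}

#' Score a table of significant signals
#'
#' Joins detected signals with their per-PT annotations (evidence grade and
#' IME/DME membership), applies the rubric, and tallies the per-level
#' counts. Signals without an annotation are listed explicitly in the
#' result's `unannotated` element and never scored with a silent default.
#'
#' @param signals Tibble with at least `pt`, `n`, `ror_lo` (or `ror025`)
#'   and, when available, `deaths`. Typically [detect_signals()] output
#'   augmented with death counts.
#' @param annotations Tibble with columns `pt`, `evidence`, and either
#'   logical `ime`/`dme` columns or a `medical_event` column with values
#'   `"DME"`, `"IME"`, `"none"`. A `deaths` column here overrides one in
#'   `signals`.
#' @param rubric A `priority_rubric`.
#' @return List with `results` (one row per annotated signal: pt, inputs,
#'   component points, score, level), `level_counts` (named integer
#'   vector low/moderate/high), and `unannotated` (character vector of
#'   PTs lacking an annotation).
#' @export
score_table <- function(signals, annotations, rubric = default_rubric()) {
  signals <- tibble::as_tibble(signals)
  annotations <- tibble::as_tibble(annotations)
  if (!"ror025" %in% names(signals) && "ror_lo" %in% names(signals)) {
    signals$ror025 <- signals$ror_lo
  }
  stopifnot(all(c("pt", "n", "ror025") %in% names(signals)),
            "pt" %in% names(annotations))
  if ("medical_event" %in% names(annotations)) {
    annotations$dme <- toupper(annotations$medical_event) == "DME"
    annotations$ime <- toupper(annotations$medical_event) == "IME"
  }
  if (!all(c("evidence", "ime", "dme") %in% names(annotations))) {
    stop("annotations need 'evidence' plus 'ime'/'dme' flags (or 'medical_event')",
         call. = FALSE)
  }
  key <- tolower(trimws(signals$pt))
  akey <- tolower(trimws(annotations$pt))
  hit <- match(key, akey)
  unannotated <- signals$pt[is.na(hit)]
  scored <- signals[!is.na(hit), , drop = FALSE]
  ann <- annotations[hit[!is.na(hit)], , drop = FALSE]
  if ("deaths" %in% names(ann)) {
    scored$deaths <- ann$deaths
  } else if (!"deaths" %in% names(scored)) {
    stop("death counts must be supplied in 'signals' or 'annotations'", call. = FALSE)
  }
  if (nrow(scored) == 0) {
    empty <- tibble::tibble(pt = character(), n = integer(), ror025 = numeric(),
                            deaths = integer(), score = integer(), level = character())
    return(list(results = empty,
                level_counts = c(low = 0L, moderate = 0L, high = 0L),
                unannotated = unannotated))
  }
  pts <- priority_score(scored$n, scored$ror025, scored$deaths,
                        dme = ann$dme, ime = ann$ime,
                        evidence = ann$evidence, rubric = rubric)
  results <- dplyr::bind_cols(
    scored[, intersect(c("soc", "pt", "n", "ror025", "deaths"), names(scored))],
    tibble::tibble(ime = ann$ime, dme = ann$dme,
                   evidence = normalize_evidence(ann$evidence)),
    pts
  )
  lev <- factor(results$level, levels = c("low", "moderate", "high"))
  list(results = results,
       level_counts = stats::setNames(as.integer(table(lev)), levels(lev)),
       unannotated = unannotated)
}

extdata <- function(file) {
  system.file("extdata", file, package = "faersignal", mustWork = TRUE)
}

#' Published pola+BR signal set with priority inputs
#'
#' The 58 significant pola+BR signals with the inputs the priority rubric
#' consumes (report count, ROR CI lower bound, death count, IME/DME status,
#' evidence grade) and the published score and level for cross-checking.
#'
#' @return Tibble with 58 rows.
#' @export
pola_br_signal_annotations <- function() {
  readr::read_csv(extdata("pola_br_signal_annotations.csv"),
                  col_types = "ccnnnccnc", progress = FALSE)
}

#' Published severe versus non-severe stratum counts for pola+BR
#'
#' Per-variable counts of serious and non-serious pola+BR reports (sex and
#' per-PT rows) with the published test statistic where one was printed.
#' Rows whose printed statistic is irreconcilable with their own printed
#' counts are flagged `print_consistent = FALSE`.
#'
#' @return Tibble with one row per variable.
#' @export
pola_br_severity_counts <- function() {
  readr::read_csv(extdata("pola_br_severity_counts.csv"),
                  col_types = "ciinccl", progress = FALSE)
}

#' Reference DME / IME membership lists
#'
#' Synthetic subsets of the regulator-curated designated and important
#' medical event lists, seeded from the published pola+BR signal
#' annotations; real analyses should supply the full EMA lists.
#'
#' @return Character vector of Preferred Terms.
#' @export
dme_reference <- function() readLines(extdata("dme_reference_synthetic.txt"))

#' @rdname dme_reference
#' @export
ime_reference <- function() readLines(extdata("ime_reference_synthetic.txt"))

#' PT to SOC mapping for the pola+BR signal set
#'
#' @return A `meddra_map` covering the 58 published signals.
#' @export
pola_br_soc_map <- function() read_soc_map(extdata("pt_soc_map.tsv"))
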