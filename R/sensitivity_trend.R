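# Cumulative-by-year ROR series: the sensitivity analysis that tracks a
# signal's ROR and CI as reports accumulate.

#' Cumulative ROR series for one Preferred Term
#'
#' For each period (report year), a 2x2 table is built from all
#' deduplicated reports with `report_year` up to and including the period,
#' and the ROR with its Woolf CI is computed. Periods whose cumulative
#' table has a zero cell (or no cohort report) are skipped and listed in
#' the `skipped` attribute, since early years may lack comparator events
#' for rare PTs. The final point reproduces the all-data signal exactly.
#'
#' @param cohort A `faers_cohort`.
#' @param pt Preferred Term (case-insensitive).
#' @param periods Ordered integer vector of report years; defaults to the
#'   years present in the data.
#' @param conf_level CI level.
#' @return Tibble with columns `period`, `a`, `b`, `c`, `d`, `ror`,
#'   `ror_lo`, `ror_hi`; skipped periods in `attr(, "skipped")`.
#' @export
cumulative_series <- function(cohort, pt, periods = NULL, conf_level = 0.95) {
  stopifnot(inherits(cohort, "faers_cohort"), length(pt) == 1)
  demo <- cohort$demo
  if (is.null(periods)) periods <- sort(unique(demo$report_year))
  periods <- sort(unique(as.integer(periods)))
  pt_key <- tolower(trimws(pt))
  with_pt <- unique(cohort$reac$primaryid[tolower(trimws(cohort$reac$pt)) == pt_key])
  has_pt <- demo$primaryid %in% with_pt
  out <- list()
  skipped <- integer(0)
  for (yr in periods) {
    sel <- demo$report_year <= yr
    a <- sum(sel & demo$in_cohort & has_pt)
    b <- sum(sel & demo$in_cohort & !has_pt)
    c <- sum(sel & !demo$in_cohort & has_pt)
    d <- sum(sel & !demo$in_cohort & !has_pt)
    if (min(a, b, c, d) == 0) {
      skipped <- c(skipped, yr)
      next
    }
    ci <- ror_ci(a, b, c, d, conf_level = conf_level)
    out[[as.character(yr)]] <- tibble::tibble(
      period = yr, a = a, b = b, c = c, d = d,
      ror = ci$ror, ror_lo = ci$ror_lo, ror_hi = ci$ror_hi)
  }
  res <- if (length(out) > 0) dplyr::bind_rows(out) else
    tibble::tibble(period = integer(), a = integer(), b = integer(),
                   c = integer(), d = integer(), ror = numeric(),
                   ror_lo = numeric(), ror_hi = numeric())
  attr(res, "skipped") <- skipped
  res
}

#' Top signals by cohort report count
#'
#' Selects the `k` Preferred Terms with the largest report counts among the
#' detected signals, breaking count ties lexicographically. Requesting more
#' than are available returns all of them with a warning.
#'
#' @param signals [detect_signals()] output (needs `pt` and `n`).
#' @param k Number of PTs to return.
#' @return Character vector of PTs, largest count first.
#' @export
top_signals_by_count <- function(signals, k = 10) {
  stopifnot(k >= 0)
  signals <- tibble::as_tibble(signals)
  if (k > nrow(signals)) {
    warning(sprintf("requested %d signals but only %d available", k, nrow(signals)))
    k <- nrow(signals)
  }
  ordered <- dplyr::arrange(signals, dplyr::desc(.data$n), .data$pt)
  utils::head(ordered$pt, k)
}
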