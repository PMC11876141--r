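# Reporting odds ratio signal detection: 2x2 contingency tables, Woolf
# confidence intervals, and the n >= 10 / lower-bound > 1 signal criterion.

#' Reporting odds ratio with a Woolf (log-normal) confidence interval
#'
#' The ROR for a 2x2 table is (a*d)/(b*c), with `a` the cohort reports
#' carrying the event, `b` cohort reports without it, and `c`, `d` the same
#' split among comparator reports. The confidence interval is
#' `exp(log(ROR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param a,b,c,d Non-negative counts (vectorized).
#' @param conf_level Confidence level; 0.95 gives z = 1.96.
#' @param zero_cell `"strict"` errors on any zero cell; `"haldane"` adds
#'   0.5 to every cell (Haldane–Anscombe) before computing.
#' @return Tibble with columns `ror`, `ror_lo`, `ror_hi`.
#' @examples
#' ror_ci(10, 90, 100, 9900) # ROR 11, CI roughly (5.56, 21.77)
#' @export
ror_ci <- function(a, b, c, d, conf_level = 0.95,
                   zero_cell = c("strict", "haldane")) {
  zero_cell <- match.arg(zero_cell)
  counts <- cbind(a, b, c, d)
  if (any(is.na(counts))) stop("counts must not be missing", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  has_zero <- rowSums(counts == 0) > 0
  if (any(has_zero)) {
    if (zero_cell == "strict") {
      stop("zero cell in contingency table; use zero_cell = \"haldane\" to apply the +0.5 correction",
           call. = FALSE)
    }
    counts[has_zero, ] <- counts[has_zero, , drop = FALSE] + 0.5
  }
  a <- unname(counts[, 1]); b <- unname(counts[, 2])
  c <- unname(counts[, 3]); d <- unname(counts[, 4])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  log_ror <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  tibble::tibble(
    ror = exp(log_ror),
    ror_lo = exp(log_ror - z * se),
    ror_hi = exp(log_ror + z * se)
  )
}

#' 2x2 contingency table for one Preferred Term
#'
#' The counting unit is the deduplicated report with set semantics: a
#' report listing the PT several times contributes once. `a` counts cohort
#' reports with the PT, `b` cohort reports without, `c`/`d` the same among
#' all non-cohort reports.
#'
#' @param cohort A `faers_cohort`.
#' @param pt A single Preferred Term (matched case-insensitively).
#' @return Named list with integers `a`, `b`, `c`, `d`.
#' @export
pt_contingency <- function(cohort, pt) {
  stopifnot(inherits(cohort, "faers_cohort"), length(pt) == 1)
  with_pt <- unique(cohort$reac$primaryid[tolower(trimws(cohort$reac$pt)) ==
                                            tolower(trimws(pt))])
  in_cohort <- cohort$demo$in_cohort
  has_pt <- cohort$demo$primaryid %in% with_pt
  list(a = sum(in_cohort & has_pt), b = sum(in_cohort & !has_pt),
       c = sum(!in_cohort & has_pt), d = sum(!in_cohort & !has_pt))
}

# Count a (cohort reports with PT) and c (comparator reports with PT) for
# every PT at once.
pt_counts_all <- function(cohort) {
  pairs <- cohort$reac |>
    dplyr::mutate(pt_key = tolower(trimws(.data$pt))) |>
    dplyr::distinct(.data$primaryid, .data$pt_key, .keep_all = TRUE)
  pairs$in_cohort <- cohort$demo$in_cohort[match(pairs$primaryid, cohort$demo$primaryid)]
  pairs |>
    dplyr::group_by(.data$pt_key) |>
    dplyr::summarise(pt = dplyr::first(.data$pt),
                     a = sum(.data$in_cohort), c = sum(!.data$in_cohort),
                     .groups = "drop")
}

#' Detect disproportionality signals across all Preferred Terms
#'
#' For every PT with at least `min_count` cohort reports, computes the ROR
#' and its Woolf confidence interval against all non-cohort reports, and
#' flags the PT as a significant signal when the CI lower bound exceeds
#' `ci_lower_gt`. Results are ordered by SOC, then report count descending.
#'
#' @param cohort A `faers_cohort` with a non-empty cohort.
#' @param soc_map Optional `meddra_map`; unmapped PTs get SOC `"Unmapped"`.
#' @param min_count Minimum cohort report count for a PT to be evaluated.
#' @param ci_lower_gt Signal threshold on the CI lower bound.
#' @param conf_level Confidence level of the interval.
#' @return Tibble with columns `soc`, `pt`, `n`, `ror`, `ror_lo`, `ror_hi`,
#'   `significant`.
#' @export
detect_signals <- function(cohort, soc_map = NULL, min_count = 10,
                           ci_lower_gt = 1, conf_level = 0.95) {
  stopifnot(inherits(cohort, "faers_cohort"))
  if (cohort$n_total_db == 0) stop("empty report database", call. = FALSE)
  if (cohort$n_cohort == 0) stop("cohort is empty; no signals to evaluate", call. = FALSE)
  counts <- pt_counts_all(cohort)
  counts <- counts[counts$a >= min_count, , drop = FALSE]
  if (nrow(counts) == 0) {
    return(tibble::tibble(soc = character(), pt = character(), n = integer(),
                          ror = numeric(), ror_lo = numeric(),
                          ror_hi = numeric(), significant = logical()))
  }
  b <- cohort$n_cohort - counts$a
  d <- (cohort$n_total_db - cohort$n_cohort) - counts$c
  ci <- ror_ci(counts$a, b, counts$c, d, conf_level = conf_level,
               zero_cell = "haldane")
  res <- tibble::tibble(
    soc = if (is.null(soc_map)) "Unmapped" else map_pt_to_soc(counts$pt, soc_map),
    pt = counts$pt, n = as.integer(counts$a),
    ror = ci$ror, ror_lo = ci$ror_lo, ror_hi = ci$ror_hi,
    significant = counts$a >= min_count & ci$ror_lo > ci_lower_gt
  )
  dplyr::arrange(res, .data$soc, dplyr::desc(.data$n), .data$pt)
}
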