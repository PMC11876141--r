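# Severe vs non-severe comparisons: per-PT 2x2 tests (Pearson chi-squared
# without continuity correction, or Fisher's exact test when expected cell
# counts are small) and Welch t-tests for continuous demographics.

as_2x2 <- function(a, b, c, d) {
  m <- matrix(c(a, c, b, d), nrow = 2,
              dimnames = list(event = c("yes", "no"),
                              stratum = c("serious", "non_serious")))
  if (any(is.na(m)) || any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  m
}

#' Pearson chi-squared test on a 2x2 table, no continuity correction
#'
#' Equivalent to the closed form `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`
#' with p from the chi-squared distribution on 1 df. Yates correction is
#' deliberately off: published pharmacovigilance severity tables use the
#' uncorrected statistic.
#'
#' @param a,b,c,d Cell counts: `a` serious reports with the event, `b`
#'   serious without, `c` non-serious with, `d` non-serious without.
#' @return List with `statistic`, `p_value`, `test_used = "pearson"`.
#' @export
pearson_chi2 <- function(a, b, c, d) {
  m <- as_2x2(a, b, c, d)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate 2x2 table: a zero margin", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       test_used = "pearson")
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value summing the probabilities of all tables with the
#' observed margins that are no more probable than the observed table.
#'
#' @inheritParams pearson_chi2
#' @return List with `statistic = NA` (Fisher reports no statistic),
#'   `p_value`, `test_used = "fisher"`.
#' @export
fisher_exact <- function(a, b, c, d) {
  m <- as_2x2(a, b, c, d)
  p <- stats::fisher.test(m)$p.value
  list(statistic = NA_real_, p_value = min(p, 1), test_used = "fisher")
}

#' Choose between Pearson and Fisher for a 2x2 table
#'
#' The classical rule: Fisher's exact test when any expected cell count
#' under independence is below 5, otherwise the Pearson chi-squared test.
#' An expected count of exactly 5 stays with Pearson.
#'
#' @inheritParams pearson_chi2
#' @return `"pearson"` or `"fisher"`.
#' @export
choose_test <- function(a, b, c, d) {
  m <- as_2x2(a, b, c, d)
  n <- sum(m)
  if (n == 0) return("fisher")
  expected <- outer(rowSums(m), colSums(m)) / n
  if (min(expected) < 5) "fisher" else "pearson"
}

#' Independent two-sample t-test
#'
#' Welch's unequal-variance form by default; set `equal_variance = TRUE`
#' for the pooled-variance test. Missing values are dropped per sample.
#'
#' @param x,y Numeric samples with at least two non-missing values each.
#' @param equal_variance Pool the variances?
#' @return List with `statistic` (t), `p_value`, `test_used = "t"`, and
#'   the group means.
#' @export
welch_t <- function(x, y, equal_variance = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each sample needs at least two non-missing values", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = equal_variance)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       test_used = "t", mean_x = mean(x), mean_y = mean(y))
}

severity_test_row <- function(a, b, c, d) {
  degenerate <- (a + c) == 0 || (b + d) == 0 || (a + b) == 0 || (c + d) == 0
  test <- choose_test(a, b, c, d)
  if (test == "pearson" && !degenerate) {
    res <- pearson_chi2(a, b, c, d)
  } else {
    res <- fisher_exact(a, b, c, d)
  }
  tibble::tibble(serious = a, non_serious = c, statistic = res$statistic,
                 p_value = res$p_value, test_used = res$test_used,
                 degenerate = degenerate)
}

#' Compare severe and non-severe cohort reports
#'
#' Builds, for each Preferred Term, the 2x2 table of seriousness by
#' presence of the PT among cohort reports, runs the Pearson or Fisher test
#' per [choose_test()], and adds Welch t-test rows for continuous
#' demographics and a chi-squared row for sex.
#'
#' @param cohort A `faers_cohort`.
#' @param pts PTs to test; defaults to every PT with at least `min_count`
#'   cohort reports.
#' @param continuous Demographic columns of `demo` to compare with t-tests.
#' @param min_count Default PT inclusion threshold.
#' @return Tibble with columns `variable`, `serious`, `non_serious`,
#'   `statistic`, `p_value`, `test_used`, `degenerate`.
#' @export
compare_all <- function(cohort, pts = NULL,
                        continuous = c("age_years", "weight_kg"),
                        min_count = 10) {
  stopifnot(inherits(cohort, "faers_cohort"))
  demo <- cohort$demo[cohort$demo$in_cohort, , drop = FALSE]
  n_serious <- sum(demo$serious)
  n_nonserious <- sum(!demo$serious)
  rows <- list()

  for (field in continuous) {
    x <- demo[[field]][demo$serious]
    y <- demo[[field]][!demo$serious]
    if (sum(!is.na(x)) >= 2 && sum(!is.na(y)) >= 2) {
      tt <- welch_t(x, y)
      rows[[field]] <- tibble::tibble(
        variable = field, serious = NA_integer_, non_serious = NA_integer_,
        statistic = tt$statistic, p_value = tt$p_value, test_used = "t",
        degenerate = FALSE)
    } else {
      rows[[field]] <- tibble::tibble(
        variable = field, serious = NA_integer_, non_serious = NA_integer_,
        statistic = NA_real_, p_value = NA_real_, test_used = "t",
        degenerate = TRUE)
    }
  }

  known_sex <- demo$sex %in% c("M", "F")
  sm <- sum(demo$serious & demo$sex == "M"); nm <- sum(!demo$serious & demo$sex == "M")
  sf <- sum(demo$serious & demo$sex == "F"); nf <- sum(!demo$serious & demo$sex == "F")
  if (all(c(sm + sf, nm + nf, sm + nm, sf + nf) > 0)) {
    sex_row <- severity_test_row(sm, sf, nm, nf)
    rows[["sex"]] <- dplyr::bind_cols(tibble::tibble(variable = "sex (male)"),
                                      sex_row)
  }

  reac <- cohort$reac[cohort$reac$primaryid %in% demo$primaryid, , drop = FALSE]
  reac$pt_key <- tolower(trimws(reac$pt))
  pairs <- dplyr::distinct(reac, .data$primaryid, .data$pt_key, .keep_all = TRUE)
  pairs$serious <- demo$serious[match(pairs$primaryid, demo$primaryid)]
  counts <- pairs |>
    dplyr::group_by(.data$pt_key) |>
    dplyr::summarise(pt = dplyr::first(.data$pt),
                     a = sum(.data$serious), c = sum(!.data$serious),
                     .groups = "drop")
  if (is.null(pts)) {
    counts <- counts[(counts$a + counts$c) >= min_count, , drop = FALSE]
  } else {
    counts <- counts[counts$pt_key %in% tolower(trimws(pts)), , drop = FALSE]
  }
  pt_rows <- lapply(seq_len(nrow(counts)), function(i) {
    a <- counts$a[i]; c <- counts$c[i]
    row <- severity_test_row(a, n_serious - a, c, n_nonserious - c)
    dplyr::bind_cols(tibble::tibble(variable = counts$pt[i]), row)
  })
  dplyr::bind_rows(c(rows, pt_rows))
}
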