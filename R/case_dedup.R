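# Case-version deduplication, regimen cohort construction, seriousness
# classification and descriptive characteristics.

SERIOUS_CODES <- c("DE", "LT", "HO", "DS")

#' Default synonym sets for the pola+BR regimen
#'
#' Each element is one regimen component; a case is a cohort member when
#' every component is matched by at least one suspect drug entry. Matching
#' is case-insensitive exact matching on `drugname` or `prod_ai`, so trade
#' names must be listed explicitly.
#'
#' @return Named list of character vectors.
#' @export
pola_br_regimen <- function() {
  list(
    polatuzumab = c("polatuzumab vedotin", "polatuzumab", "polivy",
                    "polatuzumab vedotin-piiq"),
    bendamustine = c("bendamustine", "bendamustine hydrochloride",
                     "treanda", "bendeka"),
    rituximab = c("rituximab", "rituxan", "mabthera")
  )
}

# primaryid tie-break: numeric where all ids parse, else lexicographic.
primaryid_order_key <- function(id) {
  num <- suppressWarnings(as.numeric(id))
  if (!anyNA(num)) num else rank(id, ties.method = "min")
}

#' Deduplicate case versions across quarterly bundles
#'
#' FAERS distributes several versions of one case (same `caseid`,
#' incremented `caseversion`) as follow-up information arrives. For each
#' `caseid` the version with the most recent FDA acceptance date is kept;
#' ties on the date keep the larger `primaryid` (the later database
#' insertion). The operation is idempotent and independent of bundle order.
#'
#' @param bundles A `faers_bundle` or list of them.
#' @return A `faers_cases` object: list with a per-report `demo` tibble
#'   (one row per retained case, with derived `age_years`, `weight_kg`,
#'   `report_year`, `serious`), the child tables restricted to retained
#'   reports, and dedup bookkeeping (`n_input_reports`, `n_removed`).
#' @export
deduplicate <- function(bundles) {
  if (inherits(bundles, "faers_bundle")) bundles <- list(bundles)
  stopifnot(length(bundles) > 0,
            all(vapply(bundles, inherits, TRUE, "faers_bundle")))
  demo <- dplyr::bind_rows(lapply(bundles, `[[`, "demo"))
  drug <- dplyr::bind_rows(lapply(bundles, `[[`, "drug"))
  reac <- dplyr::bind_rows(lapply(bundles, `[[`, "reac"))
  outc <- dplyr::bind_rows(lapply(bundles, `[[`, "outc"))
  indi <- dplyr::bind_rows(lapply(bundles, `[[`, "indi"))
  if (nrow(demo) == 0) stop("no reports to deduplicate", call. = FALSE)
  if (!"fda_dt_parsed" %in% names(demo)) demo$fda_dt_parsed <- parse_fda_date(demo$fda_dt)
  if (!"report_year" %in% names(demo)) {
    demo$report_year <- as.integer(format(demo$fda_dt_parsed, "%Y"))
  }

  demo$.id_key <- primaryid_order_key(demo$primaryid)
  case_key <- primaryid_order_key(demo$caseid)
  ord <- order(case_key, -as.numeric(demo$fda_dt_parsed), -demo$.id_key)
  demo_o <- demo[ord, , drop = FALSE]
  kept <- demo_o[!duplicated(demo_o$caseid), , drop = FALSE]
  kept <- kept[order(kept$.id_key), , drop = FALSE]
  kept$.id_key <- NULL

  ids <- kept$primaryid
  drug <- drug[drug$primaryid %in% ids, , drop = FALSE]
  reac <- reac[reac$primaryid %in% ids, , drop = FALSE]
  outc <- outc[outc$primaryid %in% ids, , drop = FALSE]
  indi <- indi[indi$primaryid %in% ids, , drop = FALSE]

  serious_ids <- unique(outc$primaryid[outc$outc_cod %in% SERIOUS_CODES])
  kept$serious <- kept$primaryid %in% serious_ids

  structure(
    list(demo = kept, drug = tibble::as_tibble(drug),
         reac = tibble::as_tibble(reac), outc = tibble::as_tibble(outc),
         indi = tibble::as_tibble(indi),
         n_input_reports = nrow(demo), n_removed = nrow(demo) - nrow(kept)),
    class = "faers_cases"
  )
}

#' @export
print.faers_cases <- function(x, ...) {
  cat(sprintf("<faers_cases> %d deduplicated reports (%d versions removed)\n",
              nrow(x$demo), x$n_removed))
  if (!is.null(attr(x, "cohort"))) {
    cat(sprintf("  cohort: %d reports\n", sum(x$demo$in_cohort)))
  }
  invisible(x)
}

#' Classify report seriousness from outcome codes
#'
#' A report is serious when any outcome code is DE (death), LT
#' (life-threatening), HO (hospitalization) or DS (disability). Other codes
#' (CA, RI, OT) do not confer seriousness under this definition; the code
#' set is configurable.
#'
#' @param outcomes Character vector of outcome codes for one report, or a
#'   list of such vectors.
#' @param serious_codes Codes that define a serious report.
#' @return Logical scalar (or vector, for list input).
#' @export
classify_serious <- function(outcomes, serious_codes = SERIOUS_CODES) {
  if (is.list(outcomes)) {
    return(vapply(outcomes, classify_serious, TRUE, serious_codes = serious_codes))
  }
  any(outcomes %in% serious_codes)
}

match_synonyms <- function(drug, synonyms) {
  syn <- tolower(trimws(synonyms))
  tolower(drug$drugname) %in% syn | tolower(drug$prod_ai) %in% syn
}

#' Build the combination-regimen cohort
#'
#' A deduplicated report joins the cohort when at least `require_k` of the
#' regimen's synonym sets are each matched by a drug entry whose role code
#' is in `roles` (default: primary or secondary suspect). The default
#' `require_k = length(regimen)` demands every component co-reported as a
#' suspect on the same report.
#'
#' @param cases A `faers_cases` object from [deduplicate()].
#' @param regimen Non-empty list of character vectors of drug synonyms.
#' @param roles Role codes that qualify a drug entry.
#' @param require_k Number of regimen components that must be matched.
#' @return A `faers_cohort`: the `faers_cases` object with an `in_cohort`
#'   column on `demo` and counts `n_total_db`, `n_cohort`.
#' @export
build_cohort <- function(cases, regimen = pola_br_regimen(),
                         roles = c("PS", "SS"), require_k = length(regimen)) {
  stopifnot(inherits(cases, "faers_cases"))
  if (length(regimen) == 0) stop("regimen must contain at least one synonym set", call. = FALSE)
  if (require_k < 1 || require_k > length(regimen)) {
    stop("require_k must be between 1 and the number of regimen components", call. = FALSE)
  }
  suspects <- cases$drug[cases$drug$role_cod %in% roles, , drop = FALSE]
  hits <- vapply(regimen, function(syn) {
    ids <- unique(suspects$primaryid[match_synonyms(suspects, syn)])
    cases$demo$primaryid %in% ids
  }, logical(nrow(cases$demo)))
  if (is.null(dim(hits))) hits <- matrix(hits, nrow = nrow(cases$demo))
  n_matched <- rowSums(hits)
  cases$demo$in_cohort <- n_matched >= require_k
  cases$n_total_db <- nrow(cases$demo)
  cases$n_cohort <- sum(cases$demo$in_cohort)
  class(cases) <- c("faers_cohort", class(cases))
  cases
}

age_bin <- function(age_years) {
  dplyr::case_when(
    is.na(age_years) ~ "Unknown",
    age_years < 18 ~ "<18",
    age_years <= 65 ~ "18-65",
    TRUE ~ ">65"
  )
}

summary_block <- function(values, block, levels = NULL) {
  tab <- table(values)
  if (!is.null(levels)) {
    tab <- tab[match(levels, names(tab))]
    tab[is.na(tab)] <- 0
    names(tab) <- levels
  }
  total <- sum(tab)
  tibble::tibble(
    block = block, category = names(tab), n = as.integer(tab),
    pct = if (total > 0) round(100 * as.integer(tab) / total, 2) else 0
  )
}

#' Descriptive characteristics of the cohort
#'
#' Counts and percentages by sex, age bin (<18, 18-65, >65, Unknown),
#' reporting country, indication, seriousness and report year — the layout
#' of a standard spontaneous-report characteristics table. Percentages are
#' within-block and sum to 100 up to rounding.
#'
#' @param cohort A `faers_cohort`.
#' @return Tibble with columns `block`, `category`, `n`, `pct`.
#' @export
demographics_summary <- function(cohort) {
  stopifnot(inherits(cohort, "faers_cohort"))
  demo <- cohort$demo[cohort$demo$in_cohort, , drop = FALSE]
  if (nrow(demo) == 0) {
    return(tibble::tibble(block = character(), category = character(),
                          n = integer(), pct = numeric()))
  }
  sex <- dplyr::recode(demo$sex, F = "Female", M = "Male", .default = "Unknown")
  country <- ifelse(is.na(demo$occr_country), "Unknown", demo$occr_country)
  indi <- cohort$indi[cohort$indi$primaryid %in% demo$primaryid, , drop = FALSE]
  ind_per_case <- indi |>
    dplyr::distinct(.data$primaryid, .data$indi_pt) |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  ind <- ind_per_case$indi_pt[match(demo$primaryid, ind_per_case$primaryid)]
  ind[is.na(ind)] <- "Unknown"
  dplyr::bind_rows(
    summary_block(sex, "Sex", c("Female", "Male", "Unknown")),
    summary_block(age_bin(demo$age_years), "Age (years)",
                  c("<18", "18-65", ">65", "Unknown")),
    summary_block(country, "Reported country"),
    summary_block(ind, "Indication"),
    summary_block(ifelse(demo$serious, "Serious outcome", "Non-serious outcome"),
                  "Outcome", c("Non-serious outcome", "Serious outcome")),
    summary_block(as.character(demo$report_year), "Report year")
  )
}
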