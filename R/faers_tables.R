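# Readers/writers for FAERS-style quarterly ASCII bundles and the PT->SOC map.

FAERS_TABLES <- c("demo", "drug", "reac", "outc", "indi")

FAERS_COLUMNS <- list(
  demo = c("primaryid", "caseid", "caseversion", "fda_dt", "event_dt",
           "age", "age_cod", "sex", "wt", "wt_cod", "occr_country"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
  reac = c("primaryid", "pt"),
  outc = c("primaryid", "outc_cod"),
  indi = c("primaryid", "indi_drug_seq", "indi_pt")
)

ROLE_CODES <- c("PS", "SS", "C", "I")
OUTCOME_CODES <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

#' Normalize a reported age to years
#'
#' FAERS ages carry a unit code: `YR` (years), `MON` (months) or `DY`
#' (days). Unknown units or implausible values (outside \[0, 120) years)
#' become `NA`.
#'
#' @param age Numeric vector of reported ages.
#' @param age_cod Character vector of unit codes, recycled against `age`.
#' @return Numeric vector of ages in years.
#' @examples
#' normalize_age(c(6, 730, 60), c("MON", "DY", "YR"))
#' @export
normalize_age <- function(age, age_cod) {
  age <- suppressWarnings(as.numeric(age))
  div <- dplyr::case_when(
    toupper(age_cod) %in% c("YR", "YEAR", "") | is.na(age_cod) ~ 1,
    toupper(age_cod) == "MON" ~ 12,
    toupper(age_cod) == "DY" ~ 365,
    TRUE ~ NA_real_
  )
  yrs <- age / div
  yrs[!is.na(yrs) & (yrs < 0 | yrs >= 120)] <- NA_real_
  yrs
}

#' Normalize a reported weight to kilograms
#'
#' @param wt Numeric vector of reported weights.
#' @param wt_cod Unit code, `KG` or `LBS`.
#' @return Numeric vector of weights in kg.
#' @export
normalize_weight <- function(wt, wt_cod) {
  wt <- suppressWarnings(as.numeric(wt))
  dplyr::case_when(
    toupper(wt_cod) %in% c("KG", "") | is.na(wt_cod) ~ wt,
    toupper(wt_cod) == "LBS" ~ wt * 0.45359237,
    TRUE ~ NA_real_
  )
}

parse_fda_date <- function(x) {
  x <- trimws(as.character(x))
  x[x == ""] <- NA_character_
  as.Date(x, format = "%Y%m%d")
}

read_faers_file <- function(path, delim = "$") {
  readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    trim_ws = TRUE, na = character(), progress = FALSE,
    show_col_types = FALSE
  )
}

require_columns <- function(df, table, file) {
  names(df) <- tolower(names(df))
  missing <- setdiff(FAERS_COLUMNS[[table]], names(df))
  if (length(missing) > 0) {
    stop(sprintf("file '%s' (%s table) is missing mandatory column(s): %s",
                 file, toupper(table), paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  df[FAERS_COLUMNS[[table]]]
}

blank_to_na <- function(x) {
  x <- trimws(x)
  x[x == ""] <- NA_character_
  x
}

# Validate one raw table; returns list(records, n_rejected, reasons).
# Parsing is total: every row is either kept (possibly normalized) or
# counted as a reasoned rejection.
validate_table <- function(df, table) {
  reasons <- character(0)
  keep <- rep(TRUE, nrow(df))
  if (table == "demo") {
    df$fda_dt_parsed <- parse_fda_date(df$fda_dt)
    bad <- is.na(df$fda_dt_parsed)
    if (any(bad)) reasons <- c(reasons, sprintf("unparseable fda_dt: %d row(s)", sum(bad)))
    keep <- keep & !bad
    sex <- toupper(trimws(df$sex))
    df$sex <- ifelse(sex %in% c("F", "M"), sex, "UNK")
    cv <- suppressWarnings(as.integer(df$caseversion))
    cv[is.na(cv) | cv < 0] <- 0L
    df$caseversion <- cv
    df$age_years <- normalize_age(blank_to_na(df$age), blank_to_na(df$age_cod))
    df$weight_kg <- normalize_weight(blank_to_na(df$wt), blank_to_na(df$wt_cod))
    df$report_year <- as.integer(format(df$fda_dt_parsed, "%Y"))
    df$occr_country <- blank_to_na(df$occr_country)
  } else if (table == "drug") {
    role <- toupper(trimws(df$role_cod))
    bad <- !(role %in% ROLE_CODES)
    if (any(bad)) reasons <- c(reasons, sprintf("invalid role_cod: %d row(s)", sum(bad)))
    keep <- keep & !bad
    df$role_cod <- role
    df$drugname <- trimws(df$drugname)
    df$prod_ai <- trimws(df$prod_ai)
  } else if (table == "reac") {
    df$pt <- trimws(df$pt)
    bad <- is.na(df$pt) | df$pt == ""
    if (any(bad)) reasons <- c(reasons, sprintf("empty pt: %d row(s)", sum(bad)))
    keep <- keep & !bad
  } else if (table == "outc") {
    code <- toupper(trimws(df$outc_cod))
    bad <- !(code %in% OUTCOME_CODES)
    if (any(bad)) reasons <- c(reasons, sprintf("invalid outc_cod: %d row(s)", sum(bad)))
    keep <- keep & !bad
    df$outc_cod <- code
  } else if (table == "indi") {
    df$indi_pt <- trimws(df$indi_pt)
    bad <- is.na(df$indi_pt) | df$indi_pt == ""
    if (any(bad)) reasons <- c(reasons, sprintf("empty indi_pt: %d row(s)", sum(bad)))
    keep <- keep & !bad
  }
  list(records = df[keep, , drop = FALSE], n_rejected = sum(!keep), reasons = reasons)
}

locate_quarter_files <- function(path, label = NULL) {
  if (is.list(path) || (is.character(path) && !is.null(names(path)))) {
    files <- as.list(path)
    names(files) <- tolower(names(files))
  } else {
    stopifnot(dir.exists(path))
    files <- lapply(FAERS_TABLES, function(tab) {
      pat <- sprintf("^%s.*\\.(txt|TXT)(\\.gz)?$", toupper(tab))
      hits <- list.files(path, pattern = pat, full.names = TRUE)
      if (!is.null(label)) {
        tagged <- hits[grepl(label, basename(hits), fixed = TRUE)]
        if (length(tagged) > 0) hits <- tagged
      }
      hits
    })
    names(files) <- FAERS_TABLES
  }
  missing <- FAERS_TABLES[vapply(files[FAERS_TABLES], length, 1L) == 0]
  if (length(missing) > 0) {
    stop(sprintf("no file found for table(s): %s", paste(toupper(missing), collapse = ", ")),
         call. = FALSE)
  }
  too_many <- FAERS_TABLES[vapply(files[FAERS_TABLES], length, 1L) > 1]
  if (length(too_many) > 0) {
    stop(sprintf("multiple candidate files for table(s): %s (pass named paths)",
                 paste(toupper(too_many), collapse = ", ")), call. = FALSE)
  }
  lapply(files[FAERS_TABLES], `[[`, 1)
}

#' Read one quarterly FAERS-style bundle
#'
#' Reads the five dollar-delimited ASCII tables (DEMO, DRUG, REAC, OUTC,
#' INDI) that make up one quarterly extract, validates and types every row,
#' and drops orphan child rows whose `primaryid` does not appear in DEMO.
#' Malformed rows are counted and reported in the bundle's `log`, never
#' silently discarded.
#'
#' @param path Either a directory containing files named like
#'   `DEMO23Q1.txt`, ..., or a named list/vector with elements `demo`,
#'   `drug`, `reac`, `outc`, `indi` giving explicit file paths. Plain or
#'   gzip-compressed files are accepted.
#' @param label Quarter tag, e.g. `"2023Q1"`. When `path` is a directory
#'   the label also disambiguates file names.
#' @param delim Field delimiter; FAERS convention is `"$"`.
#' @return A `faers_bundle`: list with tibbles `demo`, `drug`, `reac`,
#'   `outc`, `indi`, the `label`, and a `log` tibble of rejection counts.
#' @seealso [write_quarter()]
#' @export
read_quarter <- function(path, label = NULL, delim = "$") {
  files <- locate_quarter_files(path, label)
  log <- list()
  tabs <- list()
  for (tab in FAERS_TABLES) {
    raw <- read_faers_file(files[[tab]], delim = delim)
    raw <- require_columns(raw, tab, files[[tab]])
    v <- validate_table(raw, tab)
    tabs[[tab]] <- tibble::as_tibble(v$records)
    log[[tab]] <- tibble::tibble(
      table = toupper(tab), n_read = nrow(raw), n_kept = nrow(v$records),
      n_rejected = v$n_rejected,
      reasons = paste(v$reasons, collapse = "; ")
    )
  }
  # orphan child rows: primaryid absent from DEMO
  ids <- tabs$demo$primaryid
  for (tab in setdiff(FAERS_TABLES, "demo")) {
    orphan <- !(tabs[[tab]]$primaryid %in% ids)
    if (any(orphan)) {
      log[[tab]]$n_rejected <- log[[tab]]$n_rejected + sum(orphan)
      log[[tab]]$n_kept <- log[[tab]]$n_kept - sum(orphan)
      log[[tab]]$reasons <- paste(c(
        log[[tab]]$reasons[nzchar(log[[tab]]$reasons)],
        sprintf("orphan primaryid: %d row(s)", sum(orphan))), collapse = "; ")
      tabs[[tab]] <- tabs[[tab]][!orphan, , drop = FALSE]
    }
  }
  new_faers_bundle(tabs$demo, tabs$drug, tabs$reac, tabs$outc, tabs$indi,
                   label = label, log = dplyr::bind_rows(log))
}

#' Construct a FAERS bundle from in-memory tables
#'
#' @param demo,drug,reac,outc,indi Tibbles with the FAERS column layout
#'   (see `read_quarter()` for the mandatory columns).
#' @param label Quarter tag.
#' @param log Optional ingestion log tibble.
#' @return A `faers_bundle` object.
#' @export
new_faers_bundle <- function(demo, drug, reac, outc, indi, label = NULL,
                             log = NULL) {
  structure(
    list(demo = tibble::as_tibble(demo), drug = tibble::as_tibble(drug),
         reac = tibble::as_tibble(reac), outc = tibble::as_tibble(outc),
         indi = tibble::as_tibble(indi), label = label, log = log),
    class = "faers_bundle"
  )
}

#' @export
print.faers_bundle <- function(x, ...) {
  cat(sprintf("<faers_bundle %s> %d reports; %d drug / %d reaction / %d outcome / %d indication rows\n",
              x$label %||% "(unlabelled)", nrow(x$demo), nrow(x$drug),
              nrow(x$reac), nrow(x$outc), nrow(x$indi)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

quarter_suffix <- function(label) {
  # "2023Q1" -> "23Q1"
  if (grepl("^\\d{4}Q[1-4]$", label)) substr(label, 3, 6) else label
}

#' Write a bundle back out as quarterly ASCII files
#'
#' Emits the five dollar-delimited files (`DEMOyyQq.txt`, ...) so that
#' `read_quarter()` on the output reproduces the bundle record for record.
#' Blank optional fields are written as empty strings.
#'
#' @param bundle A `faers_bundle`.
#' @param dir Output directory (created if absent).
#' @param delim Field delimiter.
#' @return Invisibly, a named character vector of the file paths written.
#' @export
write_quarter <- function(bundle, dir, delim = "$") {
  stopifnot(inherits(bundle, "faers_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  label <- bundle$label %||% "00Q0"
  out <- character(0)
  for (tab in FAERS_TABLES) {
    df <- bundle[[tab]][FAERS_COLUMNS[[tab]]]
    df[] <- lapply(df, function(col) {
      col <- as.character(col)
      col[is.na(col)] <- ""
      col
    })
    path <- file.path(dir, sprintf("%s%s.txt", toupper(tab), quarter_suffix(label)))
    readr::write_delim(df, path, delim = delim, na = "")
    out[tab] <- path
  }
  invisible(out)
}

#' Read a PT to System Organ Class mapping
#'
#' Two-column tab-separated text with header `pt`, `soc`. Keys are matched
#' case-insensitively after trimming; each PT must map to exactly one SOC.
#'
#' @param path Path to the mapping file.
#' @return A `meddra_map` object (named character vector, lower-cased keys).
#' @export
read_soc_map <- function(path) {
  df <- readr::read_tsv(path, col_types = "cc", progress = FALSE,
                        show_col_types = FALSE)
  if (!all(c("pt", "soc") %in% names(df))) {
    stop("SOC map must have columns 'pt' and 'soc'", call. = FALSE)
  }
  key <- tolower(trimws(df$pt))
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    clash <- tapply(df$soc, key, function(s) length(unique(s)) > 1)
    if (any(clash)) {
      stop(sprintf("PT(s) mapped to more than one SOC: %s",
                   paste(names(clash)[clash], collapse = ", ")), call. = FALSE)
    }
    df <- df[!duplicated(key), ]
    key <- key[!duplicated(key)]
  }
  structure(stats::setNames(df$soc, key), class = "meddra_map")
}

#' Map Preferred Terms to their System Organ Class
#'
#' Case-insensitive exact lookup; PTs absent from the map return the
#' sentinel `"Unmapped"` rather than erroring, so signal tables can always
#' be grouped by SOC.
#'
#' @param pt Character vector of MedDRA Preferred Terms.
#' @param map A `meddra_map` from [read_soc_map()].
#' @return Character vector of SOC names.
#' @export
map_pt_to_soc <- function(pt, map) {
  stopifnot(inherits(map, "meddra_map"))
  soc <- unname(map[tolower(trimws(pt))])
  soc[is.na(soc)] <- "Unmapped"
  soc
}
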